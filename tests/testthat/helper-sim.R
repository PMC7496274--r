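# Shared small simulated fixtures, built once per test run.

# default half-diallel F2 at a modest genome (12 chromosomes)
hd_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      founders <- make_founders(rep(15, 12), rep(60e6, 12), seed = 101)
      pop <- simulate_population(
        founders, cross_plan(generation = "F2", n_per_cross = 50),
        seed = 102)
      cache <<- list(founders = founders, pop = pop,
                     M = encode_parental_dosage(pop),
                     rin = build_rin_design(pop))
    }
    cache
  }
})

# tiny two-chromosome founder set for io/haplotype tests
small_founders <- function(seed = 11)
  make_founders(rep(8, 2), rep(40e6, 2), seed = seed)

expect_same_values <- function(a, b, tol = 1e-12) {
  expect_equal(unname(as.vector(a)), unname(as.vector(b)), tolerance = tol)
}
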