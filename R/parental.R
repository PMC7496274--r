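#' Encode parental-origin allele counts (the four-column marker design)
#'
#' For every marker, builds the n x 4 matrix whose entry (i, j) is the
#' number of alleles individual i inherited from founder j. With
#' homozygous parents, the counts at a marker are uniquely determined from
#' the offspring alt-allele dosage wherever the two parents of the
#' individual's cross carry different alleles; markers monomorphic within
#' a cross are masked uninformative for that cross. Offspring dosages that
#' are missing, or inconsistent with the parental alleles, are masked
#' per-entry and counted in the mask report rather than dropping the
#' individual.
#'
#' @param pop a \code{population} (supplies cross membership and, by
#'   default, the genotypes).
#' @param founders the \code{founder_set} (defaults to \code{pop$founders}).
#' @param genotypes optional dosage matrix overriding the population's own
#'   (e.g. re-read from a VCF, possibly with errors/missingness).
#' @return a \code{parental_dosage}: array \code{counts} (n x markers x 4),
#'   logical \code{informative} (crosses x markers), logical \code{valid}
#'   (n x markers, FALSE where masked), plus ids, cross labels, map and
#'   founder ids.
#' @export
encode_parental_dosage <- function(pop, founders = pop$founders,
                                   genotypes = NULL) {
  stopifnot(inherits(pop, "population"))
  from_truth <- is.null(genotypes)
  if (from_truth) genotypes <- genotype_dosage(pop)
  map <- founders$map
  hap <- founders$haplotypes
  ids <- founders$founder_ids
  n <- length(pop$ids)
  m <- nrow(map)
  crosses <- pop$crosses
  if (any(!pop$cross %in% names(crosses)))
    stop("individual(s) with unknown cross")
  counts <- array(0, dim = c(n, m, 4L),
                  dimnames = list(pop$ids, map$marker, ids))
  informative <- matrix(FALSE, length(crosses), m,
                        dimnames = list(names(crosses), map$marker))
  valid <- matrix(FALSE, n, m, dimnames = list(pop$ids, map$marker))

  for (cl in names(crosses)) {
    rows <- which(pop$cross == cl)
    pa <- match(crosses[[cl]][1], ids)
    pb <- match(crosses[[cl]][2], ids)
    aA <- hap[pa, ]
    aB <- hap[pb, ]
    inf <- aA != aB
    informative[cl, ] <- inf
    g <- genotypes[rows, , drop = FALSE]
    # countA = g where parent A carries the alt allele, 2 - g otherwise
    cntA <- sweep(g, 2L, ifelse(aA == 1, 0, 2), "-") *
      rep(ifelse(aA == 1, 1, -1), each = length(rows))
    ok <- !is.na(g) & cntA >= 0 & cntA <= 2 &
      matrix(inf, length(rows), m, byrow = TRUE)
    cntA[!ok] <- 0
    cntB <- ifelse(ok, 2 - cntA, 0)
    counts[rows, , pa] <- counts[rows, , pa] + cntA
    counts[rows, , pb] <- counts[rows, , pb] + cntB
    valid[rows, ] <- ok
  }
  n_masked <- sum(informative[pop$cross, ] & !valid)
  structure(list(counts = counts, informative = informative, valid = valid,
                 ids = pop$ids, cross = pop$cross, crosses = crosses,
                 founder_ids = ids, map = map, n_masked = n_masked,
                 provenance = if (from_truth) "tracked-truth" else "inferred"),
            class = "parental_dosage")
}

#' @export
print.parental_dosage <- function(x, ...) {
  cat(sprintf(paste0("parental_dosage: %d individuals x %d markers x 4 ",
                     "founders; %d masked entr%s\n"),
              dim(x$counts)[1], dim(x$counts)[2], x$n_masked,
              ifelse(x$n_masked == 1, "y", "ies")))
  invisible(x)
}

#' Tracked-truth parental allele counts
#'
#' Reads founder-origin counts directly off the simulator's origin record;
#' used as the oracle against which \code{\link{encode_parental_dosage}}
#' is checked.
#'
#' @param pop an origin-tracked \code{population}.
#' @return n x markers x 4 array of counts.
#' @export
parental_counts_truth <- function(pop) {
  n <- length(pop$ids)
  m <- ncol(pop$origins1)
  counts <- array(0L, dim = c(n, m, 4L),
                  dimnames = list(pop$ids, pop$founders$map$marker,
                                  pop$founders$founder_ids))
  for (f in 1:4)
    counts[, , f] <- (pop$origins1 == f) + (pop$origins2 == f)
  counts
}

#' Build the rin nuisance design
#'
#' Fixed-effect columns correcting for a ripening mutation segregating in
#' the crosses that contain the carrier parent: a per-carrier-cross
#' intercept, an additive code a = mutant dosage - 1, a dominance code
#' d = [heterozygote], and cross-by-(a, d) interaction columns. All columns
#' are zero outside carrier crosses. The expansion is deliberately
#' redundant (main effects plus full interactions); rank deficiency is
#' resolved downstream by pivoted least squares.
#'
#' @param pop a \code{population}.
#' @param rin_marker marker id of the mutation locus (default: the
#'   founder set's rin marker).
#' @param carrier carrier founder label (default: the founder set's).
#' @param dosage optional observed mutant-allele dosage per individual;
#'   default is the tracked truth.
#' @return a \code{rin_design}: matrix \code{X} (n x columns),
#'   \code{indicator}, \code{a}, \code{d} vectors.
#' @export
build_rin_design <- function(pop, rin_marker = pop$founders$rin_marker,
                             carrier = pop$founders$rin_carrier,
                             dosage = NULL) {
  stopifnot(inherits(pop, "population"))
  if (!carrier %in% pop$founders$founder_ids)
    stop("carrier not in founder set: ", carrier)
  if (is.null(dosage)) {
    j <- match(rin_marker, pop$founders$map$marker)
    if (is.na(j)) stop("rin marker not in map: ", rin_marker)
    ci <- match(carrier, pop$founders$founder_ids)
    dosage <- (pop$origins1[, j] == ci) + (pop$origins2[, j] == ci)
  }
  carrier_crosses <- names(pop$crosses)[vapply(pop$crosses, function(p)
    carrier %in% p, TRUE)]
  ind <- as.numeric(pop$cross %in% carrier_crosses)
  a <- ifelse(ind == 1, dosage - 1, 0)
  d <- ifelse(ind == 1 & dosage == 1, 1, 0)
  cols <- list()
  for (cl in carrier_crosses) {
    in_cl <- as.numeric(pop$cross == cl)
    cols[[paste0("rin_", cl)]] <- in_cl
  }
  cols[["rin_a"]] <- a
  cols[["rin_d"]] <- d
  if (length(carrier_crosses) > 1L) {
    for (cl in carrier_crosses) {
      in_cl <- pop$cross == cl
      cols[[paste0("rin_a_", cl)]] <- ifelse(in_cl, a, 0)
      cols[[paste0("rin_d_", cl)]] <- ifelse(in_cl, d, 0)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- pop$ids
  structure(list(X = X, indicator = ind, a = a, d = d,
                 carrier_crosses = carrier_crosses, carrier = carrier),
            class = "rin_design")
}
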