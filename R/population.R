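#' Specify the crossing and inbreeding plan
#'
#' @param crosses list of length-2 character vectors (parent pairs); default
#'   is all six pairwise crosses of the four founders (half diallel).
#' @param generation "F1", "F2" or "F6".
#' @param n_per_cross individuals (lines) per cross.
#' @param rin_selection if TRUE, crosses containing the rin carrier exclude
#'   mutant homozygotes from F2 selfing entry, and only lines whose F5 plant
#'   is homozygous wild type advance to F6.
#' @param ssd_generations selfing rounds from F2 to the final RIL
#'   generation (default 4: F2 -> F6 by single-seed descent).
#' @return a \code{cross_plan} list.
#' @export
cross_plan <- function(crosses = NULL, generation = c("F2", "F6", "F1"),
                       n_per_cross = 50L, rin_selection = FALSE,
                       ssd_generations = 4L) {
  generation <- match.arg(generation)
  if (n_per_cross < 1L) stop("n_per_cross must be >= 1")
  structure(list(crosses = crosses, generation = generation,
                 n_per_cross = as.integer(n_per_cross),
                 rin_selection = isTRUE(rin_selection),
                 ssd_generations = as.integer(ssd_generations)),
            class = "cross_plan")
}

# One meiosis: recombine the two origin vectors of a parent into a gamete.
# Crossover count per chromosome is Poisson(map length in Morgans), crossover
# positions are uniform in bp and there is no interference, i.e. the Haldane
# model. `chrom_index` is a list of marker indices per chromosome,
# `chrom_pos` the matching positions, `lens` the chromosome lengths in bp.
make_gamete <- function(orig1, orig2, chrom_index, chrom_pos, lens,
                        rate_cM_per_Mbp) {
  gam <- integer(length(orig1))
  for (k in seq_along(chrom_index)) {
    idx <- chrom_index[[k]]
    morgans <- rate_cM_per_Mbp * (lens[k] / 1e6) / 100
    n_xo <- rpois(1L, morgans)
    strand <- sample.int(2L, 1L)
    if (n_xo == 0L) {
      gam[idx] <- if (strand == 1L) orig1[idx] else orig2[idx]
    } else {
      xo <- sort(runif(n_xo, 0, lens[k]))
      # strand at a marker flips once per crossover to its left
      flips <- findInterval(chrom_pos[[k]], xo)
      s <- (strand - 1L + flips) %% 2L
      gam[idx] <- ifelse(s == 0L, orig1[idx], orig2[idx])
    }
  }
  gam
}

#' Simulate half-diallel populations by meiosis and single-seed descent
#'
#' Gametes are formed under the Haldane model: crossover counts are Poisson
#' with mean equal to the chromosome map length (a uniform cM/Mbp rate times
#' physical length), crossover positions are uniform, and there is no
#' interference. F2 individuals are selfed F1s; F6 RILs are obtained by
#' \code{ssd_generations} rounds of single-seed descent from an F2 plant.
#' The founder origin of every allele is tracked and retained, which gives
#' downstream encoders an exact truth record.
#'
#' With \code{rin_selection}, in crosses containing the rin carrier, F2
#' plants homozygous for the mutant allele are not advanced, and the selfing
#' chain is redrawn from the same F2 plant until the F5 plant is homozygous
#' wild type (mirroring selection applied during line development).
#'
#' @param founders a \code{founder_set}.
#' @param plan a \code{cross_plan}.
#' @param recomb_rate_cM_per_Mbp uniform genetic map rate (default 2).
#' @param seed integer seed.
#' @return a \code{population}: ids, cross labels, generation, parent pairs,
#'   origin matrices (n x markers, values 1..4 indexing founders) for both
#'   homologues, and the founder set.
#' @export
simulate_population <- function(founders, plan,
                                recomb_rate_cM_per_Mbp = 2, seed = 1L) {
  stopifnot(inherits(founders, "founder_set"), inherits(plan, "cross_plan"))
  if (recomb_rate_cM_per_Mbp < 0) stop("recombination rate must be >= 0")
  crosses <- plan$crosses
  if (is.null(crosses)) crosses <- half_diallel_crosses(founders)
  ids <- founders$founder_ids
  for (cr in crosses)
    if (!all(cr %in% ids)) stop("unknown parent in cross: ",
                                paste(cr, collapse = " x "))
  set.seed(seed)
  map <- founders$map
  chroms <- unique(map$chrom)
  chrom_index <- lapply(chroms, function(ch) which(map$chrom == ch))
  chrom_pos <- lapply(chrom_index, function(i) map$pos_bp[i])
  lens <- founders$chrom_lengths_bp[chroms]
  m <- nrow(map)
  rin_col <- match(founders$rin_marker, map$marker)
  carrier_idx <- match(founders$rin_carrier, ids)

  n_tot <- length(crosses) * plan$n_per_cross
  o1 <- matrix(NA_integer_, n_tot, m)
  o2 <- matrix(NA_integer_, n_tot, m)
  cross_lab <- character(n_tot)
  indiv <- character(n_tot)

  self_once <- function(ind) {
    g1 <- make_gamete(ind[[1]], ind[[2]], chrom_index, chrom_pos, lens,
                      recomb_rate_cM_per_Mbp)
    g2 <- make_gamete(ind[[1]], ind[[2]], chrom_index, chrom_pos, lens,
                      recomb_rate_cM_per_Mbp)
    list(g1, g2)
  }
  rin_dosage <- function(ind)
    (ind[[1]][rin_col] == carrier_idx) + (ind[[2]][rin_col] == carrier_idx)

  row <- 0L
  for (ci in seq_along(crosses)) {
    pa <- match(crosses[[ci]][1], ids)
    pb <- match(crosses[[ci]][2], ids)
    lab <- cross_label(crosses[[ci]])
    f1 <- list(rep(pa, m), rep(pb, m))
    select_rin <- plan$rin_selection && carrier_idx %in% c(pa, pb)
    for (i in seq_len(plan$n_per_cross)) {
      row <- row + 1L
      if (plan$generation == "F1") {
        ind <- f1
      } else {
        repeat {
          f2 <- self_once(f1)
          if (!select_rin || rin_dosage(f2) < 2L) break
        }
        ind <- f2
        if (plan$generation == "F6") {
          # SSD chain F2 -> F5 (ssd_generations - 1 selfings), redraw the
          # whole chain from the same F2 plant if F5 selection fails.
          attempt <- 0L
          repeat {
            attempt <- attempt + 1L
            f5 <- f2
            for (g in seq_len(plan$ssd_generations - 1L)) f5 <- self_once(f5)
            if (!select_rin || rin_dosage(f5) == 0L) break
            if (attempt >= 500L) stop("rin selection failed repeatedly for ",
                                      lab, " line ", i)
          }
          ind <- self_once(f5)
        }
      }
      o1[row, ] <- ind[[1]]
      o2[row, ] <- ind[[2]]
      cross_lab[row] <- lab
      indiv[row] <- sprintf("%s_%s_%03d", lab, plan$generation, i)
    }
  }
  structure(list(ids = indiv, cross = cross_lab,
                 generation = plan$generation,
                 crosses = setNames(crosses, vapply(crosses, cross_label, "")),
                 origins1 = o1, origins2 = o2,
                 founders = founders, seed = seed,
                 recomb_rate_cM_per_Mbp = recomb_rate_cM_per_Mbp),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d %s individuals, %d cross(es), %d markers\n",
              length(x$ids), x$generation, length(unique(x$cross)),
              ncol(x$origins1)))
  invisible(x)
}

#' Alt-allele dosage matrix of a population
#'
#' Translates tracked founder origins into 0/1/2 alt-allele dosages using
#' the founder haplotypes.
#'
#' @param pop a \code{population}.
#' @return integer matrix individuals x markers with dimnames.
#' @export
genotype_dosage <- function(pop) {
  hap <- pop$founders$haplotypes
  m <- ncol(pop$origins1)
  col_idx <- rep(seq_len(m), each = nrow(pop$origins1))
  a1 <- matrix(hap[cbind(as.vector(pop$origins1), col_idx)],
               nrow = nrow(pop$origins1))
  a2 <- matrix(hap[cbind(as.vector(pop$origins2), col_idx)],
               nrow = nrow(pop$origins1))
  g <- a1 + a2
  dimnames(g) <- list(pop$ids, pop$founders$map$marker)
  g
}

#' Mutant rin-allele dosage of each individual
#'
#' Counts the alleles at the rin locus that descend from the carrier
#' founder (tracked truth).
#'
#' @param pop a \code{population}.
#' @return integer vector in 0..2, named by individual.
#' @export
rin_dosage_truth <- function(pop) {
  j <- match(pop$founders$rin_marker, pop$founders$map$marker)
  ci <- match(pop$founders$rin_carrier, pop$founders$founder_ids)
  setNames((pop$origins1[, j] == ci) + (pop$origins2[, j] == ci), pop$ids)
}
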