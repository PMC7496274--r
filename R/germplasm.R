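#' Simulate a germplasm panel as a mixture of founder and novel haplotypes
#'
#' Within each designated region an accession carries, independently and
#' with probability \code{founder_mixture}, the haplotype of a randomly
#' chosen founder; otherwise it carries a novel haplotype, constructed by
#' mutating a founder haplotype until it differs from every founder at one
#' or more region markers. Accessions are homozygous by default;
#' \code{het_fraction} makes a fraction of accessions carry two independent
#' draws (hybrids). Markers outside the regions are filled with random
#' founder alleles. The per-accession, per-region truth (which founder, or
#' "novel") is retained for oracle checks.
#'
#' @param founders a \code{founder_set}.
#' @param regions list of \code{qtl_region}s; default one region spanning
#'   each chromosome.
#' @param founder_mixture probability in [0, 1] that a region haplotype is
#'   a founder haplotype.
#' @param n_accessions panel size.
#' @param seed integer seed.
#' @param het_fraction fraction of accessions with independently drawn
#'   homologues (default 0, i.e. fully homozygous panel).
#' @param novel_mutation_rate per-marker flip probability used to build
#'   novel haplotypes.
#' @param missing_rates optional per-marker missing-call probabilities
#'   (recycled over markers), emulating poorly performing assays.
#' @return a \code{germplasm_panel}: genotype dosage matrix (with NA for
#'   missing calls), map, regions, and truth table (accession, region,
#'   haplotype origin per homologue).
#' @export
simulate_germplasm <- function(founders, regions = NULL,
                               founder_mixture = 0.6, n_accessions = 500L,
                               seed = 1L, het_fraction = 0,
                               novel_mutation_rate = 0.3,
                               missing_rates = 0) {
  stopifnot(inherits(founders, "founder_set"))
  if (founder_mixture < 0 || founder_mixture > 1)
    stop("founder_mixture must be in [0, 1]")
  set.seed(seed)
  map <- founders$map
  hap <- founders$haplotypes
  m <- nrow(map)
  if (is.null(regions)) {
    regions <- lapply(unique(map$chrom), function(ch)
      qtl_region(ch, 1, max(map$pos_bp[map$chrom == ch]), label = ch))
  }
  reg_idx <- lapply(regions, markers_in_region, map = map)
  if (any(vapply(reg_idx, length, 1L) == 0L))
    stop("region without markers")
  reg_lab <- vapply(seq_along(regions), function(i)
    ifelse(is.na(regions[[i]]$label), paste0("region", i),
           regions[[i]]$label), "")

  novel_hap <- function(idx) {
    base <- hap[sample.int(4L, 1L), idx]
    repeat {
      flip <- runif(length(idx)) < novel_mutation_rate
      if (!any(flip)) flip[sample.int(length(idx), 1L)] <- TRUE
      cand <- ifelse(flip, 1L - base, base)
      if (all(vapply(1:4, function(f) any(cand != hap[f, idx]), TRUE)))
        return(cand)
    }
  }

  a1 <- matrix(NA_integer_, n_accessions, m)
  a2 <- matrix(NA_integer_, n_accessions, m)
  truth <- vector("list", n_accessions)
  is_het <- runif(n_accessions) < het_fraction
  outside <- setdiff(seq_len(m), unlist(reg_idx))
  for (i in seq_len(n_accessions)) {
    draw_one <- function() {
      h <- integer(m)
      org <- character(length(regions))
      if (length(outside))
        h[outside] <- hap[cbind(sample.int(4L, length(outside), TRUE),
                                outside)]
      for (r in seq_along(regions)) {
        idx <- reg_idx[[r]]
        if (runif(1) < founder_mixture) {
          f <- sample.int(4L, 1L)
          h[idx] <- hap[f, idx]
          org[r] <- founders$founder_ids[f]
        } else {
          h[idx] <- novel_hap(idx)
          org[r] <- "novel"
        }
      }
      list(h = h, org = org)
    }
    d1 <- draw_one()
    d2 <- if (is_het[i]) draw_one() else d1
    a1[i, ] <- d1$h
    a2[i, ] <- d2$h
    truth[[i]] <- data.frame(accession = sprintf("acc_%04d", i),
                             region = reg_lab, hap1 = d1$org, hap2 = d2$org,
                             stringsAsFactors = FALSE)
  }
  g <- a1 + a2
  if (any(missing_rates > 0)) {
    pm <- rep_len(missing_rates, m)
    drop <- matrix(runif(n_accessions * m), n_accessions, m) <
      matrix(pm, n_accessions, m, byrow = TRUE)
    g[drop] <- NA_integer_
  }
  dimnames(g) <- list(sprintf("acc_%04d", seq_len(n_accessions)), map$marker)
  structure(list(genotypes = g, map = map, regions = regions,
                 region_labels = reg_lab,
                 truth = do.call(rbind, truth), founders = founders,
                 seed = seed), class = "germplasm_panel")
}

#' @export
print.germplasm_panel <- function(x, ...) {
  cat(sprintf("germplasm_panel: %d accessions, %d markers, %d region(s)\n",
              nrow(x$genotypes), ncol(x$genotypes), length(x$regions)))
  invisible(x)
}
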