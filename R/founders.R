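#' Simulate a set of four homozygous founder lines
#'
#' Generates a physical marker map and one binary (reference/alternative)
#' allele per founder per marker. Founders are fully homozygous inbreds, as
#' the crossed parents of commercial hybrids are. Alleles are drawn i.i.d.
#' per founder so that each unordered founder pair differs, in expectation,
#' at \code{diff_fraction} of the markers. Because markers are biallelic,
#' four founders cannot all differ pairwise at one marker; requested
#' fractions above 0.5 are realised with balanced 2/2 allele splits, which
#' maximise polymorphism (each pair then differs at 2/3 of markers in
#' expectation).
#'
#' One marker is designated as the ripening-mutation (rin) locus; mutant
#' alleles are the alleles descending from the carrier founder at that
#' marker. By default it is the marker closest to the middle of chromosome
#' 5 (or of the last chromosome when fewer than five are simulated).
#'
#' @param n_markers_per_chrom integer vector, markers per chromosome.
#' @param chrom_lengths_bp chromosome lengths in bp (same length).
#' @param seed integer seed; the same seed reproduces the founder set
#'   bit-for-bit.
#' @param founder_ids four founder labels; the first two are treated as
#'   cherry-type and the last two as round-type parents.
#' @param diff_fraction target pairwise difference fraction (default 0.4).
#' @param rin_marker optional marker id to use as the rin locus.
#' @param rin_carrier founder carrying the homozygous mutant rin allele.
#' @return a \code{founder_set}: list with \code{founder_ids},
#'   \code{haplotypes} (4 x n_markers 0/1 matrix), \code{map},
#'   \code{rin_marker}, \code{rin_carrier}, \code{rin_genotype},
#'   \code{fruit_type}.
#' @export
make_founders <- function(n_markers_per_chrom, chrom_lengths_bp, seed,
                          founder_ids = c("C074", "C085", "R075", "R104"),
                          diff_fraction = 0.4,
                          rin_marker = NULL, rin_carrier = "R075") {
  if (length(n_markers_per_chrom) != length(chrom_lengths_bp))
    stop("n_markers_per_chrom and chrom_lengths_bp lengths differ")
  if (any(n_markers_per_chrom < 1)) stop("need >= 1 marker per chromosome")
  if (any(chrom_lengths_bp <= 0)) stop("chromosome lengths must be > 0")
  if (length(founder_ids) != 4L || anyDuplicated(founder_ids))
    stop("exactly four distinct founder ids required")
  if (!rin_carrier %in% founder_ids) stop("rin carrier not a founder")
  if (diff_fraction < 0 || diff_fraction > 1)
    stop("diff_fraction must be in [0, 1]")
  set.seed(seed)
  n_chrom <- length(n_markers_per_chrom)
  chroms <- sprintf("ch%02d", seq_len(n_chrom))
  pos <- vector("list", n_chrom)
  for (k in seq_len(n_chrom)) {
    pos[[k]] <- sort(sample.int(chrom_lengths_bp[k], n_markers_per_chrom[k]))
  }
  map <- marker_map(
    marker = sprintf("m_%s_%04d", rep(chroms, n_markers_per_chrom),
                     unlist(lapply(n_markers_per_chrom, seq_len))),
    chrom = rep(chroms, n_markers_per_chrom),
    pos_bp = unlist(pos))
  m <- nrow(map)

  if (diff_fraction <= 0.5) {
    # P(two independent Bernoulli(q) draws differ) = 2 q (1 - q)
    q <- (1 - sqrt(1 - 2 * diff_fraction)) / 2
    hap <- matrix(rbinom(4L * m, 1L, q), nrow = 4L)
  } else {
    hap <- vapply(seq_len(m), function(j) sample(c(0L, 0L, 1L, 1L)),
                  integer(4L))
  }
  dimnames(hap) <- list(founder_ids, map$marker)

  if (is.null(rin_marker)) {
    k <- min(5L, n_chrom)
    idx <- which(map$chrom == chroms[k])
    rin_marker <- map$marker[idx[which.min(abs(map$pos_bp[idx] -
                                                 chrom_lengths_bp[k] / 2))]]
  }
  if (!rin_marker %in% map$marker) stop("rin marker not in map")

  structure(list(
    founder_ids = founder_ids,
    haplotypes = hap,
    map = map,
    chrom_lengths_bp = setNames(as.numeric(chrom_lengths_bp), chroms),
    rin_marker = rin_marker,
    rin_carrier = rin_carrier,
    rin_genotype = setNames(ifelse(founder_ids == rin_carrier, 2L, 0L),
                            founder_ids),
    fruit_type = setNames(c("cherry", "cherry", "round", "round"),
                          founder_ids),
    seed = seed), class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf(
    "founder_set: %s; %d markers on %d chromosomes; rin locus %s (carrier %s)\n",
    paste(x$founder_ids, collapse = ", "), ncol(x$haplotypes),
    length(unique(x$map$chrom)), x$rin_marker, x$rin_carrier))
  invisible(x)
}

#' All pairwise crosses of a half diallel
#'
#' @param founders a \code{founder_set}.
#' @return list of length 6 with the unordered parent pairs.
#' @export
half_diallel_crosses <- function(founders) {
  ids <- founders$founder_ids
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) out[[length(out) + 1L]] <- c(ids[i], ids[j])
  out
}

cross_label <- function(parents) paste(parents, collapse = "x")
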