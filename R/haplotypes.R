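#' Remove poorly performing markers
#'
#' Drops markers whose missing-call fraction exceeds the threshold and
#' reports the removals.
#'
#' @param G dosage matrix (individuals x markers, NA missing).
#' @param max_missing_fraction markers with a missing rate strictly above
#'   this are removed (default 0.23).
#' @return the filtered matrix; removed marker ids in attribute
#'   \code{removed}, per-marker missing rates in attribute
#'   \code{missing_fraction}.
#' @export
filter_markers <- function(G, max_missing_fraction = 0.23) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]")
  miss <- colMeans(is.na(G))
  drop <- miss > max_missing_fraction
  if (all(drop)) stop("all markers removed at threshold ",
                      max_missing_fraction)
  if (any(drop))
    message("filter_markers: removed ", sum(drop), " of ", length(drop),
            " markers (missing fraction > ", max_missing_fraction, ")")
  out <- G[, !drop, drop = FALSE]
  attr(out, "removed") <- colnames(G)[drop]
  attr(out, "missing_fraction") <- miss[!drop]
  out
}

#' Call QTL-region haplotypes
#'
#' A region haplotype is the ordered concatenation of unphased genotype
#' symbols (0/1/2, "." for missing) at the region's markers. Founder
#' reference haplotypes are taken from the founder set (homozygous, so
#' symbols 0/2 only). Accessions whose fraction of non-missing region
#' calls falls below \code{min_call} are flagged uncallable and excluded
#' from frequency denominators.
#'
#' @param G dosage matrix (individuals x markers).
#' @param map \code{marker_map} matching G's columns.
#' @param regions list of \code{qtl_region}s.
#' @param founders \code{founder_set} providing reference haplotypes.
#' @param min_call minimum callable fraction (default 0.8).
#' @return a \code{haplotype_table}: per region, accession haplotype
#'   strings, callable flags, and founder reference strings.
#' @export
call_region_haplotypes <- function(G, map, regions, founders,
                                   min_call = 0.8) {
  stopifnot(inherits(founders, "founder_set"))
  sym <- function(v) {
    s <- as.character(v)
    s[is.na(v)] <- "."
    paste(s, collapse = "")
  }
  per_region <- lapply(seq_along(regions), function(r) {
    region <- regions[[r]]
    idx <- markers_in_region(map, region)
    if (length(idx) == 0L)
      stop("region without markers: ",
           ifelse(is.na(region$label), paste0("#", r), region$label))
    mk <- map$marker[idx]
    gcols <- match(mk, colnames(G))
    if (anyNA(gcols)) stop("genotype matrix lacks region marker(s): ",
                           paste(mk[is.na(gcols)], collapse = ", "))
    sub <- G[, gcols, drop = FALSE]
    callable <- rowMeans(!is.na(sub)) >= min_call
    haplo <- apply(sub, 1L, sym)
    fcols <- match(mk, colnames(founders$haplotypes))
    fref <- apply(founders$haplotypes[, fcols, drop = FALSE] * 2L, 1L, sym)
    list(label = ifelse(is.na(region$label), paste0("region", r),
                        region$label),
         markers = mk, haplotypes = haplo, callable = callable,
         founder_ref = fref)
  })
  names(per_region) <- vapply(per_region, function(x) x$label, "")
  structure(list(regions = per_region, min_call = min_call),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d region(s), %d accessions\n",
              length(x$regions),
              length(x$regions[[1]]$haplotypes)))
  invisible(x)
}

# does haplotype string a match reference b, missing positions wildcarded?
hap_matches <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca != "."
  all(ca[ok] == cb[ok])
}

#' Founder-haplotype representation frequencies
#'
#' For each region, the percentage of callable accessions whose haplotype
#' string exactly matches any founder reference string at all non-missing
#' positions (missing positions are wildcards), with a per-founder
#' breakdown and the median frequency across regions. Regions without
#' callable accessions are reported NA and excluded from the median. If
#' two founders share a reference haplotype in a region the collision is
#' reported, since per-founder frequencies then overlap.
#'
#' @param ht a \code{haplotype_table}.
#' @return list with \code{per_region} (data frame: region, n_callable,
#'   represented_pct, one column per founder, collision flag) and
#'   \code{median_pct}.
#' @export
representation_frequencies <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  rows <- lapply(ht$regions, function(rg) {
    idx <- which(rg$callable)
    n_call <- length(idx)
    founders <- names(rg$founder_ref)
    collision <- anyDuplicated(rg$founder_ref) > 0L
    if (n_call == 0L) {
      per_f <- setNames(rep(NA_real_, length(founders)), founders)
      return(data.frame(region = rg$label, n_callable = 0L,
                        represented_pct = NA_real_, t(per_f),
                        collision = collision, stringsAsFactors = FALSE))
    }
    match_mat <- vapply(founders, function(f)
      vapply(rg$haplotypes[idx], hap_matches, TRUE, b = rg$founder_ref[[f]]),
      logical(n_call))
    if (n_call == 1L) match_mat <- matrix(match_mat, nrow = 1L,
                                          dimnames = list(NULL, founders))
    any_match <- apply(match_mat, 1L, any)
    per_f <- 100 * colMeans(match_mat)
    data.frame(region = rg$label, n_callable = n_call,
               represented_pct = 100 * mean(any_match), t(per_f),
               collision = collision, stringsAsFactors = FALSE)
  })
  per_region <- do.call(rbind, rows)
  rownames(per_region) <- NULL
  list(per_region = per_region,
       median_pct = median(per_region$represented_pct, na.rm = TRUE))
}
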