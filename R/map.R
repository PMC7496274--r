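#' Construct a physical marker map
#'
#' A marker map is a data frame with columns \code{marker}, \code{chrom} and
#' \code{pos_bp} (1-based physical position). Markers are sorted by
#' chromosome and position; identifiers must be unique and positions
#' strictly increasing within a chromosome.
#'
#' @param marker character vector of unique marker identifiers.
#' @param chrom chromosome labels.
#' @param pos_bp integer physical positions (bp, 1-based).
#' @return a \code{marker_map} data frame.
#' @export
marker_map <- function(marker, chrom, pos_bp) {
  stopifnot(length(marker) == length(chrom), length(chrom) == length(pos_bp))
  if (length(marker) == 0L) stop("a marker map needs at least one marker")
  if (anyDuplicated(marker)) stop("duplicate marker ids: ",
    paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(pos_bp < 1)) stop("positions must be >= 1")
  m <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                  pos_bp = as.integer(pos_bp), stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$pos_bp), , drop = FALSE]
  rownames(m) <- NULL
  dup <- unlist(tapply(m$pos_bp, m$chrom, function(p) any(duplicated(p))))
  if (any(dup)) stop("duplicate positions within chromosome(s): ",
                     paste(names(dup)[dup], collapse = ", "))
  class(m) <- c("marker_map", "data.frame")
  m
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d markers on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}

is_marker_map <- function(x) inherits(x, "marker_map")

#' Physical region on a chromosome
#'
#' Coordinates are 1-based and inclusive at both ends.
#'
#' @param chrom chromosome label.
#' @param start_bp,end_bp region boundaries in bp; \code{start_bp <= end_bp}.
#' @param label optional region name.
#' @return a \code{qtl_region} object.
#' @export
qtl_region <- function(chrom, start_bp, end_bp, label = NA_character_) {
  if (end_bp < start_bp) stop("region end before start: [",
                              start_bp, ", ", end_bp, "]")
  structure(list(chrom = as.character(chrom),
                 start_bp = as.numeric(start_bp),
                 end_bp = as.numeric(end_bp),
                 label = as.character(label)),
            class = "qtl_region")
}

#' Region from Mbp endpoints
#'
#' Printed interval endpoints such as 54.52 Mbp are interpreted as exact and
#' converted as pos * 1e6 bp.
#'
#' @inheritParams qtl_region
#' @param start_mbp,end_mbp endpoints in Mbp.
#' @return a \code{qtl_region}.
#' @export
region_from_mbp <- function(chrom, start_mbp, end_mbp, label = NA_character_) {
  qtl_region(chrom, start_mbp * 1e6, end_mbp * 1e6, label)
}

#' @export
print.qtl_region <- function(x, ...) {
  cat(sprintf("qtl_region %s: %s:%.0f-%.0f (%.3g kbp)\n",
              ifelse(is.na(x$label), "", x$label), x$chrom,
              x$start_bp, x$end_bp, interval_width_kbp(x)))
  invisible(x)
}

markers_in_region <- function(map, region) {
  which(map$chrom == region$chrom &
          map$pos_bp >= region$start_bp & map$pos_bp <= region$end_bp)
}
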