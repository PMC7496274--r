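#' Detect recombinants within a QTL region
#'
#' An individual is recombinant iff its founder-origin assignment (the
#' count of alleles from the cross's first parent: 2, 1 or 0) changes
#' between consecutive informative markers inside the region; each change
#' is reported as the open physical interval between those two marker
#' positions.
#'
#' @param pop a \code{population} (one cross, or filtered to one cross).
#' @param region a \code{qtl_region}.
#' @param map \code{marker_map} (defaults to the population's).
#' @param M optional precomputed \code{parental_dosage}; default is
#'   inferred from the population genotypes.
#' @param crosses crosses to analyse (default all); a cross with fewer
#'   than two informative region markers is an error.
#' @return data frame: individual, cross, left_marker, right_marker,
#'   left_pos_bp, right_pos_bp (one row per breakpoint; individuals
#'   without breakpoints are absent). Attribute \code{n_informative}
#'   gives the informative marker count per cross.
#' @export
find_recombinants <- function(pop, region, map = pop$founders$map,
                              M = NULL, crosses = unique(pop$cross)) {
  if (is.null(M)) M <- encode_parental_dosage(pop)
  idx <- markers_in_region(map, region)
  out <- list()
  n_inf <- integer(0)
  for (cl in crosses) {
    inf_idx <- idx[M$informative[cl, idx]]
    n_inf[cl] <- length(inf_idx)
    if (length(inf_idx) < 2L)
      stop("fewer than 2 informative region markers for cross ", cl)
    pa <- match(pop$crosses[[cl]][1], M$founder_ids)
    rows <- which(pop$cross == cl)
    cntA <- M$counts[rows, inf_idx, pa, drop = TRUE]
    if (length(rows) == 1L) cntA <- matrix(cntA, nrow = 1L)
    valid <- M$valid[rows, inf_idx, drop = FALSE]
    for (ii in seq_along(rows)) {
      jj <- which(valid[ii, ])
      if (length(jj) < 2L) next
      a <- cntA[ii, jj]
      ch <- which(diff(a) != 0)
      for (b in ch) {
        out[[length(out) + 1L]] <- data.frame(
          individual = pop$ids[rows[ii]], cross = cl,
          left_marker = map$marker[inf_idx[jj[b]]],
          right_marker = map$marker[inf_idx[jj[b + 1L]]],
          left_pos_bp = map$pos_bp[inf_idx[jj[b]]],
          right_pos_bp = map$pos_bp[inf_idx[jj[b + 1L]]],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual = character(), cross = character(),
               left_marker = character(), right_marker = character(),
               left_pos_bp = numeric(), right_pos_bp = numeric(),
               stringsAsFactors = FALSE)
  attr(res, "n_informative") <- n_inf
  res
}

#' Contrast the two allelic classes of a recombinant family
#'
#' Two-sided test (Student's t by default, Kruskal-Wallis as the
#' rank-based alternative) of the trait values of the two homozygous
#' allelic classes.
#'
#' @param values_a,values_b trait values of the two classes (>= 2 each).
#' @param test "t" or "kw".
#' @param alpha significance level for the verdict (default 0.05).
#' @return list: P, significant, test, means of both classes.
#' @export
contrast_family <- function(values_a, values_b, test = c("t", "kw"),
                            alpha = 0.05) {
  test <- match.arg(test)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least two observations per allelic class")
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    P <- 1
  } else if (test == "t") {
    if (var(values_a) == 0 && var(values_b) == 0) {
      # degenerate: distinct constants separate perfectly
      P <- if (values_a[1] == values_b[1]) 1 else 0
    } else {
      P <- t.test(values_a, values_b)$p.value
    }
  } else {
    P <- kruskal_wallis_assoc(pooled,
                              rep(c("A", "B"),
                                  c(length(values_a), length(values_b))))$P
  }
  list(P = P, significant = P < alpha, test = test,
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' A recombinant family for substitution mapping
#'
#' @param id family label.
#' @param segment \code{qtl_region} over which the two allelic classes
#'   differ (the differential segment).
#' @param significant verdict of the family's allelic contrast.
#' @param P optional contrast P value.
#' @return a \code{recombinant_family}.
#' @export
recombinant_family <- function(id, segment, significant, P = NA_real_) {
  stopifnot(inherits(segment, "qtl_region"))
  structure(list(id = id, segment = segment,
                 significant = isTRUE(significant), P = P),
            class = "recombinant_family")
}

# closed-interval helpers on the physical axis (continuous semantics)
iv_intersect <- function(a, b) {
  s <- max(a[1], b[1]); e <- min(a[2], b[2])
  if (s > e) NULL else c(s, e)
}
iv_subtract <- function(a, b) {
  # a minus b; may split in two
  if (is.null(iv_intersect(a, b))) return(list(a))
  pieces <- list()
  if (b[1] > a[1]) pieces[[length(pieces) + 1L]] <- c(a[1], min(b[1], a[2]))
  if (b[2] < a[2]) pieces[[length(pieces) + 1L]] <- c(max(b[2], a[1]), a[2])
  pieces
}

#' Refine a QTL interval by substitution mapping
#'
#' The refined interval is the intersection of the differential segments
#' of all significant families, minus the union of the differential
#' segments of the non-significant families, all within the parent
#' region. Families are treated as a set: the result does not depend on
#' their order. Contradictions (significant families with disjoint
#' segments, a fully excluded intersection, or an exclusion that splits
#' the interval in two) raise an error naming the families involved
#' rather than guessing.
#'
#' @param families list of \code{recombinant_family} objects (>= 1
#'   significant).
#' @param parent the parent \code{qtl_region}.
#' @return the refined \code{qtl_region}.
#' @export
refine_interval <- function(families, parent) {
  stopifnot(inherits(parent, "qtl_region"))
  sig <- Filter(function(f) f$significant, families)
  nonsig <- Filter(function(f) !f$significant, families)
  if (length(sig) == 0L) stop("no significant family: nothing to refine")
  chroms <- vapply(families, function(f) f$segment$chrom, "")
  if (!all(chroms == parent$chrom))
    stop("family segment(s) on a different chromosome than the parent region")
  cur <- c(parent$start_bp, parent$end_bp)
  for (f in sig) {
    cur <- iv_intersect(cur, c(f$segment$start_bp, f$segment$end_bp))
    if (is.null(cur))
      stop("contradiction: significant families with disjoint segments (",
           paste(vapply(sig, function(x) x$id, ""), collapse = ", "), ")")
  }
  pieces <- list(cur)
  for (f in nonsig) {
    b <- c(f$segment$start_bp, f$segment$end_bp)
    pieces <- unlist(lapply(pieces, iv_subtract, b = b), recursive = FALSE)
    pieces <- Filter(function(p) p[2] > p[1], pieces)
    if (length(pieces) == 0L)
      stop("contradiction: non-significant family ", f$id,
           " excludes the whole remaining interval")
    if (length(pieces) > 1L)
      stop("ambiguous refinement: family ", f$id,
           " splits the interval in two")
  }
  qtl_region(parent$chrom, pieces[[1]][1], pieces[[1]][2],
             label = parent$label)
}

#' Interval width in kbp
#'
#' Width is the distance between the endpoint coordinates,
#' (end_bp - start_bp) / 1000; printed Mbp endpoints are interpreted as
#' exact (54.52 Mbp = 54,520,000 bp), so e.g. 54.52-54.85 Mbp spans
#' 330 kbp.
#'
#' @param region a \code{qtl_region}.
#' @return width in kbp.
#' @export
interval_width_kbp <- function(region) {
  (region$end_bp - region$start_bp) / 1000
}

#' Genes overlapping an interval
#'
#' Reads gene features from a GFF3 annotation and returns those with any
#' overlap with the region, sorted by start.
#'
#' @param annotation path to a GFF3 file, or a data frame as returned by
#'   \code{ape::read.gff}.
#' @param region a \code{qtl_region}.
#' @param feature_type feature type(s) to keep (default "gene").
#' @return data frame of overlapping gene features sorted by start, with
#'   columns seqid, start, end, strand, attributes.
#' @export
genes_in_interval <- function(annotation, region,
                              feature_type = "gene") {
  gff <- if (is.character(annotation)) {
    tryCatch(ape::read.gff(annotation),
             error = function(e) stop("unparseable GFF3: ",
                                      conditionMessage(e)))
  } else annotation
  stopifnot(all(c("seqid", "type", "start", "end") %in% names(gff)))
  keep <- gff$type %in% feature_type &
    as.character(gff$seqid) == region$chrom &
    gff$start <= region$end_bp & gff$end >= region$start_bp
  out <- gff[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
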