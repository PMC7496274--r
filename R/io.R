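header_comment <- function(seed = NULL, config_hash = NULL) {
  paste0("diallelQTL v", as.character(packageVersion("diallelQTL")),
         if (!is.null(seed)) paste0(" seed=", seed),
         if (!is.null(config_hash)) paste0(" config=", config_hash))
}

#' Write genotypes as VCF v4.2
#'
#' Biallelic SNP records with a GT field. Phased separators ("|") are used
#' when \code{phased = TRUE} (origin-tracked simulated data); missing calls
#' are "./.". REF/ALT are A/T placeholders: the array markers carry no
#' sequence context, only 0/1 allele codes.
#'
#' @param genotypes individuals x markers dosage matrix (0/1/2, NA missing).
#' @param map matching \code{marker_map}.
#' @param path output file.
#' @param phased write phased genotypes (requires \code{alleles1},
#'   \code{alleles2} matrices instead of dosages).
#' @param alleles1,alleles2 per-homologue 0/1 allele matrices, used when
#'   \code{phased = TRUE}.
#' @param seed,config_hash reproducibility metadata written into the
#'   header.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(genotypes, map, path, phased = FALSE,
                      alleles1 = NULL, alleles2 = NULL,
                      seed = NULL, config_hash = NULL) {
  stopifnot(ncol(genotypes) == nrow(map))
  samples <- rownames(genotypes)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(nrow(genotypes)))
  if (phased) {
    stopifnot(!is.null(alleles1), !is.null(alleles2))
    gt <- matrix(paste0(t(alleles1), "|", t(alleles2)),
                 nrow = nrow(map))
  } else {
    g <- t(genotypes)
    gt <- matrix("./.", nrow(map), length(samples))
    gt[!is.na(g) & g == 0] <- "0/0"
    gt[!is.na(g) & g == 1] <- "0/1"
    gt[!is.na(g) & g == 2] <- "1/1"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=", header_comment(seed, config_hash)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  body <- cbind(map$chrom, map$pos_bp, map$marker, "A", "T", ".", ".",
                ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a dosage matrix and marker map
#'
#' Dosage is the ALT-allele count in the GT field; "./." (or ".|.") is
#' missing. Multiallelic records are skipped with a message. The per-marker
#' missing fraction is attached as attribute \code{missing_fraction} for
#' downstream marker filtering.
#'
#' @param vcf_path path to a VCF v4.2 file.
#' @return list with \code{genotypes} (individuals x markers, NA missing)
#'   and \code{map} (a \code{marker_map}).
#' @export
read_genotypes <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message("skipping ", sum(multi), " multiallelic record(s): ",
            paste(utils::head(fix[multi, "ID"], 5L), collapse = ", "))
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(rownames(v@gt), colnames(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  dos <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dos <- matrix(dos, nrow = nrow(gt))
  genotypes <- t(dos)
  rownames(genotypes) <- colnames(gt)
  colnames(genotypes) <- fix[, "ID"]
  map <- marker_map(fix[, "ID"], fix[, "CHROM"], as.integer(fix[, "POS"]))
  ord <- match(map$marker, colnames(genotypes))
  genotypes <- genotypes[, ord, drop = FALSE]
  attr(genotypes, "missing_fraction") <-
    setNames(colMeans(is.na(genotypes)), colnames(genotypes))
  list(genotypes = genotypes, map = map)
}

#' Write a trait table as TSV
#'
#' Tab-separated, "NA" for missing, with a reproducibility header comment.
#'
#' @param traits trait table data frame.
#' @param path output file.
#' @param seed,config_hash metadata for the header comment.
#' @return \code{path}, invisibly.
#' @export
write_trait_table <- function(traits, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_comment(seed, config_hash)), con)
  # full-precision numeric formatting so round trips are lossless
  fmt <- as.data.frame(lapply(traits, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- NA_character_
      out
    } else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a trait table from TSV
#'
#' Numeric parsing is locale-independent ("." decimal separator); empty
#' cells and "NA" are missing. Duplicated genotype-by-trial rows are an
#' error unless a \code{replicate} column disambiguates them.
#'
#' @param tsv_path path to a tab-separated trait table with a header row.
#' @param check_duplicates error on duplicate (genotype_id, trial)
#'   combinations (default TRUE; skipped when a replicate column exists).
#' @return a trait table data frame.
#' @export
read_trait_table <- function(tsv_path, check_duplicates = TRUE) {
  tab <- read.delim(tsv_path, sep = "\t", header = TRUE,
                    na.strings = c("NA", ""), comment.char = "#",
                    stringsAsFactors = FALSE, dec = ".",
                    check.names = FALSE)
  if (!"genotype_id" %in% names(tab))
    stop("trait table lacks a genotype_id column")
  if (check_duplicates && !"replicate" %in% names(tab)) {
    key <- if ("trial" %in% names(tab))
      paste(tab$genotype_id, tab$trial) else tab$genotype_id
    if (anyDuplicated(key))
      stop("duplicate genotype_id x trial rows: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Read QTL regions from a BED file
#'
#' BED is 0-based, half-open; internal coordinates are 1-based inclusive:
#' start_bp = bed_start + 1, end_bp = bed_end.
#'
#' @param bed_path path to a BED3+ file (optional 4th column = label).
#' @return list of \code{qtl_region}s.
#' @export
read_regions <- function(bed_path) {
  bed <- read.delim(bed_path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs >= 3 columns")
  lapply(seq_len(nrow(bed)), function(i) {
    s <- as.numeric(bed[i, 2]); e <- as.numeric(bed[i, 3])
    if (e < s) stop("BED line ", i, ": end < start")
    qtl_region(bed[i, 1], s + 1, e,
               label = if (ncol(bed) >= 4L) as.character(bed[i, 4])
                       else NA_character_)
  })
}

#' Write QTL regions as BED
#'
#' Inverse of \code{\link{read_regions}}: bed_start = start_bp - 1,
#' bed_end = end_bp.
#'
#' @param regions list of \code{qtl_region}s.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_regions <- function(regions, path) {
  lines <- vapply(regions, function(r)
    paste(r$chrom, format(r$start_bp - 1, scientific = FALSE),
          format(r$end_bp, scientific = FALSE),
          ifelse(is.na(r$label), ".", r$label), sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# stable hash of a config list (for output provenance headers); the
# output location is not part of the parameters and is excluded
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}
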