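pipeline_stage_names <- c("simulate", "encode", "scan-f2", "scan-f6",
                          "scan-dp", "kw-scan", "qtl-map", "haplotypes",
                          "sensory-model", "finemap")

stage_deps <- list(
  "simulate" = character(), "encode" = "simulate",
  "scan-f2" = "encode", "scan-f6" = "simulate", "scan-dp" = "simulate",
  "kw-scan" = "simulate", "qtl-map" = c("scan-f2"),
  "haplotypes" = "simulate", "sensory-model" = "simulate",
  "finemap" = c("encode", "scan-f2"))

#' Default pipeline configuration
#'
#' A small but complete run: a 12-chromosome map, the six half-diallel F2
#' crosses, one metabolite trait with a planted single-founder QTL, a
#' sensory attribute driven by that metabolite, and a germplasm panel.
#' Every effective parameter is echoed into the run manifest.
#'
#' @param seed global seed (mandatory for any stochastic stage).
#' @param out_dir output directory.
#' @param stages stages to run, in dependency order.
#' @return a config list for \code{\link{run_pipeline}}.
#' @export
default_pipeline_config <- function(seed, out_dir,
                                    stages = c("simulate", "encode",
                                               "scan-f2", "qtl-map",
                                               "haplotypes",
                                               "sensory-model")) {
  list(
    seed = seed, out_dir = out_dir, stages = stages,
    simulate = list(
      n_chrom = 12L, markers_per_chrom = 50L, chrom_length_bp = 60e6,
      diff_fraction = 0.4, generation = "F2", n_per_cross = 50L,
      rin_selection = FALSE, recomb_rate_cM_per_Mbp = 2,
      qtl = list(trait = "PHET", founder = "C085", effect = 1,
                 chrom = 4L, pos_frac = 0.5),
      baseline = 4, cross_background_sd = 0.5, residual_sd = 1,
      sensory = list(attribute = "a_fruity", weight = 1, noise_sd = 0.5)),
    haplotypes = list(n_accessions = 300L, founder_mixture = 0.6,
                      min_call = 0.8, max_missing = 0.23),
    scan = list(logp_threshold = 3.5, bin_size_bp = 5e6,
                min_informative_n = 10L),
    sensory_model = list(n_trees = 300L, n_permutations = 100L),
    finemap = list(flank_bp = 5e6))
}

validate_pipeline_config <- function(config) {
  required <- c("seed", "out_dir", "stages")
  miss <- required[vapply(required, function(f)
    is.null(config[[f]]) || length(config[[f]]) == 0L, TRUE)]
  if (length(miss)) stop("config lacks field(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
        !is.finite(config$seed))
    stop("config lacks field(s): seed (must be a single integer)")
  bad <- setdiff(config$stages, pipeline_stage_names)
  if (length(bad)) stop("unknown stage name(s): ",
                        paste(bad, collapse = ", "))
  for (st in config$stages) {
    need <- setdiff(stage_deps[[st]], config$stages)
    if (length(need)) stop("stage ", st, " requires stage(s): ",
                           paste(need, collapse = ", "))
  }
  ord <- match(config$stages, pipeline_stage_names)
  if (is.unsorted(ord)) stop("stages out of dependency order")
  invisible(TRUE)
}

stage_log <- function(stage, status, detail = "") {
  message(sprintf("[%s] %s %s", stage, status, detail))
}

#' Run the simulate/encode/scan/summarize pipeline
#'
#' Executes the configured stages in dependency order, writing every
#' output under \code{config$out_dir} with the config hash and seed in
#' file headers; a JSON manifest lists the produced files with checksums.
#' The configuration is validated (field presence, known stage names,
#' dependency order) before any stage runs, and a stage failure stops all
#' downstream stages.
#'
#' @param config a config list (see \code{\link{default_pipeline_config}})
#'   or the path to a YAML file holding one.
#' @return invisibly, the manifest list (also written to
#'   \code{manifest.json}); intermediate R objects are attached as
#'   attribute \code{state}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(default_pipeline_config(config$seed,
                                               config$out_dir,
                                               config$stages %||%
                                                 c("simulate")),
                       config)
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(config)
  seed <- config$seed
  st <- new.env(parent = emptyenv())
  files <- list()
  add_file <- function(path, what) {
    files[[length(files) + 1L]] <<- list(path = path, what = what,
                                         md5 = unname(tools::md5sum(path)))
  }
  out <- function(name) file.path(config$out_dir, name)

  for (stage in config$stages) {
    stage_log(stage, "start")
    if (stage == "simulate") {
      sc <- config$simulate
      st$founders <- make_founders(
        rep(sc$markers_per_chrom, sc$n_chrom),
        rep(sc$chrom_length_bp, sc$n_chrom),
        seed = seed, diff_fraction = sc$diff_fraction)
      st$pop <- simulate_population(
        st$founders,
        cross_plan(generation = sc$generation,
                   n_per_cross = sc$n_per_cross,
                   rin_selection = sc$rin_selection),
        recomb_rate_cM_per_Mbp = sc$recomb_rate_cM_per_Mbp,
        seed = seed + 1L)
      q <- sc$qtl
      chrom_id <- sprintf("ch%02d", q$chrom)
      idx <- which(st$founders$map$chrom == chrom_id)
      qmk <- st$founders$map$marker[idx[ceiling(length(idx) * q$pos_frac)]]
      st$qtl_marker <- qmk
      effects <- setNames(as.list(rep(0, 4)), st$founders$founder_ids)
      effects[[q$founder]] <- q$effect
      st$arch <- trait_architecture(list(trait_spec(
        q$trait, type = "metabolite", baseline = sc$baseline,
        qtls = do.call(data.frame, c(list(marker = qmk), effects)),
        cross_background_sd = sc$cross_background_sd,
        residual_sd = sc$residual_sd)))
      st$traits <- simulate_traits(st$pop, st$arch, seed = seed + 2L)
      sn <- sc$sensory
      st$traits <- simulate_sensory(
        st$traits,
        sensory_map(setNames(list(list(
          weights = setNames(sn$weight, q$trait),
          noise_sd = sn$noise_sd)), sn$attribute)),
        seed = seed + 3L)
      g <- genotype_dosage(st$pop)
      write_vcf(g, st$founders$map, out("genotypes.vcf"), seed = seed,
                config_hash = chash)
      write_trait_table(st$traits, out("traits.tsv"), seed = seed,
                        config_hash = chash)
      write.table(st$founders$map, out("marker_map.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(qtl_marker = qmk, trait = q$trait, founder = q$founder,
             effect = q$effect, seed = seed, config = chash),
        out("truth.json"), auto_unbox = TRUE, pretty = TRUE)
      add_file(out("genotypes.vcf"), "VCF genotypes")
      add_file(out("traits.tsv"), "trait table")
      add_file(out("marker_map.tsv"), "marker map")
      add_file(out("truth.json"), "simulation truth")
      stage_log(stage, "done",
                sprintf("(%d individuals, %d markers)",
                        length(st$pop$ids), nrow(st$founders$map)))
    } else if (stage == "encode") {
      st$M <- encode_parental_dosage(st$pop)
      st$rin <- build_rin_design(st$pop)
      df <- data.frame(marker = rep(st$M$map$marker,
                                    each = length(st$M$ids)),
                       individual = rep(st$M$ids, nrow(st$M$map)),
                       do.call(cbind, lapply(1:4, function(f)
                         as.vector(st$M$counts[, , f]))),
                       informative = as.vector(st$M$valid))
      names(df)[3:6] <- st$M$founder_ids
      write_trait_table(df, out("parental_dosage.tsv"), seed = seed,
                        config_hash = chash)
      add_file(out("parental_dosage.tsv"), "parental dosage")
      stage_log(stage, "done", sprintf("(%d masked)", st$M$n_masked))
    } else if (stage %in% c("scan-f2", "scan-f6", "scan-dp", "kw-scan")) {
      cfg <- scan_config(logp_threshold = config$scan$logp_threshold,
                         bin_size_bp = config$scan$bin_size_bp,
                         min_informative_n = config$scan$min_informative_n)
      tcol <- config$simulate$qtl$trait
      res <- switch(stage,
        "scan-f2" = scan_f2(preprocess_profiles(st$traits,
                                                compounds = tcol),
                            st$M, st$rin, cfg, trait_cols = tcol),
        "scan-f6" = scan_f6(preprocess_profiles(st$traits,
                                                compounds = tcol),
                            genotype_dosage(st$pop), st$founders$map, cfg,
                            trait_cols = tcol),
        "scan-dp" = scan_dp(preprocess_profiles(st$traits,
                                                compounds = tcol),
                            genotype_dosage(st$pop), st$founders$map, cfg,
                            trait_cols = tcol),
        "kw-scan" = {
          g <- genotype_dosage(st$pop)
          y <- preprocess_profiles(st$traits, compounds = tcol)[[tcol]]
          do.call(rbind, lapply(seq_len(nrow(st$founders$map)), function(j) {
            if (length(unique(g[, j])) < 2L) return(NULL)
            r <- kruskal_wallis_assoc(y, g[, j], trait = tcol,
                                      marker = st$founders$map$marker[j])
            r$chrom <- st$founders$map$chrom[j]
            r$pos_bp <- st$founders$map$pos_bp[j]
            r
          }))
        })
      st[[paste0("res_", gsub("-", "_", stage))]] <- res
      fn <- out(paste0(gsub("-", "_", stage), "_results.tsv"))
      write_trait_table(res, fn, seed = seed, config_hash = chash)
      add_file(fn, paste(stage, "association results"))
      stage_log(stage, "done", sprintf("(%d rows)", nrow(res)))
    } else if (stage == "qtl-map") {
      cfg <- scan_config(logp_threshold = config$scan$logp_threshold,
                         bin_size_bp = config$scan$bin_size_bp)
      qm <- summarize_qtl_map(st$res_scan_f2, cfg)
      st$qtl_map <- qm
      write_trait_table(qm, out("qtl_map.tsv"), seed = seed,
                        config_hash = chash)
      if (nrow(qm) > 0) {
        regs <- lapply(seq_len(nrow(qm)), function(i)
          qtl_region(qm$chrom[i], qm$bin_start_bp[i] + 1, qm$bin_end_bp[i],
                     label = qm$trait[i]))
        write_regions(regs, out("qtl_map.bed"))
        add_file(out("qtl_map.bed"), "QTL bins (BED)")
      }
      add_file(out("qtl_map.tsv"), "binned QTL map")
      stage_log(stage, "done", sprintf("(%d bins)", nrow(qm)))
    } else if (stage == "haplotypes") {
      hc <- config$haplotypes
      regions <- list(qtl_region(st$founders$map$chrom[
        match(st$qtl_marker, st$founders$map$marker)],
        max(1, st$founders$map$pos_bp[
          match(st$qtl_marker, st$founders$map$marker)] - 2.5e6),
        st$founders$map$pos_bp[
          match(st$qtl_marker, st$founders$map$marker)] + 2.5e6,
        label = "qtl_region"))
      panel <- simulate_germplasm(st$founders, regions,
                                  founder_mixture = hc$founder_mixture,
                                  n_accessions = hc$n_accessions,
                                  seed = seed + 4L)
      G <- filter_markers(panel$genotypes, hc$max_missing)
      keep <- colnames(G)
      ht <- call_region_haplotypes(G,
                                   st$founders$map[
                                     st$founders$map$marker %in% keep, ],
                                   regions, st$founders,
                                   min_call = hc$min_call)
      fr <- representation_frequencies(ht)
      st$hap_freq <- fr
      write_trait_table(fr$per_region, out("haplotype_frequencies.tsv"),
                        seed = seed, config_hash = chash)
      add_file(out("haplotype_frequencies.tsv"), "haplotype frequencies")
      stage_log(stage, "done",
                sprintf("(median %.1f%%)", fr$median_pct))
    } else if (stage == "sensory-model") {
      sm <- config$sensory_model
      tcol <- config$simulate$qtl$trait
      attr_col <- config$simulate$sensory$attribute
      pre <- preprocess_profiles(st$traits, compounds = tcol)
      rf <- rf_sensory_model(pre[[attr_col]],
                             as.matrix(pre[tcol]),
                             n_trees = sm$n_trees,
                             n_permutations = sm$n_permutations,
                             seed = seed + 5L)
      st$rf <- rf
      write_trait_table(rf$importance, out("sensory_importance.tsv"),
                        seed = seed, config_hash = chash)
      add_file(out("sensory_importance.tsv"), "sensory importances")
      stage_log(stage, "done",
                sprintf("(var explained %.2f)", rf$var_explained))
    } else if (stage == "finemap") {
      fmc <- config$finemap
      j <- match(st$qtl_marker, st$founders$map$marker)
      region <- qtl_region(st$founders$map$chrom[j],
                           max(1, st$founders$map$pos_bp[j] - fmc$flank_bp),
                           st$founders$map$pos_bp[j] + fmc$flank_bp,
                           label = "finemap_target")
      ridx <- markers_in_region(st$founders$map, region)
      eligible <- rownames(st$M$informative)[
        rowSums(st$M$informative[, ridx, drop = FALSE]) >= 2L]
      eligible <- intersect(eligible, unique(st$pop$cross))
      if (length(eligible) == 0L)
        stop("finemap: no cross with >= 2 informative region markers")
      rec <- find_recombinants(st$pop, region, M = st$M,
                               crosses = eligible)
      st$recombinants <- rec
      write_trait_table(rec, out("recombinants.tsv"), seed = seed,
                        config_hash = chash)
      add_file(out("recombinants.tsv"), "region recombinants")
      stage_log(stage, "done", sprintf("(%d breakpoints)", nrow(rec)))
    }
  }
  manifest <- list(config = config, config_hash = chash,
                   package_version =
                     as.character(packageVersion("diallelQTL")),
                   files = files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  attr(manifest, "state") <- st
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
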