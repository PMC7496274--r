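#' Define the generative architecture of one trait
#'
#' The generative model mirrors the association model used downstream: a
#' trait value is baseline + founder-allelic QTL effects + rin effects
#' (additive and dominance, in carrier crosses only) + a per-genotype
#' cross-background draw + a per-observation residual. Traits of type
#' "metabolite" are exponentiated (base 2) onto a positive abundance scale
#' and multiplied by a per-trial batch factor, so that log2 transformation
#' and trial-mean centering remove the batch effect exactly.
#'
#' @param name trait (column) name.
#' @param type "linear" (left on the additive scale), "metabolite"
#'   (2^value times trial factor) or "score" (additive, for sensory-like
#'   traits).
#' @param baseline intercept on the additive scale.
#' @param qtls data frame with column \code{marker} and one effect column
#'   per founder (effects in trait-SD units per inherited allele), or NULL.
#' @param rin_a,rin_d additive and dominance rin effects (additive code is
#'   mutant dosage - 1, dominance code is the heterozygote indicator).
#' @param cross_background_sd per-genotype background SD; scalar or named
#'   per cross.
#' @param residual_sd per-observation residual SD.
#' @return a \code{trait_spec} list.
#' @export
trait_spec <- function(name, type = c("linear", "metabolite", "score"),
                       baseline = 0, qtls = NULL, rin_a = 0, rin_d = 0,
                       cross_background_sd = 0, residual_sd = 0) {
  type <- match.arg(type)
  if (!is.null(qtls)) stopifnot(is.data.frame(qtls), "marker" %in% names(qtls))
  if (any(cross_background_sd < 0) || any(residual_sd < 0))
    stop("SDs must be >= 0")
  structure(list(name = name, type = type, baseline = baseline, qtls = qtls,
                 rin_a = rin_a, rin_d = rin_d,
                 cross_background_sd = cross_background_sd,
                 residual_sd = residual_sd), class = "trait_spec")
}

#' Bundle trait specs and trial batch factors
#'
#' @param traits list of \code{trait_spec}s.
#' @param trial_factors named positive multiplicative batch factors, one
#'   per trial (applied to metabolite traits on the abundance scale).
#' @return a \code{trait_architecture}.
#' @export
trait_architecture <- function(traits, trial_factors = c(T1 = 1)) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (any(trial_factors <= 0)) stop("trial factors must be > 0")
  nm <- vapply(traits, function(t) t$name, "")
  if (anyDuplicated(nm)) stop("duplicate trait names")
  structure(list(traits = setNames(traits, nm),
                 trial_factors = trial_factors),
            class = "trait_architecture")
}

# count of alleles inherited from each founder at one marker (truth)
founder_counts_at <- function(pop, marker) {
  j <- match(marker, pop$founders$map$marker)
  if (is.na(j)) stop("QTL marker absent from map: ", marker)
  vapply(seq_along(pop$founders$founder_ids), function(f)
    (pop$origins1[, j] == f) + (pop$origins2[, j] == f),
    numeric(length(pop$ids)))
}

#' Simulate trait values for a population
#'
#' One row per individual per replicate; replicates share the genetic and
#' background terms of their genotype and differ in the residual draw.
#' Each replicate is assigned to one trial (recycled over
#' \code{names(arch$trial_factors)} unless \code{trials} is given).
#'
#' @param pop a \code{population}.
#' @param arch a \code{trait_architecture}.
#' @param seed integer seed.
#' @param replicates observations per genotype.
#' @param trials optional trial label per replicate.
#' @return a trait table: data frame with genotype_id, cross, trial,
#'   generation, fruit_type and one numeric column per trait.
#' @export
simulate_traits <- function(pop, arch, seed = 1L, replicates = 1L,
                            trials = NULL) {
  stopifnot(inherits(pop, "population"), inherits(arch, "trait_architecture"))
  set.seed(seed)
  n <- length(pop$ids)
  if (is.null(trials)) {
    tf <- names(arch$trial_factors)
    trials <- tf[((seq_len(replicates) - 1L) %% length(tf)) + 1L]
  }
  stopifnot(length(trials) == replicates,
            all(trials %in% names(arch$trial_factors)))
  rin_dos <- rin_dosage_truth(pop)
  carrier_crosses <- names(pop$crosses)[vapply(pop$crosses, function(p)
    pop$founders$rin_carrier %in% p, TRUE)]
  in_carrier <- pop$cross %in% carrier_crosses

  type_of_parents <- function(p) {
    tp <- pop$founders$fruit_type[p]
    if (all(tp == "cherry")) "cherry" else if (all(tp == "round")) "round"
    else "cherry_x_round"
  }
  ctype <- vapply(pop$crosses, type_of_parents, "")
  out <- data.frame(
    genotype_id = rep(pop$ids, replicates),
    cross = rep(pop$cross, replicates),
    trial = rep(trials, each = n),
    generation = pop$generation,
    fruit_type = rep(unname(ctype[pop$cross]), replicates),
    replicate = rep(seq_len(replicates), each = n),
    stringsAsFactors = FALSE)

  for (ts in arch$traits) {
    g <- rep(ts$baseline, n)
    if (!is.null(ts$qtls)) {
      eff_cols <- intersect(pop$founders$founder_ids, names(ts$qtls))
      for (q in seq_len(nrow(ts$qtls))) {
        cnt <- founder_counts_at(pop, ts$qtls$marker[q])
        for (f in eff_cols) {
          fi <- match(f, pop$founders$founder_ids)
          g <- g + ts$qtls[[f]][q] * cnt[, fi]
        }
      }
    }
    if (ts$rin_a != 0 || ts$rin_d != 0) {
      a_code <- ifelse(in_carrier, rin_dos - 1, 0)
      d_code <- ifelse(in_carrier & rin_dos == 1L, 1, 0)
      g <- g + ts$rin_a * a_code + ts$rin_d * d_code
    }
    bg_sd <- ts$cross_background_sd
    if (length(bg_sd) > 1L) {
      miss <- setdiff(unique(pop$cross), names(bg_sd))
      if (length(miss)) stop("no background SD for cross(es): ",
                             paste(miss, collapse = ", "))
      bg_sd <- unname(bg_sd[pop$cross])
    }
    g <- g + rnorm(n, 0, bg_sd)
    vals <- rep(g, replicates) +
      rnorm(n * replicates, 0, ts$residual_sd)
    if (ts$type == "metabolite") {
      vals <- 2^vals * unname(arch$trial_factors[out$trial])
    }
    out[[ts$name]] <- vals
  }
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Map metabolite abundances to sensory attributes
#'
#' @param attributes named list; each element has \code{weights} (a named,
#'   signed vector over compound columns), \code{noise_sd} and optionally
#'   \code{link}, a monotone function applied to the weighted sum.
#' @return a \code{sensory_map}.
#' @export
sensory_map <- function(attributes) {
  for (a in attributes) {
    if (is.null(a$weights) || length(a$weights) == 0L)
      stop("each attribute needs at least one weight")
  }
  structure(list(attributes = attributes), class = "sensory_map")
}

#' Simulate sensory attributes from compound abundances
#'
#' Attribute = link(sum of weights times log2 abundance) + Gaussian noise,
#' appended to the trait table as new columns.
#'
#' @param traits a trait table holding the weighted compound columns.
#' @param smap a \code{sensory_map}.
#' @param seed integer seed.
#' @return the trait table with attribute columns appended.
#' @export
simulate_sensory <- function(traits, smap, seed = 1L) {
  stopifnot(inherits(smap, "sensory_map"))
  set.seed(seed)
  for (nm in names(smap$attributes)) {
    a <- smap$attributes[[nm]]
    miss <- setdiff(names(a$weights), names(traits))
    if (length(miss)) stop("missing compound column(s): ",
                           paste(miss, collapse = ", "))
    s <- rep(0, nrow(traits))
    for (cmp in names(a$weights))
      s <- s + a$weights[[cmp]] * log2(traits[[cmp]])
    if (!is.null(a$link)) s <- a$link(s)
    noise <- if (is.null(a$noise_sd)) 0 else a$noise_sd
    traits[[nm]] <- s + rnorm(nrow(traits), 0, noise)
  }
  traits
}

#' Genotype means of a trait table
#'
#' Unweighted means over non-missing replicates, computed per genotype
#' within trial (or across trials when \code{by_trial = FALSE}); metadata
#' columns are carried along.
#'
#' @param traits a trait table.
#' @param trait_cols columns to average; default: all numeric non-metadata.
#' @param by_trial keep trials separate (default TRUE).
#' @return aggregated trait table, one row per genotype (x trial).
#' @export
genotype_means <- function(traits, trait_cols = NULL, by_trial = TRUE) {
  meta <- c("genotype_id", "cross", "trial", "generation", "fruit_type",
            "replicate")
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                          meta)
  keys <- if (by_trial && "trial" %in% names(traits))
    traits[c("genotype_id", "trial")] else traits["genotype_id"]
  agg <- aggregate(traits[trait_cols], by = keys,
                   FUN = function(x) mean(x, na.rm = TRUE))
  agg[trait_cols] <- lapply(agg[trait_cols], function(x) {
    x[is.nan(x)] <- NA_real_
    x
  })
  first <- !duplicated(do.call(paste, c(keys, sep = "\r")))
  carry <- intersect(setdiff(meta, c(names(keys), "replicate")), names(traits))
  agg <- merge(cbind(keys, traits[carry])[first, , drop = FALSE], agg,
               by = names(keys), sort = FALSE)
  agg <- agg[order(match(agg$genotype_id, unique(traits$genotype_id))), ,
             drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("trait_table", "data.frame")
  agg
}
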