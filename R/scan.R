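#' Scan configuration
#'
#' @param logp_threshold Log P significance threshold (default 3.5).
#' @param bin_size_bp QTL-map bin width in bp (default 5 Mbp).
#' @param min_informative_n minimum non-missing, informative observations
#'   for a marker (or trait) to be tested.
#' @param aggregate average replicated observations to genotype means
#'   before scanning (default TRUE).
#' @param type_levels diversity-panel fruit-type coding: "two" (cherry vs
#'   round/beef) or "three".
#' @return a \code{scan_config} list.
#' @export
scan_config <- function(logp_threshold = 3.5, bin_size_bp = 5e6,
                        min_informative_n = 10L, aggregate = TRUE,
                        type_levels = c("two", "three")) {
  if (logp_threshold <= 0) stop("threshold must be > 0")
  if (bin_size_bp <= 0) stop("bin size must be > 0")
  structure(list(logp_threshold = logp_threshold, bin_size_bp = bin_size_bp,
                 min_informative_n = as.integer(min_informative_n),
                 aggregate = isTRUE(aggregate),
                 type_levels = match.arg(type_levels)),
            class = "scan_config")
}

empty_assoc <- function() {
  data.frame(trait = character(), marker = character(), chrom = character(),
             pos_bp = numeric(), model = character(), effect = numeric(),
             se = numeric(), statistic = numeric(), df = numeric(),
             P = numeric(), logP = numeric(), r2 = numeric(),
             n_effective = integer(), cross = character(),
             note = character(), stringsAsFactors = FALSE)
}

assoc_row <- function(trait, marker, chrom, pos_bp, model, effect = NA_real_,
                      se = NA_real_, statistic = NA_real_, df = NA_real_,
                      P = NA_real_, r2 = NA_real_, n_effective = NA_integer_,
                      cross = NA_character_, note = NA_character_) {
  data.frame(trait = trait, marker = marker, chrom = chrom, pos_bp = pos_bp,
             model = model, effect = effect, se = se, statistic = statistic,
             df = df, P = P, logP = ifelse(is.na(P), NA_real_, logp(P)),
             r2 = r2, n_effective = n_effective, cross = cross, note = note,
             stringsAsFactors = FALSE)
}

# sum-to-zero contrast basis for the four founder columns
founder_contrast_basis <- function(type = c("sum", "helmert")) {
  type <- match.arg(type)
  K <- if (type == "sum") stats::contr.sum(4) else stats::contr.helmert(4)
  rownames(K) <- NULL
  K
}

#' F2 half-diallel mixed-model genome scan
#'
#' Fits, for every marker and trait, the mixed model
#' y = cross.genotype + rin + marker + error on all crosses simultaneously:
#' a random genotype effect with a per-cross REML variance component, the
#' rin nuisance design, and the four parental allele-count columns as the
#' fixed marker term. The genetic-background correction includes fixed
#' per-cross intercepts, so founder marker effects are identified from
#' within-cross segregation; without them, cross-mean differences caused
#' by any real QTL would leak into every marker's founder columns through
#' the between-cross information and de-localize the scan. The parental columns sum rowwise to 2 and are entered
#' under a sum-to-zero constraint; the marker term is tested by a Wald
#' statistic on its estimable subspace, with degrees of freedom equal to
#' its rank (at most 3). On genotype means the coefficient covariance is
#' given the Kackar-Harville correction for estimated per-cross variances
#' and the Wald statistic is referred to a Kenward-Roger F approximation
#' with estimated denominator df (reducing to the chi-square reference as
#' the denominator df grow). Traits are
#' aggregated to genotype means first when replicated. Markers informative
#' in no cross are skipped with a reason; individuals from crosses where
#' the marker is uninformative are excluded marker-wise and the effective
#' sample size reported.
#'
#' @param traits trait table (rows matching the encoded population's
#'   individuals via genotype_id).
#' @param M a \code{parental_dosage} from
#'   \code{\link{encode_parental_dosage}}.
#' @param rin a \code{rin_design}, or NULL to omit the correction.
#' @param config a \code{scan_config}.
#' @param trait_cols traits to scan (default: all numeric non-metadata).
#' @param markers subset of marker ids to test (default: all).
#' @param contrast_type constraint basis for the founder effects
#'   ("sum" or "helmert"; the Wald statistic is invariant to the choice).
#' @return association results, one row per trait x tested marker, with
#'   per-founder effect estimates and standard errors attached as
#'   attribute \code{founder_effects}.
#' @export
scan_f2 <- function(traits, M, rin = NULL, config = scan_config(),
                    trait_cols = NULL, markers = NULL,
                    contrast_type = "sum") {
  stopifnot(inherits(M, "parental_dosage"))
  meta <- c("genotype_id", "cross", "trial", "generation", "fruit_type",
            "replicate")
  if (config$aggregate && anyDuplicated(traits$genotype_id))
    traits <- genotype_means(traits, trait_cols, by_trial = FALSE)
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                          meta)
  idx <- match(M$ids, traits$genotype_id)
  if (anyNA(idx)) stop("trait table lacks genotype(s): ",
                       paste(utils::head(M$ids[is.na(idx)], 5), collapse = ", "))
  traits <- traits[idx, , drop = FALSE]
  if (is.null(markers)) markers <- M$map$marker
  K <- founder_contrast_basis(contrast_type)
  rinX <- if (is.null(rin)) NULL else rin$X

  out <- vector("list", length(trait_cols) * length(markers))
  founder_eff <- vector("list", length(out))
  k_out <- 0L

  # fixed per-cross intercepts: the genetic-background correction must
  # absorb cross-mean differences (else a QTL anywhere leaks into every
  # marker's founder columns through the between-cross information), so
  # founder marker effects are identified from within-cross segregation
  cross_f <- factor(M$cross)
  crossX <- stats::model.matrix(~ 0 + cross_f)
  colnames(crossX) <- paste0("cross_", levels(cross_f))

  for (tr in trait_cols) {
    y_all <- traits[[tr]]
    if (sum(!is.na(y_all)) < config$min_informative_n) next
    # starting values from the null-model fit, reused across markers
    X0 <- cbind(crossX, rinX)
    fit0 <- tryCatch(
      fit_reml_halfdiallel(y_all, X0, M$cross, M$ids),
      error = function(e) NULL)
    init <- if (is.null(fit0)) NULL else
      list(sigma2_g = fit0$vc$total, sigma2_e = fit0$vc$sigma2_e)

    for (mk in markers) {
      j <- match(mk, M$map$marker)
      k_out <- k_out + 1L
      inf_crosses <- rownames(M$informative)[M$informative[, j]]
      keep <- M$cross %in% inf_crosses & M$valid[, j] & !is.na(y_all)
      n_eff <- sum(keep)
      if (length(inf_crosses) == 0L) {
        out[[k_out]] <- assoc_row(tr, mk, M$map$chrom[j], M$map$pos_bp[j],
                                  "F2-diallel", n_effective = 0L,
                                  note = "uninformative in all crosses")
        next
      }
      if (n_eff < config$min_informative_n) {
        out[[k_out]] <- assoc_row(tr, mk, M$map$chrom[j], M$map$pos_bp[j],
                                  "F2-diallel", n_effective = n_eff,
                                  note = "too few informative observations")
        next
      }
      D <- M$counts[keep, j, , drop = TRUE]
      Mk <- D %*% K
      colnames(Mk) <- paste0("mk", seq_len(ncol(Mk)))
      X <- cbind(crossX[keep, , drop = FALSE],
                 if (is.null(rinX)) NULL else rinX[keep, , drop = FALSE],
                 Mk)
      marker_cols <- (ncol(X) - ncol(Mk) + 1L):ncol(X)
      fit <- tryCatch(
        fit_reml_halfdiallel(y_all[keep], X, M$cross[keep], M$ids[keep],
                             init = init),
        error = function(e) NULL)
      if (is.null(fit)) {
        out[[k_out]] <- assoc_row(tr, mk, M$map$chrom[j], M$map$pos_bp[j],
                                  "F2-diallel", n_effective = n_eff,
                                  note = "fit failed")
        next
      }
      w <- wald_block_kr(fit, marker_cols)
      if (w$df == 0L) {
        out[[k_out]] <- assoc_row(tr, mk, M$map$chrom[j], M$map$pos_bp[j],
                                  "F2-diallel", n_effective = n_eff,
                                  note = "marker term inestimable")
        next
      }
      # map constrained coefficients back to per-founder effects
      kept_mk <- fit$kept[fit$kept %in% marker_cols]
      b_mk <- fit$beta[kept_mk]
      Ck <- fit$cov_beta_adj[fit$kept %in% marker_cols,
                             fit$kept %in% marker_cols, drop = FALSE]
      Ksub <- K[, kept_mk - marker_cols[1L] + 1L, drop = FALSE]
      eff4 <- drop(Ksub %*% b_mk)
      se4 <- sqrt(pmax(diag(Ksub %*% Ck %*% t(Ksub)), 0))
      founder_eff[[k_out]] <- data.frame(
        trait = tr, marker = mk, founder = M$founder_ids,
        effect = eff4, se = se4, stringsAsFactors = FALSE)
      # explained variance: Wald-based approximation on genotype means
      r2 <- w$W / (w$W + n_eff)
      out[[k_out]] <- assoc_row(
        tr, mk, M$map$chrom[j], M$map$pos_bp[j], "F2-diallel",
        effect = max(abs(eff4)), se = se4[which.max(abs(eff4))],
        statistic = w$W, df = w$df, P = w$P, r2 = r2,
        n_effective = n_eff,
        cross = paste(inf_crosses, collapse = ";"),
        note = if (!fit$vc$converged) "REML not converged" else NA_character_)
    }
  }
  res <- do.call(rbind, c(list(empty_assoc()), out[!vapply(out, is.null, TRUE)]))
  rownames(res) <- NULL
  attr(res, "founder_effects") <-
    do.call(rbind, founder_eff[!vapply(founder_eff, is.null, TRUE)])
  res
}

#' Diversity-panel association scan
#'
#' Ordinary least squares of trait on fruit type plus marker dosage,
#' y = type + marker + error, with a two-sided t-test on the marker
#' coefficient. Fruit type is coded cherry vs round/beef by default.
#'
#' @param traits trait table with a \code{fruit_type} column.
#' @param G dosage matrix (individuals x markers), rows matching
#'   \code{traits$genotype_id} by name or position.
#' @param map \code{marker_map} for G's columns.
#' @param config a \code{scan_config}.
#' @param trait_cols traits to scan.
#' @return association results, one row per trait x marker.
#' @export
scan_dp <- function(traits, G, map, config = scan_config(),
                    trait_cols = NULL) {
  if (!"fruit_type" %in% names(traits)) stop("fruit_type column missing")
  meta <- c("genotype_id", "cross", "trial", "generation", "fruit_type",
            "replicate")
  if (config$aggregate && anyDuplicated(traits$genotype_id))
    traits <- genotype_means(traits, trait_cols, by_trial = FALSE)
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                          meta)
  if (!is.null(rownames(G))) {
    idx <- match(rownames(G), traits$genotype_id)
    if (anyNA(idx)) stop("trait table lacks genotype(s) present in G")
    traits <- traits[idx, , drop = FALSE]
  } else stopifnot(nrow(G) == nrow(traits))
  type <- if (config$type_levels == "two")
    factor(ifelse(traits$fruit_type == "cherry", "cherry", "round_beef"))
  else factor(traits$fruit_type)

  out <- vector("list", length(trait_cols) * nrow(map))
  k_out <- 0L
  for (tr in trait_cols) {
    y <- traits[[tr]]
    for (j in seq_len(nrow(map))) {
      k_out <- k_out + 1L
      g <- G[, j]
      ok <- !is.na(y) & !is.na(g)
      if (sum(ok) < config$min_informative_n) {
        out[[k_out]] <- assoc_row(tr, map$marker[j], map$chrom[j],
                                  map$pos_bp[j], "DP",
                                  n_effective = sum(ok),
                                  note = "too few observations")
        next
      }
      if (var(g[ok]) == 0) {
        out[[k_out]] <- assoc_row(tr, map$marker[j], map$chrom[j],
                                  map$pos_bp[j], "DP",
                                  n_effective = sum(ok),
                                  note = "monomorphic")
        next
      }
      dat <- data.frame(y = y[ok], type = droplevels(type[ok]), g = g[ok])
      fml <- if (nlevels(dat$type) > 1L) y ~ type + g else y ~ g
      fit <- lm(fml, data = dat)
      sm <- suppressWarnings(summary(fit))$coefficients
      row <- sm["g", , drop = FALSE]
      # partial R2 of the marker given type
      fit0 <- lm(stats::update(fml, . ~ . - g), data = dat)
      rss0 <- sum(fit0$residuals^2)
      rss1 <- sum(fit$residuals^2)
      out[[k_out]] <- assoc_row(
        tr, map$marker[j], map$chrom[j], map$pos_bp[j], "DP",
        effect = row[1, 1], se = row[1, 2], statistic = row[1, 3],
        df = fit$df.residual, P = row[1, 4],
        r2 = if (rss0 > 0) (rss0 - rss1) / rss0 else NA_real_,
        n_effective = sum(ok))
    }
  }
  res <- do.call(rbind, c(list(empty_assoc()), out[!vapply(out, is.null, TRUE)]))
  rownames(res) <- NULL
  res
}

#' Per-cross F6 RIL scans
#'
#' Simple regression y = marker + error fitted separately within each
#' cross (two-sided t-test on the marker slope); results from different
#' crosses are never pooled. Explained variance is the within-cross R
#' squared, the squared Pearson correlation of marker and trait.
#'
#' @param traits trait table with a \code{cross} column.
#' @param G dosage matrix, rows matching \code{traits$genotype_id}.
#' @param map \code{marker_map}.
#' @param config a \code{scan_config}.
#' @param trait_cols traits to scan.
#' @return association results, one row per cross x trait x marker.
#' @export
scan_f6 <- function(traits, G, map, config = scan_config(),
                    trait_cols = NULL) {
  if (!"cross" %in% names(traits)) stop("cross column missing")
  meta <- c("genotype_id", "cross", "trial", "generation", "fruit_type",
            "replicate")
  if (config$aggregate && anyDuplicated(traits$genotype_id))
    traits <- genotype_means(traits, trait_cols, by_trial = FALSE)
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                          meta)
  if (!is.null(rownames(G))) {
    idx <- match(rownames(G), traits$genotype_id)
    if (anyNA(idx)) stop("trait table lacks genotype(s) present in G")
    traits <- traits[idx, , drop = FALSE]
  } else stopifnot(nrow(G) == nrow(traits))

  out <- list()
  for (cl in unique(traits$cross)) {
    rows <- which(traits$cross == cl)
    for (tr in trait_cols) {
      y <- traits[[tr]][rows]
      for (j in seq_len(nrow(map))) {
        g <- G[rows, j]
        ok <- !is.na(y) & !is.na(g)
        if (sum(ok) < 3L) {
          out[[length(out) + 1L]] <-
            assoc_row(tr, map$marker[j], map$chrom[j], map$pos_bp[j],
                      "F6-cross", n_effective = sum(ok), cross = cl,
                      note = "fewer than 3 informative individuals")
          next
        }
        if (var(g[ok]) == 0) {
          out[[length(out) + 1L]] <-
            assoc_row(tr, map$marker[j], map$chrom[j], map$pos_bp[j],
                      "F6-cross", n_effective = sum(ok), cross = cl,
                      note = "monomorphic")
          next
        }
        fit <- lm(y[ok] ~ g[ok])
        sm <- suppressWarnings(summary(fit))
        row <- sm$coefficients
        if (nrow(row) < 2L) next
        out[[length(out) + 1L]] <- assoc_row(
          tr, map$marker[j], map$chrom[j], map$pos_bp[j], "F6-cross",
          effect = row[2, 1], se = row[2, 2], statistic = row[2, 3],
          df = fit$df.residual, P = row[2, 4], r2 = sm$r.squared,
          n_effective = sum(ok), cross = cl)
      }
    }
  }
  res <- do.call(rbind, c(list(empty_assoc()), out))
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis marker-trait association
#'
#' Rank-based H statistic with tie correction referred to a chi-square
#' with k - 1 degrees of freedom. All-tied input yields H = 0, P = 1.
#'
#' @param y numeric trait values.
#' @param classes genotype class per observation (>= 2 non-empty classes).
#' @param trait,marker optional labels carried into the result.
#' @return a one-row association result (model "KW").
#' @export
kruskal_wallis_assoc <- function(y, classes, trait = "trait",
                                 marker = "marker") {
  ok <- !is.na(y) & !is.na(classes)
  y <- y[ok]
  classes <- factor(classes[ok])
  classes <- droplevels(classes)
  if (nlevels(classes) < 2L)
    stop("Kruskal-Wallis needs at least two non-empty classes")
  if (length(unique(y)) == 1L) {
    H <- 0; df <- nlevels(classes) - 1L; P <- 1
  } else {
    kt <- kruskal.test(y, classes)
    H <- unname(kt$statistic); df <- unname(kt$parameter); P <- kt$p.value
  }
  assoc_row(trait, marker, NA_character_, NA_real_, "KW",
            statistic = H, df = df, P = P, n_effective = length(y))
}

#' Summarize association results into a binned QTL map
#'
#' Keeps associations with Log P strictly above the threshold, bins them
#' by physical position (floor(pos / bin_size)), and reports the maximum
#' Log P per trait x bin together with the crosses in which the signal was
#' seen.
#'
#' @param results association results from a scan.
#' @param config a \code{scan_config} (threshold and bin size).
#' @return data frame trait, chrom, bin_start_bp, bin_end_bp, max_logP,
#'   peak marker/position, contributing crosses, n_markers.
#' @export
summarize_qtl_map <- function(results, config = scan_config()) {
  keep <- !is.na(results$logP) & results$logP > config$logp_threshold &
    !is.na(results$pos_bp)
  res <- results[keep, , drop = FALSE]
  if (nrow(res) == 0L)
    return(data.frame(trait = character(), chrom = character(),
                      bin_start_bp = numeric(), bin_end_bp = numeric(),
                      max_logP = numeric(), peak_marker = character(),
                      peak_pos_bp = numeric(), crosses = character(),
                      n_markers = integer(), stringsAsFactors = FALSE))
  bin <- floor(res$pos_bp / config$bin_size_bp)
  key <- paste(res$trait, res$chrom, bin, sep = "\r")
  split_idx <- split(seq_len(nrow(res)), key)
  rows <- lapply(split_idx, function(ii) {
    sub <- res[ii, , drop = FALSE]
    top <- which.max(sub$logP)
    crosses <- sort(unique(unlist(strsplit(
      sub$cross[!is.na(sub$cross)], ";", fixed = TRUE))))
    data.frame(trait = sub$trait[1], chrom = sub$chrom[1],
               bin_start_bp = floor(sub$pos_bp[1] / config$bin_size_bp) *
                 config$bin_size_bp,
               bin_end_bp = (floor(sub$pos_bp[1] / config$bin_size_bp) + 1) *
                 config$bin_size_bp,
               max_logP = sub$logP[top], peak_marker = sub$marker[top],
               peak_pos_bp = sub$pos_bp[top],
               crosses = paste(crosses, collapse = ";"),
               n_markers = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$trait, out$chrom, out$bin_start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
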