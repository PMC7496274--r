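#' Preprocess metabolite abundance profiles
#'
#' Zeros are replaced by half the compound's minimum positive value, the
#' data are log2 ("2log") transformed, and each compound is centered by
#' its trial mean on the log scale (equivalent to dividing by the trial
#' geometric mean on the raw scale), which removes multiplicative batch
#' effects between trials exactly. A raw-scale alternative (division by
#' the arithmetic trial mean before the log) is available via
#' \code{center}.
#'
#' @param traits trait table with a \code{trial} column.
#' @param compounds compound columns to transform (default: all numeric
#'   non-metadata columns).
#' @param log_base logarithm base (default 2).
#' @param center "log-mean" (default) or "raw-mean".
#' @param log_transform apply the log step (default TRUE); with FALSE the
#'   input is taken as already log-scale and only trial centering is
#'   applied, which makes the centering step idempotent.
#' @return the trait table with transformed compound columns.
#' @export
preprocess_profiles <- function(traits, compounds = NULL, log_base = 2,
                                center = c("log-mean", "raw-mean"),
                                log_transform = TRUE) {
  center <- match.arg(center)
  if (log_base <= 1) stop("log base must be > 1")
  meta <- c("genotype_id", "cross", "trial", "generation", "fruit_type",
            "replicate")
  if (is.null(compounds))
    compounds <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                         meta)
  trial <- if ("trial" %in% names(traits)) traits$trial
           else rep("T1", nrow(traits))
  for (cmp in compounds) {
    x <- traits[[cmp]]
    if (log_transform) {
      if (any(x < 0, na.rm = TRUE))
        stop("negative abundance in compound ", cmp)
      pos_min <- suppressWarnings(min(x[x > 0], na.rm = TRUE))
      if (!is.finite(pos_min)) pos_min <- 1
      x[!is.na(x) & x == 0] <- pos_min / 2
    }
    if (center == "raw-mean" && log_transform) {
      tm <- tapply(x, trial, mean, na.rm = TRUE)
      x <- x / as.vector(tm[trial])
      x <- log(x, base = log_base)
    } else {
      if (log_transform) x <- log(x, base = log_base)
      tm <- tapply(x, trial, mean, na.rm = TRUE)
      x <- x - as.vector(tm[trial])
    }
    traits[[cmp]] <- as.vector(x)
  }
  traits
}

#' Principal component summary of a profile matrix
#'
#' Columns are mean-centered (missing cells mean-imputed per column
#' first); components come from the singular value decomposition of the
#' centered matrix. Loadings are orthonormal and scores reproduce the
#' centered data.
#'
#' @param x numeric matrix or data frame (rows = profiles).
#' @param n_components number of components to return (default: all).
#' @return list with \code{scores}, \code{loadings},
#'   \code{var_explained} (fraction per returned component) and
#'   \code{center}.
#' @export
pca_summary <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least a 2 x 2 matrix")
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  if (all(apply(x, 2L, var) == 0)) stop("constant matrix has no components")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- if (is.null(n_components)) length(p$sdev)
       else min(n_components, length(p$sdev))
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       var_explained = var_frac[seq_len(k)],
       center = p$center)
}

#' Random-forest sensory-attribute model with signed importance
#'
#' Regresses one sensory attribute on the preprocessed compound matrix
#' with a bootstrap ensemble of regression trees (out-of-bag tracking).
#' Importance of a compound is the increase in out-of-bag mean squared
#' error after permuting that compound's out-of-bag values
#' (\code{n_permutations} times per tree), standardized by the standard
#' deviation of the per-tree differences. The directionality (sign) of
#' each compound is the sign of its Pearson correlation with the
#' attribute.
#'
#' @param attribute numeric vector (n >= 30).
#' @param chemicals numeric matrix of compound values (same rows).
#' @param n_trees ensemble size (default 500).
#' @param n_permutations out-of-bag permutations per tree (default 500).
#' @param seed integer seed (the ensemble and importances are then
#'   reproducible).
#' @param mtry features tried per split; default floor(p / 3) as usual
#'   for regression forests.
#' @return list with \code{importance} (data frame: compound, importance,
#'   sign, pearson_r, ranked by importance) and \code{var_explained}
#'   (out-of-bag fraction of variance explained by the model).
#' @export
rf_sensory_model <- function(attribute, chemicals, n_trees = 500L,
                             n_permutations = 500L, seed = 1L,
                             mtry = NULL) {
  chemicals <- as.matrix(chemicals)
  if (length(attribute) != nrow(chemicals))
    stop("attribute and chemicals disagree in length")
  ok <- !is.na(attribute) & complete.cases(chemicals)
  attribute <- attribute[ok]
  chemicals <- chemicals[ok, , drop = FALSE]
  if (length(attribute) < 30L) stop("need n >= 30 observations")
  if (var(attribute) == 0) stop("attribute is constant")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (is.null(colnames(chemicals)))
    colnames(chemicals) <- paste0("cmp", seq_len(ncol(chemicals)))
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(chemicals) / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = chemicals, y = attribute, ntree = n_trees, mtry = mtry,
    importance = TRUE, nPerm = n_permutations, keep.forest = FALSE)
  imp <- randomForest::importance(rf, type = 1L, scale = TRUE)[, 1L]
  r <- apply(chemicals, 2L, cor, y = attribute,
             use = "pairwise.complete.obs")
  tab <- data.frame(compound = colnames(chemicals),
                    importance = unname(imp),
                    sign = ifelse(r >= 0, "+", "-"),
                    pearson_r = unname(r), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance), , drop = FALSE]
  rownames(tab) <- NULL
  list(importance = tab,
       var_explained = rf$rsq[length(rf$rsq)])
}
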