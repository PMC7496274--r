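# Restricted maximum likelihood for the half-diallel mixed model
#
#   y = X beta + g + e,   g_i ~ N(0, sigma2_g[cross(i)]),  e ~ N(0, sigma2_e I)
#
# with one random genotype effect per genotype whose variance depends on
# the genotype's cross. V is block diagonal by genotype (compound symmetry
# within genotype); each block splits into its within-block deviation
# space (eigenvalue sigma2_e) and mean direction (sigma2_e + r sigma2_g),
# which gives cancellation-free closed forms for all REML pieces. With a
# single observation per genotype, sigma2_g and sigma2_e are jointly
# unidentifiable and the model collapses to per-cross total variances
# (heteroscedastic GLS), recorded by the collapsed flag.

# REML pieces for the replicated (non-collapsed) model.
# sX = block sums of X, sy = block sums of y, computed by rowsum();
# reps, geno_cross align with the block order of rowsum (sorted index).
reml_pieces <- function(y, X, geno_index, geno_cross, reps, sg, se) {
  sg_b <- sg[geno_cross]
  lam <- se + reps * sg_b                     # mean-direction eigenvalue
  sy <- rowsum(y, geno_index, reorder = TRUE)
  sX <- rowsum(X, geno_index, reorder = TRUE)
  mean_w <- 1 / (reps * lam) - 1 / (reps * se)  # weight shift for means
  XtViX <- crossprod(X) / se + crossprod(sX, sX * mean_w)
  XtViy <- crossprod(X, y) / se + crossprod(sX, sy * mean_w)
  ytViy <- sum(y^2) / se + sum(mean_w * sy^2)
  logdetV <- sum((reps - 1) * log(se) + log(lam))
  list(XtViX = XtViX, XtViy = XtViy, ytViy = ytViy, logdetV = logdetV)
}

# minus twice the restricted log-likelihood, replicated case
reml_deviance_full <- function(theta, y, X, geno_index, geno_cross, reps,
                               n_cross) {
  if (any(theta[seq_len(n_cross)] < 0) || theta[n_cross + 1L] <= 0)
    return(1e10)
  sg <- theta[seq_len(n_cross)]
  se <- theta[n_cross + 1L]
  p <- reml_pieces(y, X, geno_index, geno_cross, reps, sg, se)
  R <- tryCatch(chol(p$XtViX), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  b <- backsolve(R, forwardsolve(t(R), p$XtViy))
  yPy <- p$ytViy - sum(p$XtViy * b)
  p$logdetV + 2 * sum(log(diag(R))) + yPy
}

# Collapsed case: one observation per genotype, V = diag(v[cross]).
# Deviance and its analytic gradient share the weighted QR; the gradient
# uses the envelope theorem (the GLS fit minimizes the weighted RSS).
reml_collapsed_eval <- function(v, y, X, cross_index, n_per_cross) {
  w <- 1 / v[cross_index]
  sw <- sqrt(w)
  qq <- qr(X * sw)
  R <- qr.R(qq)
  d <- abs(diag(R))
  if (any(d < max(d) * 1e-12)) return(list(dev = 1e10))
  e_w <- qr.resid(qq, y * sw)                 # weighted residuals
  rss <- sum(e_w^2)
  dev <- sum(n_per_cross * log(v)) + 2 * sum(log(d)) + rss
  # leverages of the weighted design: h_i = x_wi' (Xw'Xw)^-1 x_wi
  Qm <- qr.Q(qq)
  h <- rowSums(Qm^2)
  # d/dv_c: n_c/v_c - sum_c(h_i)/v_c - sum_c(e_wi^2)/v_c
  grad <- (n_per_cross - rowsum(h + e_w^2, cross_index, reorder = TRUE)[, 1]) /
    v
  list(dev = dev, grad = grad, rss = rss)
}

#' Fit the half-diallel mixed model by REML
#'
#' Estimates per-cross genetic variance components and a residual variance
#' by restricted maximum likelihood (bounded quasi-Newton, L-BFGS-B, over
#' the non-negative component scale; analytic gradient in the collapsed
#' case, finite differences otherwise), then computes fixed effects by
#' generalized least squares at the optimum. Rank-deficient fixed-effect
#' designs are reduced to an estimable column basis by pivoted QR; dropped
#' columns are reported with NA coefficients, mirroring \code{lm}.
#'
#' When every genotype has a single observation, the per-cross genetic and
#' residual variances are jointly unidentifiable; the model then collapses
#' to per-cross total variances (heteroscedastic GLS), flagged via
#' \code{collapsed} (sigma2_g and sigma2_e are NA, \code{total} holds the
#' identifiable per-cross sums).
#'
#' @param y numeric response vector (one trait).
#' @param X fixed-effect design matrix (including intercept).
#' @param cross cross label per observation.
#' @param genotype genotype id per observation.
#' @param init optional list(sigma2_g, sigma2_e) of starting values
#'   (sigma2_g named by cross; in the collapsed case these are totals).
#' @param max_iter L-BFGS-B iteration cap.
#' @return list with \code{vc} (sigma2_g per cross, sigma2_e, per-cross
#'   \code{total}, collapsed and convergence flags, restricted
#'   log-likelihood), \code{beta} (named, NA for inestimable columns),
#'   \code{cov_beta} (estimable block), \code{kept} (estimable column
#'   indices), \code{rank}, \code{n}.
#' @export
fit_reml_halfdiallel <- function(y, X, cross, genotype, init = NULL,
                                 max_iter = 200L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(cross) == length(y),
            length(genotype) == length(y))
  keep_obs <- !is.na(y)
  y <- y[keep_obs]
  X <- X[keep_obs, , drop = FALSE]
  cross <- as.character(cross)[keep_obs]
  genotype <- as.character(genotype)[keep_obs]
  n <- length(y)
  if (n < 3L) stop("too few non-missing observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  qx <- qr(X)
  rank <- qx$rank
  kept <- sort(qx$pivot[seq_len(rank)])
  Xr <- X[, kept, drop = FALSE]

  geno_f <- factor(genotype, levels = unique(genotype))
  geno_index <- as.integer(geno_f)
  reps_tab <- tabulate(geno_index)
  geno_cross <- match(cross[!duplicated(geno_index)], sort(unique(cross)))
  cross_levels <- sort(unique(cross))
  n_cross <- length(cross_levels)
  collapsed <- all(reps_tab == 1L)
  vy <- var(y)

  if (is.na(vy) || vy == 0) {
    beta_r <- qr.coef(qr(Xr), y)
    beta <- setNames(rep(NA_real_, ncol(X)), colnames(X))
    beta[kept] <- beta_r
    return(list(vc = list(sigma2_g = setNames(rep(0, n_cross), cross_levels),
                          sigma2_e = 0,
                          total = setNames(rep(0, n_cross), cross_levels),
                          collapsed = collapsed, converged = TRUE,
                          loglik = NA_real_),
                beta = beta,
                cov_beta = matrix(0, rank, rank,
                                  dimnames = list(colnames(Xr), colnames(Xr))),
                kept = kept, rank = rank, n = n,
                cross_levels = cross_levels))
  }
  lower_v <- vy * 1e-8

  if (collapsed) {
    cross_index <- match(cross, cross_levels)
    n_per_cross <- tabulate(cross_index, n_cross)
    start <- vapply(cross_levels, function(cl) var(y[cross == cl]), 1)
    if (!is.null(init) && !is.null(init$sigma2_g)) {
      ov <- init$sigma2_g[cross_levels]
      start[!is.na(ov)] <- ov[!is.na(ov)]
    }
    start[is.na(start) | start < lower_v] <- vy
    opt <- optim(start,
                 fn = function(v) reml_collapsed_eval(v, y, Xr, cross_index,
                                                      n_per_cross)$dev,
                 gr = function(v) {
                   ev <- reml_collapsed_eval(v, y, Xr, cross_index,
                                             n_per_cross)
                   if (is.null(ev$grad)) rep(0, n_cross) else ev$grad
                 },
                 method = "L-BFGS-B", lower = lower_v,
                 control = list(maxit = max_iter, factr = 1e4,
                                parscale = rep(vy, n_cross)))
    v_hat <- opt$par
    sg <- v_hat
    se <- 0
    w <- 1 / v_hat[cross_index]
    XtViX <- crossprod(Xr * sqrt(w))
    cov_beta <- chol2inv(chol(XtViX))
    beta_r <- drop(cov_beta %*% crossprod(Xr, y * w))
    kr <- kr_pieces_collapsed(Xr, v_hat, cross_index, cov_beta)
  } else {
    mw <- mean(vapply(split(y, geno_index)[reps_tab > 1L], var, 1),
               na.rm = TRUE)
    if (is.na(mw) || mw <= 0) mw <- vy / 2
    start <- c(rep(max(vy - mw, lower_v), n_cross), max(mw, lower_v))
    if (!is.null(init)) {
      if (!is.null(init$sigma2_g)) {
        ov <- init$sigma2_g[cross_levels]
        start[seq_len(n_cross)][!is.na(ov)] <- pmax(ov[!is.na(ov)], lower_v)
      }
      if (!is.null(init$sigma2_e) && !is.na(init$sigma2_e))
        start[n_cross + 1L] <- max(init$sigma2_e, lower_v)
    }
    opt <- optim(start, reml_deviance_full, method = "L-BFGS-B",
                 y = y, X = Xr, geno_index = geno_index,
                 geno_cross = geno_cross, reps = reps_tab,
                 n_cross = n_cross,
                 lower = c(rep(0, n_cross), lower_v),
                 control = list(maxit = max_iter, factr = 1e2,
                                parscale = rep(vy, n_cross + 1L),
                                ndeps = rep(1e-6, n_cross + 1L)))
    sg <- opt$par[seq_len(n_cross)]
    se <- opt$par[n_cross + 1L]
    p <- reml_pieces(y, Xr, geno_index, geno_cross, reps_tab, sg, se)
    cov_beta <- chol2inv(chol(p$XtViX))
    beta_r <- drop(cov_beta %*% p$XtViy)
  }
  converged <- opt$convergence == 0L
  dimnames(cov_beta) <- list(colnames(Xr), colnames(Xr))
  beta <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  beta[kept] <- beta_r

  list(vc = list(sigma2_g = if (collapsed)
                   setNames(rep(NA_real_, n_cross), cross_levels) else
                   setNames(sg, cross_levels),
                 sigma2_e = if (collapsed) NA_real_ else se,
                 total = setNames(sg + se, cross_levels),
                 collapsed = collapsed, converged = converged,
                 loglik = -opt$value / 2),
       beta = beta, cov_beta = cov_beta,
       cov_beta_adj = if (collapsed && !is.null(kr)) kr$Lambda else cov_beta,
       kr = if (collapsed) kr else NULL,
       kept = kept, rank = rank, n = n,
       cross_levels = cross_levels)
}

# Kackar-Harville / Kenward-Roger small-sample pieces for the collapsed
# model V = diag(v[cross]). The naive GLS covariance
# Phi = (X'V^-1 X)^-1 ignores the sampling error of the REML per-cross
# variances; the adjusted covariance is
#   Lambda = Phi + 2 Phi [ sum_c W_cc G_c / v_c
#                          - sum_cd W_cd G_c Phi G_d ] Phi
# with G_c = X_c' X_c / v_c^2 and W the inverse expected REML information
# of the variance parameters (V is linear in v, so the second-derivative
# term of Kenward & Roger vanishes). G, W and Phi are retained for the
# F-approximation of Wald tests.
kr_pieces_collapsed <- function(X, v, cross_index, Phi) {
  k <- length(v)
  w <- 1 / v[cross_index]
  L <- tryCatch(chol(Phi), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  Bt <- (X %*% t(L)) * w
  G <- vector("list", k)
  for (cc in seq_len(k)) {
    rows <- cross_index == cc
    G[[cc]] <- crossprod(X[rows, , drop = FALSE]) / v[cc]^2
  }
  # expected REML information I[c,d] = 0.5 * sum_{i in c, j in d} P_ij^2.
  # Off-diagonal P entries are -b_i.b_j (b = row of Bt), so the cross-pair
  # sums are tr(Cc Cd) with Cc the per-cross Gram matrix of Bt rows; the
  # diagonal blocks add the P_ii corrections.
  Cg <- lapply(seq_len(k), function(cc)
    crossprod(Bt[cross_index == cc, , drop = FALSE]))
  info <- matrix(0, k, k)
  for (cc in seq_len(k)) {
    for (dd in cc:k) {
      s2 <- sum(Cg[[cc]] * Cg[[dd]])
      if (cc == dd) {
        rc <- cross_index == cc
        wi <- w[rc]
        hii <- rowSums(Bt[rc, , drop = FALSE]^2)  # w_i^2 x_i' Phi x_i
        s2 <- s2 + sum(wi^2) - 2 * sum(wi * hii)
      }
      info[cc, dd] <- info[dd, cc] <- 0.5 * s2
    }
  }
  W <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(W)) return(NULL)
  mid <- matrix(0, ncol(X), ncol(X))
  PhiG <- lapply(G, function(g) Phi %*% g)
  for (cc in seq_len(k)) {
    mid <- mid + W[cc, cc] * G[[cc]] / v[cc]
    for (dd in seq_len(k))
      mid <- mid - W[cc, dd] * G[[cc]] %*% PhiG[[dd]]
  }
  Lambda <- Phi + 2 * (Phi %*% mid %*% Phi)
  Lambda <- (Lambda + t(Lambda)) / 2
  if (any(diag(Lambda) < diag(Phi) * 0.5)) Lambda <- Phi
  list(Phi = Phi, Lambda = Lambda, G = G, W = W)
}

# Kenward-Roger F approximation for H0: beta_block = 0 in the collapsed
# model. Returns the adjusted Wald statistic, an F scale factor lambda,
# estimated denominator df and the F-based P value; falls back to the
# chi-square reference when the KR pieces are unavailable.
wald_block_kr <- function(fit, block_cols) {
  in_block <- fit$kept %in% block_cols
  if (!any(in_block)) return(list(W = 0, df = 0L, P = 1, ddf = Inf))
  if (is.null(fit$kr)) {
    wb <- wald_block(fit, block_cols, adjusted = FALSE)
    return(list(W = wb$W, df = wb$df, P = wb$P, ddf = Inf))
  }
  b <- fit$beta[fit$kept][in_block]
  Phi <- fit$kr$Phi
  Lambda <- fit$kr$Lambda
  l <- sum(in_block)
  Lsel <- diag(ncol(Phi))[, in_block, drop = FALSE]
  M_in <- Lambda[in_block, in_block, drop = FALSE]
  Minv <- tryCatch(solve(M_in), error = function(e) NULL)
  if (is.null(Minv)) {
    wb <- wald_block(fit, block_cols, adjusted = TRUE)
    return(list(W = wb$W, df = wb$df, P = wb$P, ddf = Inf))
  }
  W_stat <- drop(crossprod(b, Minv %*% b))
  # Theta = L (L' Lambda L)^-1 L'
  Theta <- Lsel %*% Minv %*% t(Lsel)
  k <- length(fit$kr$G)
  TP <- Theta %*% Phi
  A1 <- 0; A2 <- 0
  TG <- lapply(fit$kr$G, function(g) TP %*% g %*% Phi)
  tr_TG <- vapply(TG, function(m) sum(diag(m)), 1)
  for (cc in seq_len(k)) for (dd in seq_len(k)) {
    wcd <- fit$kr$W[cc, dd]
    A1 <- A1 + wcd * tr_TG[cc] * tr_TG[dd]
    A2 <- A2 + wcd * sum(TG[[cc]] * t(TG[[dd]]))
  }
  B <- (A1 + 6 * A2) / (2 * l)
  g <- ((l + 1) * A1 - (l + 4) * A2) / ((l + 2) * A2)
  c1 <- g / (3 * l + 2 * (1 - g))
  c2 <- (l - g) / (3 * l + 2 * (1 - g))
  c3 <- (l + 2 - g) / (3 * l + 2 * (1 - g))
  Estar <- 1 / (1 - A2 / l)
  Vstar <- (2 / l) * (1 + c1 * B) / ((1 - c2 * B)^2 * (1 - c3 * B))
  rho <- Vstar / (2 * Estar^2)
  m <- 4 + (l + 2) / (l * rho - 1)
  lam <- m / (Estar * (m - 2))
  if (!is.finite(m) || m <= 2 || !is.finite(lam) || lam <= 0) {
    P <- pchisq(W_stat, l, lower.tail = FALSE)
    return(list(W = W_stat, df = l, P = P, ddf = Inf))
  }
  Fstat <- lam * W_stat / l
  P <- pf(Fstat, l, m, lower.tail = FALSE)
  list(W = W_stat, df = l, P = P, ddf = m, lambda = lam)
}

# Wald test that a block of coefficients is zero, on the estimable
# subspace; invariant to the constraint basis spanning that subspace.
# Uses the small-sample adjusted coefficient covariance when available.
wald_block <- function(fit, block_cols, adjusted = TRUE) {
  in_block <- fit$kept %in% block_cols
  if (!any(in_block))
    return(list(W = 0, df = 0L, P = 1, estimable = 0L))
  b <- fit$beta[fit$kept][in_block]
  Cfull <- if (adjusted && !is.null(fit$cov_beta_adj)) fit$cov_beta_adj
           else fit$cov_beta
  C <- Cfull[in_block, in_block, drop = FALSE]
  W <- tryCatch(drop(crossprod(b, solve(C, b))), error = function(e) {
    ev <- eigen(C, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    Ci <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    drop(crossprod(b, Ci %*% b))
  })
  df <- sum(in_block)
  list(W = W, df = df, P = pchisq(W, df, lower.tail = FALSE),
       estimable = df)
}
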