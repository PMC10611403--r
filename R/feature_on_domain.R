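#' Pearson correlation test for a single pair
#'
#' Product-moment correlation with a two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor_test <- function(x, y) {
  n <- length(x)
  if (n < 3L) mmj_stop("need n >= 3 for a correlation p-value",
                       "mmjive_input_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    mmj_stop("constant input to correlation", "mmjive_validation_error")
  }
  r <- stats::cor(x, y)
  r2 <- min(r^2, 1)
  p <- if (r2 >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

cor_matrix_with_p <- function(a, b) {
  n <- nrow(a)
  r <- stats::cor(a, b)
  r2 <- pmin(r^2, 1)
  tval <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.xmin))
  p <- 2 * stats::pt(-tval, df = n - 2)
  p[r2 >= 1 - 1e-15] <- 0
  list(r = r, p = p)
}

#' Pairwise correlation between the two feature domains
#'
#' Pearson correlations between every physical-activity and gait feature
#' computed on per-subject day averages, with two-sided p-values and a
#' significance mask at `alpha` (0.1 by default, matching the usual display
#' convention for this report). The full (P+Q) x (P+Q) correlation matrix
#' (within- plus cross-domain) is also returned for heat-map style reports.
#'
#' @param means a `subject_means_matrix` (scale first for comparability).
#' @param alpha significance level for the mask.
#' @return a `correlation_matrix`: list with `r_values`, `p_values`,
#'   `mask` (all P x Q, PA rows x gait columns), `alpha`, `n`, and `full`
#'   (list `r`, `p` over all features).
#' @export
pearson_matrix <- function(means, alpha = 0.1) {
  vals <- means$values
  n <- nrow(vals)
  if (n < 3L) mmj_stop("need at least 3 subjects", "mmjive_input_error")
  sds <- apply(vals, 2L, stats::sd)
  if (any(sds == 0)) {
    mmj_stop(sprintf("constant feature column(s): %s",
                     paste(colnames(vals)[sds == 0], collapse = ", ")),
             "mmjive_validation_error")
  }
  full <- cor_matrix_with_p(vals, vals)
  diag(full$p) <- 0
  cross_r <- full$r[means$pa_features, means$gait_features, drop = FALSE]
  cross_p <- full$p[means$pa_features, means$gait_features, drop = FALSE]
  structure(list(
    r_values = cross_r, p_values = cross_p, mask = cross_p < alpha,
    alpha = alpha, n = n, full = full
  ), class = "correlation_matrix")
}

# ---- Lasso ----------------------------------------------------------------

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Exact Lasso solve by feature-sign (active-set) search for
#   min (1/2n) ||y - X b||^2 + lambda ||b||_1
# written as min 1/2 b'Qb - c'b + lambda |b|_1 with Q = X'X/n, c = X'y/n.
# The active set is grown by the worst KKT violator and each candidate is
# the exact solution of the sign-restricted quadratic; sign changes are
# handled by a line search to the first zero crossing. The objective
# strictly decreases, so the search terminates with a machine-precision
# solution (KKT residual ~ solver precision). Feasible here because the
# predictor panels are narrow (P <= a few dozen).
lasso_solve <- function(Q, c_vec, lambda, beta = numeric(length(c_vec))) {
  p <- length(c_vec)
  active <- which(beta != 0)
  theta <- sign(beta)
  for (outer in seq_len(100L * (p + 1L))) {
    g <- as.vector(Q %*% beta) - c_vec
    inactive <- setdiff(seq_len(p), active)
    viol <- abs(g[inactive]) - lambda
    if (length(inactive) && any(viol > 1e-12)) {
      j <- inactive[which.max(viol)]
      active <- c(active, j)
      theta[j] <- -sign(g[j])
    } else if (outer > 1L || length(active) == 0L) {
      return(beta)
    }
    # inner loop: exact solve on the active set with sign handling
    for (inner in seq_len(100L * (p + 1L))) {
      a <- active
      b_new <- tryCatch(
        solve(Q[a, a, drop = FALSE], c_vec[a] - lambda * theta[a]),
        error = function(e) qr.solve(Q[a, a, drop = FALSE],
                                     c_vec[a] - lambda * theta[a]))
      if (all(sign(b_new) == theta[a] | b_new == 0)) {
        beta[] <- 0
        beta[a] <- b_new
        keep <- b_new != 0
        active <- a[keep]
        theta[a[!keep]] <- 0
        break
      }
      # line search from beta[a] to b_new: stop at first zero crossing
      b_old <- beta[a]
      crossing <- which(sign(b_new) != theta[a])
      tt <- b_old[crossing] / (b_old[crossing] - b_new[crossing])
      tt[!is.finite(tt) | tt < 0] <- 0
      t_star <- min(tt)
      beta[a] <- b_old + t_star * (b_new - b_old)
      drop_i <- crossing[which.min(tt)]
      beta[a[drop_i]] <- 0
      theta[a[drop_i]] <- 0
      active <- a[-drop_i]
      if (length(active) == 0L) break
    }
    if (length(active) == 0L) {
      g <- as.vector(Q %*% beta) - c_vec
      if (max(abs(g)) <= lambda + 1e-12) return(beta)
    }
  }
  beta
}

lasso_path <- function(x, y, lambda_grid) {
  n <- length(y)
  Q <- crossprod(x) / n
  c_vec <- as.vector(crossprod(x, y)) / n
  beta <- numeric(ncol(x))
  path <- matrix(0, length(lambda_grid), ncol(x),
                 dimnames = list(NULL, colnames(x)))
  for (k in seq_along(lambda_grid)) {
    beta <- lasso_solve(Q, c_vec, lambda_grid[k], beta)
    path[k, ] <- beta
  }
  path
}

#' Lasso regression with five-fold cross-validation and the one-SE rule
#'
#' Solves `min (1/2n) ||y - b0 - X b||^2 + lambda ||b||_1` by cyclic
#' coordinate descent with warm starts over a 100-point log-spaced grid
#' from `lambda_max = max |X'y| / n` down to `1e-3 * lambda_max`. The grid
#' is evaluated by k-fold cross-validation with folds assigned at the
#' record (subject) level under a fixed seed; the reported model is the one
#' at `lambda_1se`, the largest lambda whose mean CV error is within one
#' standard error of the minimum mean CV error (the sparsest model not
#' meaningfully worse than the best).
#'
#' @param y response vector (centered internally via the intercept).
#' @param x predictor matrix, standardized columns (asserted: column means
#'   ~ 0 and mean squares ~ 1).
#' @param n_folds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param n_lambda,lambda_min_ratio grid size and lower end ratio.
#' @return a `lasso_fit`: `lambda_grid`, `coef_path`, `cv_mean_error`,
#'   `cv_se_error`, `lambda_min`, `lambda_1se`, `selected_coefs` (named,
#'   only nonzero entries), `coefficients` (full vector at lambda_1se),
#'   `intercept`, `response_name`, `predictor_names`.
#' @export
lasso_fit <- function(y, x, n_folds = 5L, seed = 1L, n_lambda = 100L,
                      lambda_min_ratio = 1e-3) {
  x <- as.matrix(x)
  n <- length(y)
  if (n != nrow(x)) mmj_stop("length(y) != nrow(x)", "mmjive_input_error")
  if (n <= n_folds) mmj_stop("need n > n_folds", "mmjive_input_error")
  cm <- colMeans(x)
  msq <- colSums(x^2) / n
  if (any(abs(cm) > 1e-6) || any(abs(msq - 1) > 0.05)) {
    mmj_stop("predictors must be standardized (mean 0, unit variance)",
             "mmjive_validation_error")
  }
  intercept <- mean(y)
  yc <- y - intercept
  lambda_max <- max(abs(crossprod(x, yc))) / n
  if (lambda_max == 0) lambda_max <- 1e-12
  lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                         length.out = n_lambda))
  path <- lasso_path(x, yc, lambda_grid)

  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  if (min(table(folds)) < 2L) {
    mmj_stop("a CV fold has fewer than 2 observations", "mmjive_input_error")
  }
  cv_err <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]
    ytr <- yc[tr]
    b0 <- mean(ytr)
    pth <- lasso_path(xtr, ytr - b0, lambda_grid)
    pred <- x[!tr, , drop = FALSE] %*% t(pth) + b0
    cv_err[f, ] <- colMeans((yc[!tr] - pred)^2)
  }
  cv_mean <- colMeans(cv_err)
  cv_se <- apply(cv_err, 2L, stats::sd) / sqrt(n_folds)
  i_min <- which.min(cv_mean)
  thr <- cv_mean[i_min] + cv_se[i_min]
  i_1se <- min(which(cv_mean <= thr))  # grid is decreasing in lambda
  coefs <- path[i_1se, ]
  structure(list(
    response_name = attr(y, "name") %||% "y",
    predictor_names = colnames(x),
    lambda_grid = lambda_grid, coef_path = path,
    cv_mean_error = cv_mean, cv_se_error = cv_se,
    lambda_min = lambda_grid[i_min], lambda_1se = lambda_grid[i_1se],
    coefficients = coefs,
    selected_coefs = coefs[coefs != 0],
    intercept = intercept, n_folds = n_folds, seed = seed
  ), class = "lasso_fit")
}

#' Lasso of every feature in one domain on the whole other domain
#'
#' Runs [lasso_fit()] with each feature of the response domain regressed on
#' all features of the predictor domain, and assembles the sparse
#' coefficient table (responses x predictors; unselected predictors are
#' `NA`, rendered blank by the writers).
#'
#' @param means a scaled `subject_means_matrix`.
#' @param direction `"gait_on_PA"` (each gait feature on the PA block) or
#'   `"PA_on_gait"`.
#' @param n_folds,seed passed to [lasso_fit()].
#' @return a `lasso_panel`: list with `coefficients` (matrix with `NA` for
#'   unselected), `fits` (per-response `lasso_fit`s), `direction`.
#' @export
lasso_panel <- function(means, direction = c("gait_on_PA", "PA_on_gait"),
                        n_folds = 5L, seed = 1L) {
  direction <- match.arg(direction)
  blocks <- block_split(means$values, means$pa_features,
                        means$gait_features)
  if (direction == "gait_on_PA") {
    xs <- blocks$x; ys <- blocks$y
  } else {
    xs <- blocks$y; ys <- blocks$x
  }
  fits <- lapply(colnames(ys), function(resp) {
    yv <- ys[, resp]
    attr(yv, "name") <- resp
    lasso_fit(yv, xs, n_folds = n_folds, seed = seed)
  })
  names(fits) <- colnames(ys)
  coefs <- t(vapply(fits, function(f) {
    b <- f$coefficients
    b[b == 0] <- NA_real_
    b
  }, numeric(ncol(xs))))
  dimnames(coefs) <- list(colnames(ys), colnames(xs))
  structure(list(coefficients = coefs, fits = fits, direction = direction),
            class = "lasso_panel")
}

# ---- Principal component regression ---------------------------------------

#' Principal component regression of gait features on PA components
#'
#' PCA (by SVD) of the scaled physical-activity block; the retained
#' component count is either given or chosen automatically as the smallest
#' `k` whose cumulative explained variance reaches 90% (the scree-elbow
#' alternative, the maximum second difference of the explained-variance
#' sequence, is computed and reported side by side). Each gait feature is
#' then regressed by ordinary least squares on the retained PC scores;
#' coefficient p-values come from the t distribution and the significance
#' mask is taken at `p_alpha`.
#'
#' @param means a scaled `subject_means_matrix`.
#' @param k number of components, or `"auto"`.
#' @param p_alpha significance level for the coefficient mask.
#' @param var_target cumulative explained-variance target for `k = "auto"`.
#' @return a `pcr_fit`: `pc_loadings` (P x k), `pc_explained` (all P
#'   fractions), `k`, `k_elbow`, `scores`, `coefficients` (Q x k),
#'   `p_values`, `mask`, `intercepts`.
#' @export
pcr_fit <- function(means, k = "auto", p_alpha = 0.05, var_target = 0.90) {
  blocks <- block_split(means$values, means$pa_features,
                        means$gait_features)
  x <- sweep(blocks$x, 2L, colMeans(blocks$x))
  y <- blocks$y
  n <- nrow(x)
  s <- svd(x)
  explained <- s$d^2 / sum(s$d^2)
  kmax <- min(n - 1L, ncol(x))
  cum <- cumsum(explained)
  k_var <- min(which(cum >= var_target - 1e-12))
  scree <- c(explained, 0)
  d2 <- diff(diff(scree))
  k_elbow <- if (length(d2)) which.max(d2) + 1L else 1L
  if (identical(k, "auto")) k <- k_var
  k <- as.integer(k)
  if (k < 1L || k > kmax) {
    mmj_stop(sprintf("k must be in 1..%d", kmax), "mmjive_input_error")
  }
  fx <- fix_signs(s$v[, seq_len(k), drop = FALSE],
                  s$u[, seq_len(k), drop = FALSE] %*%
                    diag(s$d[seq_len(k)], k))
  loadings <- fx$v
  scores <- fx$companion
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  colnames(scores) <- paste0("PC", seq_len(k))

  q <- ncol(y)
  coef <- matrix(NA_real_, q, k, dimnames = list(colnames(y),
                                                 colnames(scores)))
  pval <- coef
  intercepts <- numeric(q)
  for (j in seq_len(q)) {
    fit <- stats::lm(y[, j] ~ scores)
    sm <- summary(fit)$coefficients
    coef[j, ] <- sm[-1L, 1L]
    pval[j, ] <- sm[-1L, 4L]
    intercepts[j] <- sm[1L, 1L]
  }
  structure(list(
    pc_loadings = loadings, pc_explained = explained, k = k,
    k_elbow = k_elbow, k_variance_rule = k_var, var_target = var_target,
    scores = scores, coefficients = coef, p_values = pval,
    mask = pval < p_alpha, p_alpha = p_alpha, intercepts = intercepts
  ), class = "pcr_fit")
}
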