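#' Two-block partial least squares regression
#'
#' Finds successive pairs of unit weight vectors `(mu, nu)` maximizing the
#' cross-block covariance `mu' X' Y nu`: per component the leading singular
#' vector pair of the current `X'Y` is taken as the weights, scores are the
#' projections of each block on its weights, and both blocks are deflated
#' by the regression on the x-score (regression mode: the PA block explains
#' the gait block). Also emits correlation-circle coordinates, the Pearson
#' correlation of every original feature with each x-score.
#'
#' @param x n x P predictor block (physical activity), columns centered.
#' @param y n x Q response block (gait), columns centered.
#' @param n_components number of components (default 2).
#' @return a `pls_model`: `x_weights` (P x a), `y_weights` (Q x a),
#'   `x_scores`, `y_scores` (n x a), `x_loadings`, `y_loadings`,
#'   `covariance_explained` (per-component fractions of the squared
#'   Frobenius norm of the initial `X'Y`), `correlation_circle`
#'   ((P+Q) x a matrix with a `domain` attribute), `n_components`.
#' @export
pls_fit <- function(x, y, n_components = 2L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) mmj_stop("row mismatch between blocks",
                             "mmjive_input_error")
  if (max(abs(colMeans(x))) > 1e-8 || max(abs(colMeans(y))) > 1e-8) {
    mmj_stop("blocks must be column-centered", "mmjive_validation_error")
  }
  a <- as.integer(n_components)
  if (a < 1L || a > min(n - 1L, ncol(x), ncol(y))) {
    mmj_stop("n_components must be in 1..min(n-1, P, Q)",
             "mmjive_input_error")
  }
  c0 <- crossprod(x, y)
  total_cov <- sum(c0^2)
  if (total_cov < .Machine$double.eps) {
    mmj_stop("zero cross-covariance: no shared structure",
             "mmjive_validation_error")
  }
  p <- ncol(x); q <- ncol(y)
  W <- matrix(0, p, a); V <- matrix(0, q, a)
  Tx <- matrix(0, n, a); Uy <- matrix(0, n, a)
  Px <- matrix(0, p, a); Qy <- matrix(0, q, a)
  cov_expl <- numeric(a)
  x1 <- x; y1 <- y
  for (k in seq_len(a)) {
    ck <- crossprod(x1, y1)
    s <- svd(ck, nu = 1L, nv = 1L)
    w <- s$u[, 1L]; v <- s$v[, 1L]
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; v <- -v }
    tk <- as.vector(x1 %*% w)
    uk <- as.vector(y1 %*% v)
    tt <- sum(tk^2)
    pk <- as.vector(crossprod(x1, tk)) / tt
    qk <- as.vector(crossprod(y1, tk)) / tt
    x1 <- x1 - tcrossprod(tk, pk)
    y1 <- y1 - tcrossprod(tk, qk)
    W[, k] <- w; V[, k] <- v; Tx[, k] <- tk; Uy[, k] <- uk
    Px[, k] <- pk; Qy[, k] <- qk
    cov_expl[k] <- s$d[1L]^2 / total_cov
  }
  comp <- paste0("PC", seq_len(a))
  dimnames(W) <- list(colnames(x), comp); dimnames(V) <- list(colnames(y), comp)
  dimnames(Px) <- dimnames(W); dimnames(Qy) <- dimnames(V)
  colnames(Tx) <- comp; colnames(Uy) <- comp
  circle <- stats::cor(cbind(x, y), Tx)
  attr(circle, "domain") <- c(rep("PA", p), rep("gait", q))
  structure(list(
    x_weights = W, y_weights = V, x_scores = Tx, y_scores = Uy,
    x_loadings = Px, y_loadings = Qy, covariance_explained = cov_expl,
    correlation_circle = circle, n_components = a
  ), class = "pls_model")
}

# ---- JIVE -----------------------------------------------------------------

check_jive_ranks <- function(p, q, n, r, r1, r2) {
  if (any(c(r, r1, r2) < 0L)) {
    mmj_stop("JIVE ranks must be >= 0", "mmjive_input_error")
  }
  if (r > min(p + q, n) || r1 > p || r2 > q ||
      r + max(r1, r2) > n) {
    mmj_stop("infeasible JIVE ranks for the block dimensions",
             "mmjive_input_error")
  }
}

#' Joint and individual variation explained (JIVE)
#'
#' Decomposes two feature-by-sample blocks stacked as `Z = [X; Y]` into a
#' rank-`r` joint structure `J = [J1; J2]` shared across blocks, rank-`r_l`
#' block-specific individual structures `A_l` whose rows are orthogonal to
#' the rows of `J`, and residual noise. Estimation alternates (i) `J` as
#' the best rank-`r` approximation of `Z - A` and (ii) each `A_l` as the
#' best rank-`r_l` approximation of `X_l - J_l` projected onto the
#' orthocomplement of the row space of `J`, until the summed squared
#' Frobenius change of `(J, A1, A2)` drops below `tol`. Blocks are
#' pre-scaled to unit Frobenius norm by default so neither domain dominates
#' (recorded, and undone in the returned structures).
#'
#' @param x P x n block (features in rows, samples in columns).
#' @param y Q x n block, same columns.
#' @param r,r1,r2 joint and per-block individual ranks.
#' @param scale_blocks divide each block by its Frobenius norm before
#'   fitting (default `TRUE`).
#' @param tol convergence threshold on the summed squared Frobenius change
#'   (computed on the scaled blocks).
#' @param maxit iteration cap; non-convergence is an error carrying the
#'   last change in `$delta`.
#' @return a `jive_model`: `joint_blocks` (`J1`, `J2`), `individual_blocks`
#'   (`A1`, `A2`), `residuals` (`E1`, `E2`), `ranks`, `variance_table`
#'   (fractions of total and per block), `joint_scores` (r x n),
#'   `individual_scores` (per block), `block_norms`, `iterations`.
#' @export
jive_fit <- function(x, y, r, r1, r2, scale_blocks = TRUE, tol = 1e-9,
                     maxit = 1000L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) mmj_stop("blocks must share columns",
                                   "mmjive_input_error")
  p <- nrow(x); q <- nrow(y); n <- ncol(x)
  check_jive_ranks(p, q, n, r, r1, r2)
  fx <- if (scale_blocks) sqrt(sum(x^2)) else 1
  fy <- if (scale_blocks) sqrt(sum(y^2)) else 1
  if (fx == 0 || fy == 0) mmj_stop("a block is identically zero",
                                   "mmjive_input_error")
  z <- rbind(x / fx, y / fy)
  ix <- seq_len(p); iy <- p + seq_len(q)
  J <- matrix(0, p + q, n)
  A1 <- matrix(0, p, n); A2 <- matrix(0, q, n)
  converged <- FALSE
  delta <- Inf
  objective <- numeric(0L)
  for (it in seq_len(maxit)) {
    J_old <- J; A1_old <- A1; A2_old <- A2
    jr <- rank_approx(z - rbind(A1, A2), r)
    J <- jr$approx
    Vj <- jr$v  # n x r orthonormal row-space basis of J
    for (l in 1:2) {
      idx <- if (l == 1L) ix else iy
      rl <- if (l == 1L) r1 else r2
      res <- z[idx, , drop = FALSE] - J[idx, , drop = FALSE]
      if (!is.null(Vj)) res <- res - (res %*% Vj) %*% t(Vj)
      al <- rank_approx(res, rl)$approx
      if (l == 1L) A1 <- al else A2 <- al
    }
    delta <- sum((J - J_old)^2) + sum((A1 - A1_old)^2) + sum((A2 - A2_old)^2)
    objective <- c(objective, sum((z - J - rbind(A1, A2))^2))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("mmjive_convergence_error", "mmjive_error", "error",
                "condition"),
      list(message = sprintf(
        "JIVE did not converge in %d iterations (last delta %.3e)",
        maxit, delta), call = sys.call(), delta = delta))
    stop(cond)
  }
  # back to the input scale
  J1 <- J[ix, , drop = FALSE] * fx
  J2 <- J[iy, , drop = FALSE] * fy
  A1 <- A1 * fx; A2 <- A2 * fy
  E1 <- x - J1 - A1; E2 <- y - J2 - A2
  rownames(J1) <- rownames(A1) <- rownames(E1) <- rownames(x)
  rownames(J2) <- rownames(A2) <- rownames(E2) <- rownames(y)

  # fractions are normalized by the summed squared norms of the three
  # parts; the decomposition is exact, so this differs from ||X||_F^2 only
  # by the O(tol) cross-terms left at convergence, and it makes the
  # fractions sum to 1 exactly
  ssJ <- sum(J1^2) + sum(J2^2)
  ssA <- sum(A1^2) + sum(A2^2)
  ssE <- sum(E1^2) + sum(E2^2)
  total <- ssJ + ssA + ssE
  tot1 <- sum(J1^2) + sum(A1^2) + sum(E1^2)
  tot2 <- sum(J2^2) + sum(A2^2) + sum(E2^2)
  vt <- list(
    joint = ssJ / total, individual = ssA / total,
    residual = ssE / total,
    joint_share = c(PA = sum(J1^2), gait = sum(J2^2)) / max(ssJ, 1e-300),
    individual_share = c(PA = sum(A1^2), gait = sum(A2^2)) /
      max(ssA, 1e-300),
    per_block = rbind(
      PA = c(joint = sum(J1^2), individual = sum(A1^2),
             residual = sum(E1^2)) / max(tot1, 1e-300),
      gait = c(joint = sum(J2^2), individual = sum(A2^2),
               residual = sum(E2^2)) / max(tot2, 1e-300)))

  score_of <- function(m, k) {
    if (k == 0L) return(matrix(0, 0L, n))
    s <- svd(m, nu = k, nv = k)
    sc <- t(s$v %*% diag(s$d[seq_len(k)], k))
    ld <- fix_signs(s$u[, seq_len(k), drop = FALSE], t(sc))
    t(ld$companion)
  }
  structure(list(
    joint_blocks = list(J1 = J1, J2 = J2),
    individual_blocks = list(A1 = A1, A2 = A2),
    residuals = list(E1 = E1, E2 = E2),
    ranks = c(r = r, r1 = r1, r2 = r2),
    variance_table = vt,
    joint_scores = score_of(rbind(J1, J2), r),
    individual_scores = list(PA = score_of(A1, r1),
                             gait = score_of(A2, r2)),
    block_norms = c(PA = fx, gait = fy),
    scale_blocks = scale_blocks,
    iterations = it, delta = delta, objective = objective
  ), class = "jive_model")
}

#' Permutation-based JIVE rank selection
#'
#' Selects the joint rank by comparing the singular values of the stacked
#' (block-scaled) matrix against a null obtained by independently
#' permuting the columns of each block (which breaks cross-block
#' association while keeping within-block structure), and then each
#' block's individual rank by comparing the singular values of the block's
#' joint-residual against a null obtained by permuting each feature row
#' independently. Ranks are grown sequentially while the permutation
#' p-value `(1 + #null >= observed) / (n_perm + 1)` stays below `alpha`.
#'
#' @param x,y feature-by-sample blocks as in [jive_fit()].
#' @param n_perm number of permutations (>= 20).
#' @param alpha per-test significance level.
#' @param seed integer seed; results are deterministic given the seed.
#' @param scale_blocks as in [jive_fit()].
#' @return list with elements `r`, `r1`, `r2`.
#' @export
jive_rank_select <- function(x, y, n_perm = 100L, alpha = 0.05, seed = 1L,
                             scale_blocks = TRUE) {
  if (n_perm < 20L) mmj_stop("n_perm must be >= 20 (null too coarse)",
                             "mmjive_input_error")
  x <- as.matrix(x); y <- as.matrix(y)
  p <- nrow(x); q <- nrow(y); n <- ncol(x)
  if (ncol(y) != n) mmj_stop("blocks must share columns",
                             "mmjive_input_error")
  fx <- if (scale_blocks) sqrt(sum(x^2)) else 1
  fy <- if (scale_blocks) sqrt(sum(y^2)) else 1
  x1 <- x / fx; y1 <- y / fy
  with_seed(seed, {
    sv <- function(m) svd(m, nu = 0L, nv = 0L)$d
    # singular values below a relative floor are numerically zero: never
    # significant (guards noiseless fixtures whose residual is eps-scale)
    floor_sv <- 1e-8 * sqrt(sum(x1^2) + sum(y1^2))
    seq_rank <- function(d_obs, null1, kmax) {
      r <- 0L
      for (k in seq_len(kmax)) {
        if (d_obs[k] <= floor_sv) break
        pval <- (1 + sum(null1 >= d_obs[k])) / (length(null1) + 1)
        if (pval < alpha) r <- k else break
      }
      r
    }
    d_joint <- sv(rbind(x1, y1))
    null_joint <- vapply(seq_len(n_perm), function(b) {
      sv(rbind(x1[, sample.int(n), drop = FALSE],
               y1[, sample.int(n), drop = FALSE]))[1L]
    }, numeric(1L))
    kmax_j <- min(p + q, n)
    r <- seq_rank(d_joint, null_joint, kmax_j)

    Vj <- if (r > 0L) svd(rbind(x1, y1), nu = 0L, nv = r)$v else NULL
    ind_rank <- function(block, kmax) {
      res <- block
      if (!is.null(Vj)) res <- res - (res %*% Vj) %*% t(Vj)
      d_obs <- sv(res)
      null1 <- vapply(seq_len(n_perm), function(b) {
        perm <- t(apply(res, 1L, sample))
        sv(perm)[1L]
      }, numeric(1L))
      seq_rank(d_obs, null1, kmax)
    }
    r1 <- ind_rank(x1, min(p, n - r))
    r2 <- ind_rank(y1, min(q, n - r))
    list(r = r, r1 = r1, r2 = r2)
  })
}

#' Joint/individual variance-explained table
#'
#' Formats the variance accounting of a fitted [jive_fit()] model in the
#' standard report layout: the fraction of total variation explained by
#' the joint and individual structures, and each domain's share of those
#' structures (shares sum to 1 within a column).
#'
#' @param model a `jive_model`.
#' @return data.frame with rows `explained_variation`, `gait`, `PA` and
#'   columns `joint`, `individual`.
#' @export
variance_table <- function(model) {
  vt <- model$variance_table
  data.frame(
    row.names = c("explained_variation", "gait", "PA"),
    joint = c(vt$joint, vt$joint_share[["gait"]], vt$joint_share[["PA"]]),
    individual = c(vt$individual, vt$individual_share[["gait"]],
                   vt$individual_share[["PA"]])
  )
}
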