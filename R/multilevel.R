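#' Between/within ANOVA decomposition of a repeated-measures panel
#'
#' Exact empirical decomposition of every subject-day feature vector into
#' `grand mean + (subject mean - grand mean) + (observation - subject
#' mean)`. The between matrix has one row per subject (day-count weighting
#' enters the sums of squares only); the within matrix has one row per
#' observation and sums to zero within each subject.
#'
#' @param panel a `feature_panel`, normally scaled over daily rows.
#' @return a `multilevel_decomposition`: `grand_mean`, `between` (n x K),
#'   `within` (N x K), `values` (centered N x K), `subject_ids`,
#'   `subject_index`, `n_days`, `sums_of_squares` (per-column and overall
#'   `between`, `within`, `total`), and the feature block names.
#' @export
anova_decompose <- function(panel) {
  vals <- panel_matrix(panel)
  g <- factor(panel$data$subject, levels = unique(panel$data$subject))
  idx <- as.integer(g)
  mu <- colMeans(vals)
  sm <- rowsum(vals, g) / as.vector(table(g))
  between <- sweep(sm, 2L, mu)
  within <- vals - sm[idx, , drop = FALSE]
  centered <- sweep(vals, 2L, mu)
  nd <- as.vector(table(g))
  ss_b <- colSums(between^2 * nd)
  ss_w <- colSums(within^2)
  ss_t <- colSums(centered^2)
  structure(list(
    grand_mean = mu, between = between, within = within, values = centered,
    subject_ids = levels(g), subject_index = idx,
    n_days = stats::setNames(nd, levels(g)),
    pa_features = panel$pa_features, gait_features = panel$gait_features,
    sums_of_squares = list(
      per_column = rbind(between = ss_b, within = ss_w, total = ss_t),
      overall = c(between = sum(ss_b), within = sum(ss_w),
                  total = sum(ss_t)))
  ), class = "multilevel_decomposition")
}

psd_clip <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(mat = e$vectors %*% (lam * t(e$vectors)), values = lam,
       vectors = e$vectors)
}

#' Multilevel PCA by level-covariance separation
#'
#' Separates the between-subject and within-subject covariance of a
#' repeated-measures panel and represents each level by its leading
#' principal components. The default (`method = "moment"`) estimates the
#' between covariance from cross-day products within subject (averaged
#' over ordered day pairs j != k, which is blind to observation-level
#' noise) and takes the within covariance as total minus between; both are
#' symmetrized and projected to the nearest positive semidefinite matrix
#' by clipping negative eigenvalues. `method = "empirical"` simply
#' eigendecomposes the day-count-weighted between and the within matrices
#' of the ANOVA decomposition. Per level, the smallest component count
#' whose eigenvalues reach `retained_fraction` of the level trace is kept.
#'
#' @param decomp a [anova_decompose()] result.
#' @param retained_fraction explained-variance threshold per level.
#' @param method `"moment"` or `"empirical"`.
#' @return an `mpca_model`: `between_components`, `within_components`
#'   (orthonormal K x k loadings), `between_scores` (n x k_b),
#'   `within_scores` (N x k_w), `between_eigenvalues`,
#'   `within_eigenvalues`, `level_variance_fractions` (shares of total
#'   variation), `retained_fraction`, `method`.
#' @export
mpca_fit <- function(decomp, retained_fraction = 0.9,
                     method = c("moment", "empirical")) {
  method <- match.arg(method)
  nd <- decomp$n_days
  if (length(nd) < 2L) mmj_stop("need >= 2 subjects", "mmjive_input_error")
  if (all(nd < 2L)) {
    mmj_stop(paste("all subjects have a single day: between and within",
                   "covariance are not separable"), "mmjive_input_error")
  }
  d <- decomp$values
  N <- nrow(d)
  if (method == "moment") {
    s <- rowsum(d, factor(decomp$subject_index,
                          levels = seq_along(decomp$subject_ids)))
    m2 <- sum(nd * (nd - 1))
    raw_b <- (crossprod(s) - crossprod(d)) / m2
    sigma_t <- crossprod(d) / N
    # Finite-day correction: under the ANOVA convention the within
    # effects sum to zero within each subject exactly, so the cross-day
    # moment has expectation S_b - gamma * S_w with gamma = N / M2.
    # Solving together with S_b + S_w = total covariance gives the
    # debiased level covariances used here.
    gamma <- N / m2
    sigma_b <- (raw_b + gamma * sigma_t) / (1 + gamma)
    sigma_w <- (sigma_t - raw_b) / (1 + gamma)
  } else {
    sigma_b <- crossprod(decomp$between * sqrt(nd)) / N
    sigma_w <- crossprod(decomp$within) / N
  }
  eb <- psd_clip(sigma_b)
  ew <- psd_clip(sigma_w)
  pick_k <- function(lam) {
    tot <- sum(lam)
    if (tot <= 0) return(1L)
    min(which(cumsum(lam) / tot >= retained_fraction - 1e-12))
  }
  k_b <- pick_k(eb$values)
  k_w <- pick_k(ew$values)
  V_b <- fix_signs(eb$vectors[, seq_len(k_b), drop = FALSE])
  V_w <- fix_signs(ew$vectors[, seq_len(k_w), drop = FALSE])
  feats <- c(decomp$pa_features, decomp$gait_features)
  dimnames(V_b) <- list(feats, paste0("B", seq_len(k_b)))
  dimnames(V_w) <- list(feats, paste0("W", seq_len(k_w)))
  tr_b <- sum(eb$values); tr_w <- sum(ew$values)
  structure(list(
    between_components = V_b, within_components = V_w,
    between_scores = decomp$between %*% V_b,
    within_scores = decomp$within %*% V_w,
    between_eigenvalues = eb$values, within_eigenvalues = ew$values,
    level_variance_fractions = c(between = tr_b, within = tr_w) /
      (tr_b + tr_w),
    retained_fraction = retained_fraction, method = method
  ), class = "mpca_model")
}

#' Multilevel partial least squares
#'
#' Fits the two-block PLS of [pls_fit()] separately on the between-subject
#' and within-subject matrices of the ANOVA decomposition, splitting each
#' into its physical-activity and gait column blocks. If the within matrix
#' is identically zero (all subjects observed on a single day), the within
#' fit is skipped with a warning.
#'
#' @param decomp a [anova_decompose()] result.
#' @param n_components per-level component count.
#' @return an `ml_pls` object: list with `between` and `within`
#'   (`pls_model` or `NULL`) and `loading_tables` (first-component weight
#'   tables per level).
#' @export
ml_pls <- function(decomp, n_components = 2L) {
  fit_level <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    b <- block_split(m, decomp$pa_features, decomp$gait_features)
    pls_fit(b$x, b$y, n_components)
  }
  between <- fit_level(decomp$between)
  within <- NULL
  if (sum(decomp$within^2) < 1e-20) {
    warning("within matrix is zero (single-day subjects); ",
            "within-level PLS skipped")
  } else {
    within <- fit_level(decomp$within)
  }
  tab <- function(m) {
    if (is.null(m)) return(NULL)
    data.frame(feature = c(rownames(m$x_weights), rownames(m$y_weights)),
               domain = c(rep("PA", nrow(m$x_weights)),
                          rep("gait", nrow(m$y_weights))),
               weight_c1 = c(m$x_weights[, 1L], m$y_weights[, 1L]),
               stringsAsFactors = FALSE)
  }
  structure(list(between = between, within = within,
                 loading_tables = list(between = tab(between),
                                       within = tab(within))),
            class = "ml_pls")
}

#' Two-step multilevel JIVE
#'
#' Step 1 separates levels with [mpca_fit()]; step 2 runs [jive_fit()] on
#' the retained low-dimensional reconstruction of each level (scores times
#' loadings, split back into the physical-activity and gait column
#' blocks), with ranks either given as `c(r, r1, r2)` or selected by
#' [jive_rank_select()]. The level summary reports, per level, the MPCA
#' level share of total variation and the joint/individual fractions of
#' that level's total variation (so the residual column absorbs both JIVE
#' residual and MPCA truncation).
#'
#' @param decomp a [anova_decompose()] result.
#' @param retained_fraction MPCA retention threshold.
#' @param ranks_between,ranks_within integer vectors `c(r, r1, r2)` or
#'   `"auto"`.
#' @param n_perm,seed permutation settings for `"auto"` rank selection.
#' @param mpca_method passed to [mpca_fit()].
#' @param tol convergence tolerance forwarded to [jive_fit()].
#' @return an `ml_jive_model`: `mpca`, `between_jive`, `within_jive`,
#'   `ranks` (per level), `level_table` (long-format data.frame) and
#'   `level_fractions` (named list used by the table).
#' @export
ml_jive <- function(decomp, retained_fraction = 0.9,
                    ranks_between = "auto", ranks_within = "auto",
                    n_perm = 100L, seed = 1L,
                    mpca_method = c("moment", "empirical"), tol = 1e-9) {
  mpca <- mpca_fit(decomp, retained_fraction, match.arg(mpca_method))
  fit_level <- function(level) {
    scores <- if (level == "between") mpca$between_scores else
      mpca$within_scores
    comps <- if (level == "between") mpca$between_components else
      mpca$within_components
    raw <- if (level == "between") decomp$between else decomp$within
    ranks <- if (level == "between") ranks_between else ranks_within
    recon <- scores %*% t(comps)
    b <- block_split(recon, decomp$pa_features, decomp$gait_features)
    xb <- t(b$x); yb <- t(b$y)  # features x samples
    if (identical(ranks, "auto")) {
      rs <- jive_rank_select(xb, yb, n_perm = n_perm, alpha = 0.05,
                             seed = seed)
      ranks <- c(rs$r, rs$r1, rs$r2)
    }
    fit <- jive_fit(xb, yb, ranks[1L], ranks[2L], ranks[3L], tol = tol)
    # level fractions in the ANOVA sums-of-squares convention: between-level
    # rows are weighted by the subject's day count, within-level rows not
    wts <- if (level == "between") as.vector(decomp$n_days) else
      rep(1, nrow(raw))
    total_level <- sum(raw^2 * wts)
    jmat <- t(rbind(fit$joint_blocks$J1, fit$joint_blocks$J2))
    amat <- t(rbind(fit$individual_blocks$A1, fit$individual_blocks$A2))
    ssJ <- sum(jmat^2 * wts)
    ssA <- sum(amat^2 * wts)
    list(fit = fit, ranks = ranks,
         fractions = c(joint = ssJ / total_level,
                       individual = ssA / total_level,
                       residual = 1 - (ssJ + ssA) / total_level))
  }
  bt <- fit_level("between")
  wt <- fit_level("within")
  lf <- list(
    mpca = mpca$level_variance_fractions,
    between = bt$fractions, within = wt$fractions,
    between_shares = list(
      joint = bt$fit$variance_table$joint_share,
      individual = bt$fit$variance_table$individual_share),
    within_shares = list(
      joint = wt$fit$variance_table$joint_share,
      individual = wt$fit$variance_table$individual_share))
  level_table <- data.frame(
    level = c("between", "within",
              rep(c("between", "between", "within", "within"), each = 3L)),
    row = c("mpca_level_fraction", "mpca_level_fraction",
            rep(c("explained_variation", "gait", "PA"), 4L)),
    component = c("level", "level",
                  rep(c("joint", "individual"), each = 3L),
                  rep(c("joint", "individual"), each = 3L)),
    value = c(
      lf$mpca[["between"]], lf$mpca[["within"]],
      lf$between[["joint"]], lf$between_shares$joint[["gait"]],
      lf$between_shares$joint[["PA"]],
      lf$between[["individual"]], lf$between_shares$individual[["gait"]],
      lf$between_shares$individual[["PA"]],
      lf$within[["joint"]], lf$within_shares$joint[["gait"]],
      lf$within_shares$joint[["PA"]],
      lf$within[["individual"]], lf$within_shares$individual[["gait"]],
      lf$within_shares$individual[["PA"]]),
    stringsAsFactors = FALSE)
  structure(list(
    mpca = mpca, between_jive = bt$fit, within_jive = wt$fit,
    ranks = list(between = bt$ranks, within = wt$ranks),
    level_fractions = lf, level_table = level_table
  ), class = "ml_jive_model")
}

#' Correlations between original features and multilevel JIVE scores
#'
#' For each level, the Pearson correlation of every feature's level effect
#' (its column of the between or within matrix) with each JIVE score
#' vector at that level (joint scores first, then the per-block individual
#' scores), with two-sided p-values and significance stars at `alpha`.
#'
#' @param model an [ml_jive()] result.
#' @param decomp the matching [anova_decompose()] result.
#' @param alpha significance level for the stars.
#' @return list with elements `between` and `within`, each a list of
#'   matrices `r`, `p`, `stars` ((P+Q) x (r + r1 + r2)).
#' @export
score_feature_correlations <- function(model, decomp, alpha = 0.05) {
  level_tab <- function(fit, effect) {
    sc <- t(fit$joint_scores)
    if (ncol(sc)) colnames(sc) <- paste0("joint", seq_len(ncol(sc)))
    s1 <- t(fit$individual_scores$PA)
    if (ncol(s1)) colnames(s1) <- paste0("PA_ind", seq_len(ncol(s1)))
    s2 <- t(fit$individual_scores$gait)
    if (ncol(s2)) colnames(s2) <- paste0("gait_ind", seq_len(ncol(s2)))
    scores <- cbind(sc, s1, s2)
    cp <- cor_matrix_with_p(effect, scores)
    stars <- ifelse(cp$p < alpha, "*", "")
    dimnames(stars) <- dimnames(cp$r)
    list(r = cp$r, p = cp$p, stars = stars)
  }
  list(between = level_tab(model$between_jive, decomp$between),
       within = level_tab(model$within_jive, decomp$within))
}

#' Cross-model component score comparison
#'
#' Correlates the first (up to) two component score vectors of a
#' collection of fitted one-level and multilevel PLS/JIVE models, aligning
#' everything to the subject grain: observation-level score vectors are
#' averaged per subject, subject-level scores are used as-is.
#'
#' @param scores named list; each element is either a subject-grain matrix
#'   (n x k, rows in subject order) or a list `list(scores = N x k,
#'   subjects = character N)` for observation-grain scores.
#' @param subject_ids reference subject ordering.
#' @param max_components per-model cap (default 2).
#' @return list with `correlation` (signed) and `abs_correlation`
#'   matrices, labelled `<name>.PC<k>`.
#' @export
compare_components <- function(scores, subject_ids, max_components = 2L) {
  cols <- list()
  for (nm in names(scores)) {
    el <- scores[[nm]]
    if (is.list(el) && !is.null(el$subjects)) {
      m <- as.matrix(el$scores)
      if (!any(el$subjects %in% subject_ids)) {
        mmj_stop("disjoint subjects: cannot align score grains",
                 "mmjive_input_error")
      }
      g <- factor(el$subjects, levels = subject_ids)
      m <- rowsum(m, g) / as.vector(table(g))
    } else {
      m <- as.matrix(el)
      if (nrow(m) != length(subject_ids)) {
        mmj_stop(sprintf("model '%s': subject-grain scores must have %d rows",
                         nm, length(subject_ids)), "mmjive_input_error")
      }
    }
    for (k in seq_len(min(ncol(m), max_components))) {
      cols[[sprintf("%s.PC%d", nm, k)]] <- m[, k]
    }
  }
  m <- do.call(cbind, cols)
  cc <- stats::cor(m)
  list(correlation = cc, abs_correlation = abs(cc))
}
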