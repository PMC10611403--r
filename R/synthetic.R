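#' Specification for the synthetic two-domain panel generator
#'
#' Describes a repeated-measures world with planted low-rank joint and
#' individual structure at the between-subject and within-subject levels.
#' Defaults emulate the free-living wrist/lumbar accelerometry study shape
#' this package targets: 65 subjects, 8.78 (+/- 1.86) valid days each, 13
#' physical-activity and 11 gait features, rank-1 joint and rank-2
#' individual structures at both levels, between-level share 0.46 of total
#' variance and per-level joint shares 0.53 (between) and 0.45 (within).
#'
#' Variance accounting: with `v = noise_sd^2`, the total variance splits
#' into signal 1 and residual `v`, so the residual fraction of each level is
#' `v / (1 + v)`. `var_between` is the fraction of *total* variance (signal
#' plus residual) carried by the between level; `var_joint_b` /
#' `var_joint_w` are the fractions of each level's total carried by the
#' joint structure; the individual structure absorbs the remainder
#' (`1 - var_joint - v/(1+v)`), split equally over the blocks that have a
#' positive individual rank. All structure components and both residual
#' matrices are rescaled to hit their target sums of squares exactly, so
#' the realized variance partition equals the requested one by
#' construction.
#'
#' @param n_subjects number of subjects.
#' @param days_mean,days_sd per-subject day counts are drawn as
#'   `round(Normal(days_mean, days_sd))` clipped to `>= 1`.
#' @param P,Q block widths (physical-activity / gait feature counts).
#' @param r_b,r1_b,r2_b between-level joint and per-block individual ranks.
#' @param r_w,r1_w,r2_w within-level ranks.
#' @param var_between fraction of total variance at the between level.
#' @param var_joint_b,var_joint_w per-level joint variance fractions.
#' @param noise_sd residual standard deviation on the z-scale.
#' @param seed integer RNG seed.
#' @return a validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_subjects = 65, days_mean = 8.78,
                           days_sd = 1.86, P = 13, Q = 11,
                           r_b = 1, r1_b = 2, r2_b = 2,
                           r_w = 1, r1_w = 2, r2_w = 2,
                           var_between = 0.46,
                           var_joint_b = 0.53, var_joint_w = 0.45,
                           noise_sd = 0.5, seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects), days_mean = days_mean,
               days_sd = days_sd, P = as.integer(P), Q = as.integer(Q),
               r_b = as.integer(r_b), r1_b = as.integer(r1_b),
               r2_b = as.integer(r2_b), r_w = as.integer(r_w),
               r1_w = as.integer(r1_w), r2_w = as.integer(r2_w),
               var_between = var_between, var_joint_b = var_joint_b,
               var_joint_w = var_joint_w, noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(s) {
  ranks <- c(s$r_b, s$r1_b, s$r2_b, s$r_w, s$r1_w, s$r2_w)
  if (any(ranks < 0L)) mmj_stop("ranks must be >= 0", "mmjive_spec_error")
  if (s$n_subjects < 2L || s$P < 1L || s$Q < 1L) {
    mmj_stop("need n_subjects >= 2 and P, Q >= 1", "mmjive_spec_error")
  }
  K <- s$P + s$Q
  if (s$r_b + max(s$r1_b, s$r2_b) > min(s$n_subjects, K)) {
    mmj_stop("between-level ranks infeasible for n_subjects and P+Q",
             "mmjive_spec_error")
  }
  if (s$r1_b > s$P || s$r1_w > s$P || s$r2_b > s$Q || s$r2_w > s$Q) {
    mmj_stop("individual rank exceeds its block width", "mmjive_spec_error")
  }
  fr <- c(s$var_between, s$var_joint_b, s$var_joint_w)
  if (any(fr < 0) || any(fr > 1)) {
    mmj_stop("variance fractions must lie in [0, 1]", "mmjive_spec_error")
  }
  if (s$noise_sd < 0) mmj_stop("noise_sd must be >= 0", "mmjive_spec_error")
  v <- s$noise_sd^2
  resid_frac <- v / (1 + v)
  for (lv in c("b", "w")) {
    vj <- if (lv == "b") s$var_joint_b else s$var_joint_w
    rj <- s[[paste0("r_", lv)]]
    r1 <- s[[paste0("r1_", lv)]]
    r2 <- s[[paste0("r2_", lv)]]
    lvl_share <- if (lv == "b") s$var_between else 1 - s$var_between
    if (lvl_share == 0) next
    ind_frac <- 1 - vj - resid_frac
    if (ind_frac < -1e-12) {
      mmj_stop(sprintf(
        "level '%s': joint fraction %.3f plus residual fraction %.3f exceed 1",
        lv, vj, resid_frac), "mmjive_spec_error")
    }
    if (rj == 0L && vj > 0) {
      mmj_stop(sprintf("level '%s': joint rank 0 but joint fraction > 0", lv),
               "mmjive_spec_error")
    }
    if (r1 == 0L && r2 == 0L && ind_frac > 1e-12 && s$noise_sd == 0) {
      mmj_stop(sprintf(paste(
        "level '%s': individual ranks are 0, the implied individual",
        "fraction %.3f > 0 and noise_sd = 0 leaves no residual to absorb",
        "it"), lv, ind_frac), "mmjive_spec_error")
    }
  }
  invisible(s)
}

# Center a matrix column-wise: within the groups of `group` (plain means,
# so each subject's rows sum to zero exactly, matching the ANOVA within
# definition), or by the w-weighted grand mean (so expanded between-level
# columns have zero mean over subject-days).
center_cols <- function(m, w = NULL, group = NULL) {
  if (!is.null(group)) {
    return(m - apply(m, 2L, function(col) stats::ave(col, group)))
  }
  ww <- if (is.null(w)) rep(1, nrow(m)) else w
  sweep(m, 2L, colSums(m * ww) / sum(ww), `-`)
}

# Project the columns of s off the column space of `ortho` under the
# weighted inner product diag(w). Both s and ortho are assumed centered in
# the same scheme, which the projection preserves. Rank-deficient or zero
# columns in `ortho` are dropped.
project_off_weighted <- function(s, ortho, w = NULL) {
  if (!is.null(ortho)) {
    ortho <- ortho[, colSums(ortho^2) > 0, drop = FALSE]
  }
  if (is.null(ortho) || ncol(ortho) == 0L) return(s)
  ww <- if (is.null(w)) rep(1, nrow(s)) else w
  rw <- sqrt(ww)
  dec <- qr(ortho * rw)
  q <- qr.Q(dec)[, seq_len(dec$rank), drop = FALSE]
  s - (q %*% (t(q) %*% (s * rw))) / rw
}

# draw a centered score matrix (rows x r), centered within `group` or by
# the weighted grand mean, projected off `ortho` under diag(w), then scaled
# column-wise so the weighted sum of squares of each column equals
# ss_target / r. All planted components built this way are exactly
# orthogonal, making the planted variance partition exact.
draw_scores <- function(rows, r, ss_target, w = NULL, group = NULL,
                        ortho = NULL) {
  if (r == 0L || ss_target <= 0) return(matrix(0, rows, r))
  s <- matrix(stats::rnorm(rows * r), rows, r)
  s <- center_cols(s, w = w, group = group)
  s <- project_off_weighted(s, ortho, w = w)
  ww <- if (is.null(w)) rep(1, rows) else w
  ss <- colSums(s^2 * ww)
  sweep(s, 2L, sqrt((ss_target / r) / ss), `*`)
}

# block-confined orthonormal loadings: nonzero only on `idx` rows of K
block_loadings <- function(K, idx, r) {
  if (r == 0L) return(matrix(0, K, r))
  l <- matrix(0, K, r)
  l[idx, ] <- orthonormalize(matrix(stats::rnorm(length(idx) * r),
                                    length(idx), r))
  l
}

# iid noise matrix, centered like the level it belongs to, projected off
# the level's score columns (exact component orthogonality), and scaled to
# an exact weighted sum of squares
draw_noise <- function(rows, K, ss_target, sd0, w = NULL, group = NULL,
                       ortho = NULL) {
  if (ss_target <= 0 || sd0 <= 0) return(matrix(0, rows, K))
  e <- matrix(stats::rnorm(rows * K), rows, K)
  e <- center_cols(e, w = w, group = group)
  e <- project_off_weighted(e, ortho, w = w)
  ww <- if (is.null(w)) 1 else w
  e * sqrt(ss_target / sum(e^2 * ww))
}

synthetic_feature_names <- function(P, Q) {
  ref <- wearable_feature_names()
  pa <- if (P == length(ref$pa)) ref$pa else sprintf("pa_%02d", seq_len(P))
  gait <- if (Q == length(ref$gait)) ref$gait else
    sprintf("gait_%02d", seq_len(Q))
  list(pa = pa, gait = gait)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a multilevel two-domain feature panel
#'
#' Forward model of the between/within ANOVA decomposition: each
#' subject-day observation is `grand mean + u_i + w_ij`, where the
#' between-subject effect `u_i` and the within-subject effect `w_ij` each
#' consist of a joint low-rank structure spanning both feature blocks, a
#' block-confined individual structure per block, and level residual noise.
#' Individual scores are projected off the joint scores at each level
#' (JIVE's identifiability constraint) and within-level components are
#' centred within subject, so the planted level/component variance
#' partition is exact under the day-count-weighted sums of squares of the
#' ANOVA decomposition.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `panel` (a [feature_panel()]) and `truth`
#'   (a `synthetic_truth`: loadings, scores, expanded component matrices,
#'   planted ranks and the realized variance fraction table).
#' @export
simulate_multilevel <- function(spec) {
  validate_synthetic_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    K <- spec$P + spec$Q
    nm <- synthetic_feature_names(spec$P, spec$Q)
    n_days <- pmax(1L, as.integer(round(stats::rnorm(
      n, spec$days_mean, spec$days_sd))))
    N <- sum(n_days)
    subj <- rep(sprintf("S%03d", seq_len(n)), n_days)
    subj_f <- factor(subj, levels = unique(subj))
    day <- unlist(lapply(n_days, seq_len), use.names = FALSE)

    v <- spec$noise_sd^2
    total_ss <- N * K * (1 + v)
    resid_frac <- v / (1 + v)
    idx_pa <- seq_len(spec$P)
    idx_gait <- spec$P + seq_len(spec$Q)

    build_level <- function(level) {
      between <- level == "between"
      share <- if (between) spec$var_between else 1 - spec$var_between
      vj <- if (between) spec$var_joint_b else spec$var_joint_w
      rj <- if (between) spec$r_b else spec$r_w
      r1 <- if (between) spec$r1_b else spec$r1_w
      r2 <- if (between) spec$r2_b else spec$r2_w
      level_ss <- share * total_ss
      joint_ss <- vj * level_ss
      ind_ss <- max(0, (1 - vj - resid_frac)) * level_ss
      noise_ss <- resid_frac * level_ss
      if (r1 == 0L && r2 == 0L) {
        # no individual structure to carry this variance: the residual
        # absorbs it (validated against noise_sd = 0 in the spec check)
        noise_ss <- noise_ss + ind_ss
        ind_ss <- 0
      }
      w1 <- as.numeric(r1 > 0L)
      w2 <- as.numeric(r2 > 0L)
      wsum <- max(1, w1 + w2)
      rows <- if (between) n else N
      wts <- if (between) n_days else NULL
      grp <- if (between) NULL else subj_f
      L_j <- if (rj > 0L) {
        orthonormalize(matrix(stats::rnorm(K * rj), K, rj))
      } else matrix(0, K, 0L)
      S_j <- draw_scores(rows, rj, joint_ss, w = wts, group = grp)
      L_1 <- block_loadings(K, idx_pa, r1)
      L_2 <- block_loadings(K, idx_gait, r2)
      # individual scores are made orthogonal to the joint scores both in
      # the day-count-weighted inner product (exact sums-of-squares
      # planting) and in the plain one (JIVE's row-orthogonality
      # identifiability); at the within level the two coincide
      # the constant column keeps the projection inside the
      # weighted-centered subspace (S_j / wts alone is not W-centered)
      ortho_j <- if (between && ncol(S_j)) {
        cbind(rep(1, rows), S_j, S_j / wts)
      } else {
        S_j
      }
      S_1 <- draw_scores(rows, r1, ind_ss * w1 / wsum, w = wts, group = grp,
                         ortho = ortho_j)
      S_2 <- draw_scores(rows, r2, ind_ss * w2 / wsum, w = wts, group = grp,
                         ortho = ortho_j)
      eps <- draw_noise(rows, K, noise_ss, spec$noise_sd, w = wts,
                        group = grp, ortho = cbind(S_j, S_1, S_2))
      joint <- S_j %*% t(L_j)
      individual <- S_1 %*% t(L_1) + S_2 %*% t(L_2)
      list(joint_loadings = L_j, joint_scores = S_j,
           ind_loadings = list(pa = L_1, gait = L_2),
           ind_scores = list(pa = S_1, gait = S_2),
           joint = joint, individual = individual, noise = eps,
           target = c(level = share, joint = joint_ss / total_ss,
                      individual = ind_ss / total_ss,
                      residual = noise_ss / total_ss))
    }

    b <- build_level("between")
    w <- build_level("within")
    expand <- function(m) m[as.integer(subj_f), , drop = FALSE]
    z <- expand(b$joint + b$individual + b$noise) +
      w$joint + w$individual + w$noise
    colnames(z) <- c(nm$pa, nm$gait)

    data <- data.frame(subject = subj, day = day, check.names = FALSE)
    data <- cbind(data, as.data.frame(z, optional = TRUE))
    panel <- feature_panel(data, nm$pa, nm$gait)

    ss_frac <- function(m, wts = NULL) {
      if (is.null(wts)) sum(m^2) / total_ss else
        sum(m^2 * wts) / total_ss
    }
    realized <- data.frame(
      level = rep(c("between", "within"), each = 3L),
      component = rep(c("joint", "individual", "residual"), 2L),
      requested = c(b$target[c("joint", "individual", "residual")],
                    w$target[c("joint", "individual", "residual")]),
      realized = c(ss_frac(b$joint, n_days), ss_frac(b$individual, n_days),
                   ss_frac(b$noise, n_days), ss_frac(w$joint),
                   ss_frac(w$individual), ss_frac(w$noise)),
      stringsAsFactors = FALSE)

    truth <- structure(list(
      between = b, within = w, n_days = n_days,
      ranks = list(between = c(joint = spec$r_b, pa = spec$r1_b,
                               gait = spec$r2_b),
                   within = c(joint = spec$r_w, pa = spec$r1_w,
                              gait = spec$r2_w)),
      variance_fractions = realized, spec = spec,
      subject_index = as.integer(subj_f)
    ), class = "synthetic_truth")
    list(panel = panel, truth = truth)
  })
}

#' Simulate a one-level two-block matrix
#'
#' Single-level forward model of the joint-and-individual decomposition:
#' the n x (P+Q) subject-level matrix is `joint + individual + residual`
#' with planted ranks `(r_b, r1_b, r2_b)` and joint fraction `var_joint_b`
#' of the total variance; the residual fraction is
#' `noise_sd^2 / (1 + noise_sd^2)`.
#'
#' @param spec a [synthetic_spec()]; only the between-level ranks,
#'   `var_joint_b`, `noise_sd`, `n_subjects`, `P`, `Q` and `seed` are used.
#' @return list with `means` (a `subject_means_matrix`) and `truth`.
#' @export
simulate_one_level <- function(spec) {
  validate_synthetic_spec(spec)
  with_seed(spec$seed + 1L, {
    n <- spec$n_subjects
    K <- spec$P + spec$Q
    nm <- synthetic_feature_names(spec$P, spec$Q)
    v <- spec$noise_sd^2
    total_ss <- n * K * (1 + v)
    resid_frac <- v / (1 + v)
    joint_ss <- spec$var_joint_b * total_ss
    ind_ss <- max(0, 1 - spec$var_joint_b - resid_frac) * total_ss
    noise_ss <- resid_frac * total_ss
    if (spec$r1_b == 0L && spec$r2_b == 0L) {
      noise_ss <- noise_ss + ind_ss
      ind_ss <- 0
    }
    w1 <- as.numeric(spec$r1_b > 0L)
    w2 <- as.numeric(spec$r2_b > 0L)
    wsum <- max(1, w1 + w2)
    idx_pa <- seq_len(spec$P)
    idx_gait <- spec$P + seq_len(spec$Q)
    L_j <- if (spec$r_b > 0L) {
      orthonormalize(matrix(stats::rnorm(K * spec$r_b), K, spec$r_b))
    } else matrix(0, K, 0L)
    S_j <- draw_scores(n, spec$r_b, joint_ss)
    L_1 <- block_loadings(K, idx_pa, spec$r1_b)
    L_2 <- block_loadings(K, idx_gait, spec$r2_b)
    S_1 <- draw_scores(n, spec$r1_b, ind_ss * w1 / wsum, ortho = S_j)
    S_2 <- draw_scores(n, spec$r2_b, ind_ss * w2 / wsum, ortho = S_j)
    eps <- draw_noise(n, K, noise_ss, spec$noise_sd,
                      ortho = cbind(S_j, S_1, S_2))
    joint <- S_j %*% t(L_j)
    individual <- S_1 %*% t(L_1) + S_2 %*% t(L_2)
    vals <- joint + individual + eps
    colnames(vals) <- c(nm$pa, nm$gait)
    means <- structure(list(
      subject_ids = sprintf("S%03d", seq_len(n)),
      values = vals, pa_features = nm$pa, gait_features = nm$gait,
      n_days = stats::setNames(rep(1L, n), sprintf("S%03d", seq_len(n)))
    ), class = "subject_means_matrix")
    realized <- data.frame(
      level = "one_level",
      component = c("joint", "individual", "residual"),
      requested = c(joint_ss, ind_ss, noise_ss) / total_ss,
      realized = c(sum(joint^2), sum(individual^2), sum(eps^2)) / total_ss,
      stringsAsFactors = FALSE)
    truth <- structure(list(
      joint_loadings = L_j, joint_scores = S_j,
      ind_loadings = list(pa = L_1, gait = L_2),
      ind_scores = list(pa = S_1, gait = S_2),
      joint = joint, individual = individual, noise = eps,
      ranks = c(joint = spec$r_b, pa = spec$r1_b, gait = spec$r2_b),
      variance_fractions = realized, spec = spec
    ), class = "synthetic_truth")
    list(means = means, truth = truth)
  })
}

#' Realized versus requested variance fractions
#'
#' Recomputes, from a generator output pair, the realized sum-of-squares
#' fraction of every planted component (using day-count weighting for
#' between-level components) and tabulates it against the requested
#' fraction.
#'
#' @param x the `panel` (or one-level `means`) from a generator call.
#' @param truth the matching `synthetic_truth`.
#' @return data.frame with columns `level`, `component`, `requested`,
#'   `realized`.
#' @export
empirical_variance_report <- function(x, truth) {
  if (!inherits(truth, "synthetic_truth")) {
    mmj_stop("truth must be a synthetic_truth", "mmjive_input_error")
  }
  nrow_x <- if (inherits(x, "feature_panel")) x$N else nrow(x$values)
  nrow_truth <- if (!is.null(truth$within)) {
    nrow(truth$within$joint)
  } else {
    nrow(truth$joint)
  }
  if (nrow_x != nrow_truth) {
    mmj_stop("panel and truth shapes do not match", "mmjive_input_error")
  }
  truth$variance_fractions
}
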