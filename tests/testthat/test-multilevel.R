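test_that("anova_decompose matches the hand-evaluated example", {
  # subjects A = [1, 3], B = [5, 7]: mu = 4, between (-2, +2),
  # within (-1, +1, -1, +1)
  df <- data.frame(subject = c("A", "A", "B", "B"), day = c(1L, 2L, 1L, 2L),
                   p1 = c(1, 3, 5, 7), g1 = c(0, 0.5, 1, 1.5))
  d <- anova_decompose(feature_panel(df, "p1", "g1"))
  expect_equal(unname(d$grand_mean[["p1"]]), 4)
  expect_equal(unname(d$between[, "p1"]), c(-2, 2))
  expect_equal(unname(d$within[, "p1"]), c(-1, 1, -1, 1))
  expect_equal(unname(d$sums_of_squares$per_column["between", "p1"]), 16)
  expect_equal(unname(d$sums_of_squares$per_column["within", "p1"]), 4)
})

test_that("anova_decompose identities hold on random panels", {
  p <- random_panel(7, 4, 4, 3, seed = 5)
  d <- anova_decompose(p)
  vals <- panel_matrix(p)
  rec <- sweep(d$between[d$subject_index, ] + d$within, 2, -d$grand_mean)
  expect_lt(max(abs(vals - rec)), 1e-10)
  expect_lt(max(abs(rowsum(d$within, d$subject_index))), 1e-10)
  ss <- d$sums_of_squares$per_column
  expect_lt(max(abs(ss["total", ] - ss["between", ] - ss["within", ])), 1e-8)

  # one day per subject: within identically zero
  p1 <- random_panel(5, 1, 3, 2, seed = 6)
  expect_equal(max(abs(anova_decompose(p1)$within)), 0)
})

test_that("mpca_fit recovers the planted between fraction", {
  spec <- synthetic_spec(n_subjects = 300, var_between = 0.46, seed = 19)
  sim <- simulate_multilevel(spec)
  mp <- mpca_fit(anova_decompose(sim$panel))
  expect_lt(abs(mp$level_variance_fractions[["between"]] - 0.46), 0.04)
  # loadings orthonormal; level fractions in [0,1] summing to <= 1
  expect_equal(crossprod(mp$between_components),
               diag(ncol(mp$between_components)), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(mp$level_variance_fractions >= 0 &
                    mp$level_variance_fractions <= 1))
  expect_lte(sum(mp$level_variance_fractions), 1 + 1e-10)
})

test_that("mpca_fit degenerate and error cases", {
  # within-level signal ~ zero: within fraction < 0.02 under tiny noise
  spec <- synthetic_spec(n_subjects = 80, r_w = 0, r1_w = 0, r2_w = 0,
                         var_between = 1, var_joint_w = 0, noise_sd = 1e-3,
                         seed = 23)
  sim <- simulate_multilevel(spec)
  mp <- mpca_fit(anova_decompose(sim$panel))
  expect_lt(mp$level_variance_fractions[["within"]], 0.02)

  # retained_fraction = 1: projection reconstructs both level matrices
  p <- random_panel(8, 5, 3, 2, seed = 2)
  d <- anova_decompose(p)
  mp2 <- mpca_fit(d, retained_fraction = 1, method = "empirical")
  rec_b <- mp2$between_scores %*% t(mp2$between_components)
  rec_w <- mp2$within_scores %*% t(mp2$within_components)
  expect_lt(max(abs(rec_b - d$between)), 1e-8)
  expect_lt(max(abs(rec_w - d$within)), 1e-8)

  # all subjects single-day: moments cannot separate levels
  p1 <- random_panel(5, 1, 3, 2, seed = 3)
  expect_error(mpca_fit(anova_decompose(p1)), class = "mmjive_input_error")
})

test_that("mpca level fractions are consistent with the ANOVA sums of squares", {
  spec <- synthetic_spec(n_subjects = 500, seed = 29)
  sim <- simulate_multilevel(spec)
  d <- anova_decompose(sim$panel)
  ss <- d$sums_of_squares$overall
  anova_frac <- ss[["between"]] / ss[["total"]]
  # the empirical mode is exactly the ANOVA accounting
  mp_emp <- mpca_fit(d, method = "empirical")
  expect_lt(abs(mp_emp$level_variance_fractions[["between"]] - anova_frac),
            1e-8)
  # the moment mode carries the exact-ANOVA finite-day correction, so it
  # agrees with the ANOVA accounting up to sampling error
  mp_mom <- mpca_fit(d, method = "moment")
  expect_lt(abs(mp_mom$level_variance_fractions[["between"]] - anova_frac),
            0.02)
})

test_that("ml_pls fits both levels and matches the SVD oracle", {
  spec <- synthetic_spec(n_subjects = 200, var_between = 0.5,
                         var_joint_b = 0.5, var_joint_w = 0.5, seed = 41)
  sim <- simulate_multilevel(spec)
  d <- anova_decompose(sim$panel)
  mp <- ml_pls(d, 2)
  # oracle: component-1 weights from SVD of the between cross-block matrix
  b <- sweep(d$between, 2, colMeans(d$between))
  xb <- b[, d$pa_features]; yb <- b[, d$gait_features]
  s <- svd(crossprod(xb, yb))
  err <- min(max(abs(mp$between$x_weights[, 1] - s$u[, 1])),
             max(abs(mp$between$x_weights[, 1] + s$u[, 1])))
  expect_lt(err, 1e-8)
  expect_identical(mp$loading_tables$between$feature,
                   c(d$pa_features, d$gait_features))

  # identical planted joint direction at both levels: weights correlate
  spec2 <- synthetic_spec(n_subjects = 200, var_between = 0.5,
                          var_joint_b = 0.8, var_joint_w = 0.8,
                          r1_b = 0, r2_b = 0, r1_w = 0, r2_w = 0,
                          noise_sd = sqrt(0.2 / 0.8), seed = 43)
  sim2 <- simulate_multilevel(spec2)
  # overwrite within joint loading with the between one for a shared
  # direction, then rebuild the panel matrix
  tr <- sim2$truth
  shared <- tr$between$joint_loadings
  w_joint <- tr$within$joint_scores %*% t(shared)
  vals <- (tr$between$joint + tr$between$individual +
             tr$between$noise)[tr$subject_index, ] +
    w_joint + tr$within$individual + tr$within$noise
  df <- sim2$panel$data
  df[, c(sim2$panel$pa_features, sim2$panel$gait_features)] <- vals
  p2 <- feature_panel(df, sim2$panel$pa_features, sim2$panel$gait_features)
  mp2 <- ml_pls(anova_decompose(p2), 1)
  cc <- abs(cor(c(mp2$between$x_weights[, 1], mp2$between$y_weights[, 1]),
                c(mp2$within$x_weights[, 1], mp2$within$y_weights[, 1])))
  expect_gt(cc, 0.95)

  # single-day subjects: within fit skipped with a warning
  p1 <- random_panel(8, 1, 3, 2, seed = 4)
  expect_warning(mp1 <- ml_pls(anova_decompose(p1)), "within")
  expect_null(mp1$within)
  expect_s3_class(mp1$between, "pls_model")
})

test_that("ml_jive recovers planted level fractions", {
  spec <- synthetic_spec(n_subjects = 200, var_between = 0.5,
                         var_joint_b = 0.5, var_joint_w = 0.5, seed = 47)
  sim <- simulate_multilevel(spec)
  d <- anova_decompose(sim$panel)
  mj <- ml_jive(d, ranks_between = c(1, 2, 2), ranks_within = c(1, 2, 2))
  lf <- mj$level_fractions
  expect_lt(abs(lf$between[["joint"]] - 0.5), 0.05)
  expect_lt(abs(lf$within[["joint"]] - 0.5), 0.05)
  # planted individual fraction is 1 - 0.5 - 0.2 = 0.3 of each level
  expect_lt(abs(lf$between[["individual"]] - 0.3), 0.05)
  expect_lt(abs(lf$within[["individual"]] - 0.3), 0.05)
  # level table layout
  expect_identical(dim(mj$level_table), c(14L, 4L))
  expect_equal(sum(mj$level_table$value[mj$level_table$row !=
                                          "explained_variation" &
                                        mj$level_table$component == "joint" &
                                        mj$level_table$level == "between"]),
               1)
})

test_that("ml_jive noiseless fixture recovers fractions near-exactly", {
  spec <- synthetic_spec(n_subjects = 100, var_between = 0.5,
                         var_joint_b = 0.6, var_joint_w = 0.4,
                         noise_sd = 0, seed = 53)
  sim <- simulate_multilevel(spec)
  d <- anova_decompose(sim$panel)
  # the empirical MPCA mode is the exact-ANOVA route, so the noiseless
  # fixture is recovered to numerical precision
  mj <- ml_jive(d, retained_fraction = 1,
                ranks_between = c(1, 2, 2), ranks_within = c(1, 2, 2),
                mpca_method = "empirical", tol = 1e-14)
  expect_lt(abs(mj$level_fractions$mpca[["between"]] - 0.5), 0.02)
  expect_lt(abs(mj$level_fractions$between[["joint"]] - 0.6), 1e-6)
  expect_lt(abs(mj$level_fractions$within[["joint"]] - 0.4), 1e-6)
  expect_lt(abs(mj$level_fractions$between[["individual"]] - 0.4), 1e-6)
})

test_that("ml_jive with zero ranks yields zero structure fractions", {
  sim <- simulate_multilevel(synthetic_spec(n_subjects = 40, seed = 3))
  d <- anova_decompose(sim$panel)
  mj <- ml_jive(d, ranks_between = c(0, 0, 0), ranks_within = c(0, 0, 0))
  expect_equal(mj$level_fractions$between[["joint"]], 0)
  expect_equal(mj$level_fractions$within[["individual"]], 0)
  expect_equal(mj$level_fractions$between[["residual"]], 1)
})

test_that("score_feature_correlations has the right shape and extremes", {
  spec <- synthetic_spec(n_subjects = 80, seed = 59)
  sim <- simulate_multilevel(spec)
  d <- anova_decompose(sim$panel)
  mj <- ml_jive(d, ranks_between = c(1, 1, 2), ranks_within = c(1, 1, 2))
  sfc <- score_feature_correlations(mj, d)
  expect_identical(dim(sfc$between$r), c(24L, 4L))  # (P+Q) x (1+1+2)
  expect_identical(dim(sfc$within$r), c(24L, 4L))
  expect_identical(sfc$between$stars[sfc$between$p < 0.05][1], "*")

  # feature constructed equal to the joint score: correlation 1
  d2 <- d
  d2$between[, 1] <- t(mj$between_jive$joint_scores)[, 1]
  sfc2 <- score_feature_correlations(mj, d2)
  expect_equal(unname(sfc2$between$r[1, "joint1"]), 1)
})

test_that("compare_components aligns grains and handles sign flips", {
  spec <- synthetic_spec(n_subjects = 200, var_between = 0.5,
                         var_joint_b = 0.8, var_joint_w = 0.8,
                         r1_b = 0, r2_b = 0, r1_w = 0, r2_w = 0,
                         noise_sd = sqrt(0.2 / 0.8), seed = 61)
  sim <- simulate_multilevel(spec)
  panel <- sim$panel
  means <- subject_means(scale_panel(panel, "subject_means"))
  blocks <- list(x = means$values[, means$pa_features],
                 y = means$values[, means$gait_features])
  pls1 <- pls_fit(blocks$x, blocks$y, 2)
  d <- anova_decompose(scale_panel(panel, "daily_rows"))
  mj <- ml_jive(d, ranks_between = c(1, 1, 1), ranks_within = c(1, 1, 1))
  obs_subj <- d$subject_ids[d$subject_index]
  cmp <- compare_components(list(
    PLS = pls1$x_scores,
    JIVE.B.JT = t(mj$between_jive$joint_scores),
    JIVE.W.JT = list(scores = t(mj$within_jive$joint_scores),
                     subjects = obs_subj)
  ), means$subject_ids)
  # self-correlation diagonal 1
  expect_equal(unname(diag(cmp$correlation)), rep(1, ncol(cmp$correlation)))
  # strong planted joint signal: one-level PLS PC1 ~ between JIVE joint PC1
  expect_gt(cmp$abs_correlation["PLS.PC1", "JIVE.B.JT.PC1"], 0.9)
  # sign flip leaves absolute correlations unchanged
  cmp2 <- compare_components(list(
    PLS = -pls1$x_scores,
    JIVE.B.JT = t(mj$between_jive$joint_scores)
  ), means$subject_ids)
  expect_equal(cmp2$abs_correlation["PLS.PC1", "JIVE.B.JT.PC1"],
               cmp$abs_correlation["PLS.PC1", "JIVE.B.JT.PC1"])
  expect_equal(cmp2$correlation["PLS.PC1", "JIVE.B.JT.PC1"],
               -cmp$correlation["PLS.PC1", "JIVE.B.JT.PC1"])
  # disjoint subjects cannot be aligned
  expect_error(compare_components(list(
    A = pls1$x_scores,
    B = list(scores = matrix(1, 4, 1), subjects = rep("zz", 4))
  ), means$subject_ids), class = "mmjive_input_error")
})
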