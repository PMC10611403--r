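# Small panel fixtures built in code.

# minimal panel: 2 subjects x 2 days x (2 PA + 1 gait)
tiny_panel <- function(wear = NULL) {
  df <- data.frame(
    subject = c("s1", "s1", "s2", "s2"),
    day = c(1L, 2L, 1L, 2L),
    pa_a = c(1, 2, 3, 4),
    pa_b = c(2, 4, 6, 8),
    gait_a = c(10, 20, 30, 40))
  if (!is.null(wear)) df$wear_hours <- wear
  feature_panel(df, pa_features = c("pa_a", "pa_b"),
                gait_features = "gait_a")
}

# random panel with the given shape, no planted structure
random_panel <- function(n_subj = 5, days = 3, P = 4, Q = 3, seed = 1) {
  set.seed(seed)
  subj <- rep(sprintf("s%02d", seq_len(n_subj)), each = days)
  df <- data.frame(subject = subj, day = rep(seq_len(days), n_subj))
  pa <- sprintf("pa_%d", seq_len(P))
  gait <- sprintf("gait_%d", seq_len(Q))
  for (f in c(pa, gait)) df[[f]] <- rnorm(nrow(df))
  feature_panel(df, pa, gait)
}

expect_frobenius_lt <- function(a, b, tol) {
  expect_lt(sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-300), tol)
}
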