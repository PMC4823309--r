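# Independent brute-force oracles shared across the suite. These deliberately
# avoid the package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# explicit-loop RMSSD
rmssd_loop <- function(rr) {
  acc <- 0
  for (i in 2:length(rr)) acc <- acc + (rr[i] - rr[i - 1])^2
  sqrt(acc / (length(rr) - 1))
}

# brute-force sliding-window counter: advance by (window - overlap) until the
# window no longer fits
window_count_brute <- function(n, window, overlap) {
  step <- window - overlap
  count <- 0L
  s <- 1L
  while (s + window - 1L <= n) {
    count <- count + 1L
    s <- s + step
  }
  count
}

# 2x2 mixed-design interaction F through stats::aov with an Error() stratum
aov_interaction_F <- function(long) {
  long$subject <- factor(long$subject)
  long$group <- factor(long$group)
  long$session <- factor(long$session)
  s <- summary(stats::aov(value ~ group * session + Error(subject / session),
                          data = long))
  s[["Error: subject:session"]][[1]]["group:session", "F value"]
}

# Wilks' Lambda and Rao's F from explicit between/within scatter matrices
wilks_oracle <- function(d, g) {
  d <- as.matrix(d)
  gm <- colMeans(d)
  p <- ncol(d)
  E <- matrix(0, p, p)
  H <- matrix(0, p, p)
  for (lev in unique(g)) {
    sel <- g == lev
    m <- colMeans(d[sel, , drop = FALSE])
    H <- H + sum(sel) * tcrossprod(m - gm)
    E <- E + crossprod(sweep(d[sel, , drop = FALSE], 2, m))
  }
  lam <- det(E) / det(E + H)
  n <- nrow(d)
  list(wilks = lam, F = (1 - lam) / lam * (n - p - 1) / p)
}

# analytic expected-RMSSD-track oracle for deflection-point recovery: builds
# the deterministic beat grid from the generator's trend, the expected
# per-window RMSSD from local increment variances plus trend steps, and the
# expected tail SD of windowed RMSSD at the floor from MA(1) theory
# (SD ~ 0.866 * floor / sqrt(m)); returns the expected crossing window.
oracle_dp <- function(profile, window = 256L, overlap = 192L, k_sd = 3,
                      tail_fraction = 0.3) {
  rr <- c()
  t <- 0
  while (t < profile$duration_s) {
    v <- vagalfc:::rr_trend_ms(profile, t)
    rr <- c(rr, v)
    t <- t + v / 1000
  }
  bt <- c(0, cumsum(rr)) / 1000
  lam <- vagalfc:::local_rmssd_ms(profile, bt[-length(bt)])
  sig2 <- lam^2 / 2
  ed2 <- sig2[-length(sig2)] + sig2[-1] + diff(rr)^2
  n <- length(rr)
  step <- window - overlap
  starts <- seq(1, n - window + 1, by = step)
  ew <- sapply(starts, function(s) sqrt(mean(ed2[s:(s + window - 2)])))
  tm <- sapply(starts, function(s) mean(bt[s:(s + window)]))
  in_tail <- tm >= (1 - tail_fraction) * profile$duration_s
  thr <- mean(ew[in_tail]) + k_sd * 0.866 * profile$rmssd_floor_ms / sqrt(window - 1)
  i <- which(ew < thr)[1]
  list(dp = tm[i], spacing = stats::median(diff(tm)), threshold = thr)
}

# long-format scalar cohort with a planted group-specific T1 shift
make_scalar_cohort <- function(n_per_group, delta, sigma, seed) {
  set.seed(seed)
  n <- 2 * n_per_group
  grp <- rep(c("exercise", "control"), each = n_per_group)
  t0 <- 100 + stats::rnorm(n, sd = sigma)
  t1 <- t0 + ifelse(grp == "exercise", delta, 0) + stats::rnorm(n, sd = sigma)
  data.frame(subject = rep(sprintf("s%02d", 1:n), 2),
             group = rep(grp, 2),
             session = rep(c("T0", "T1"), each = n),
             value = c(t0, t1))
}

# small fc_cohort built directly from matrices with an optional planted
# effect block (exercise-group T1 shift on given voxels)
make_fc_cohort <- function(n_per_group, dim, effect_vox = integer(0),
                           delta = 0, sd = 1, seed = 1) {
  set.seed(seed)
  v <- prod(dim)
  n <- 2 * n_per_group
  z0 <- matrix(stats::rnorm(v * n, sd = sd), v, n)
  z1 <- matrix(stats::rnorm(v * n, sd = sd), v, n)
  grp <- factor(rep(c("exercise", "control"), each = n_per_group),
                levels = c("exercise", "control"))
  if (length(effect_vox)) {
    z1[effect_vox, grp == "exercise"] <- z1[effect_vox, grp == "exercise"] + delta
  }
  fc_cohort(z0, z1, grp, dim)
}
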