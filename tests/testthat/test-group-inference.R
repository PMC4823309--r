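test_that("interaction t map: degenerate, antisymmetry and oracle equivalence", {
  # identical maps at both sessions: no change, flat zero t
  z <- matrix(stats::rnorm(24 * 8), 24, 8)
  fc <- fc_cohort(z, z, rep(c("exercise", "control"), each = 4), c(4, 3, 2))
  expect_true(all(interaction_map(fc)$t == 0))

  fcr <- make_fc_cohort(6, c(4, 3, 2), effect_vox = 1:3, delta = 1, seed = 2)
  tm <- interaction_map(fcr)
  # swapping group labels flips the sign exactly
  fcs <- fc_cohort(fcr$z0, fcr$z1,
                   factor(ifelse(fcr$group == "exercise", "control", "exercise"),
                          levels = c("exercise", "control")),
                   fcr$dim)
  expect_equal(interaction_map(fcs)$t, -tm$t)
  # every voxel matches the brute-force 2x2 mixed ANOVA (F = t^2)
  D <- t(fcr$z1 - fcr$z0)
  for (v in sample(ncol(D), 8)) {
    long <- data.frame(subject = rep(sprintf("s%d", 1:nrow(D)), 2),
                       group = rep(as.character(fcr$group), 2),
                       session = rep(c("T0", "T1"), each = nrow(D)),
                       value = c(fcr$z0[v, ], fcr$z1[v, ]))
    expect_equal(as.numeric(tm$t)[v]^2, aov_interaction_F(long), tolerance = 1e-8)
  }
})

test_that("cluster formation respects threshold, sign and connectivity", {
  dimv <- c(3, 3, 3)
  tm <- array(0, dimv)
  expect_equal(nrow(form_clusters(tm, df = 30)), 0)
  tm[2, 2, 2] <- 10
  tab <- form_clusters(tm, df = 30)
  expect_equal(tab$size_vox, 1)
  expect_equal(tab$peak_stat, 10)
  # two voxels sharing only a corner: one cluster at 26, two at 6
  tm2 <- array(0, dimv)
  tm2[1, 1, 1] <- 8
  tm2[2, 2, 2] <- 9
  expect_equal(nrow(form_clusters(tm2, 30, connectivity = 26)), 1)
  expect_equal(nrow(form_clusters(tm2, 30, connectivity = 6)), 2)
  expect_equal(nrow(form_clusters(tm2, 30, connectivity = 18)), 2)
  # sign segregation: adjacent positive and negative excursions stay separate
  tm3 <- array(0, dimv)
  tm3[1, 1, 1] <- 8
  tm3[2, 1, 1] <- -8
  two <- form_clusters(tm3, 30, sign = "two-sided")
  expect_equal(nrow(two), 2)
  expect_setequal(two$sign, c("pos", "neg"))
  expect_equal(nrow(form_clusters(tm3, 30, sign = "pos")), 1)
})

test_that("tiny cohorts are enumerated exactly with 1/6 granularity", {
  fc <- make_fc_cohort(2, c(3, 3, 2), effect_vox = 1:2, delta = 4, seed = 5)
  res <- permutation_cluster_fwe(fc, n_perm = 1000, seed = 1)
  expect_true(attr(res, "exact"))
  expect_length(attr(res, "null_max_size"), choose(4, 2))
  if (nrow(res)) {
    expect_true(all(abs(res$p_fwe * 6 - round(res$p_fwe * 6)) < 1e-12))
  }
})

test_that("permutation FWE finds a strong planted block and is reproducible", {
  fc <- make_fc_cohort(10, c(6, 6, 4), effect_vox = c(1, 2, 7, 8), delta = 3,
                       sd = 1, seed = 7)
  r1 <- permutation_cluster_fwe(fc, n_perm = 300, seed = 11)
  r2 <- permutation_cluster_fwe(fc, n_perm = 300, seed = 11)
  expect_identical(r1$p_fwe, r2$p_fwe)
  top <- r1[1, ]
  expect_lt(top$p_fwe, 0.05)
  expect_gte(top$size_vox, 3)
  expect_warning(permutation_cluster_fwe(fc, n_perm = 50, seed = 1), "coarse")
})

test_that("post-hoc t tests match stats::t.test and flag degeneracy", {
  set.seed(12)
  x <- stats::rnorm(15); y <- stats::rnorm(15, 0.4)
  pr <- posthoc_t(x, y, "paired")
  tt <- stats::t.test(x, y, paired = TRUE)
  expect_equal(pr$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(pr$p, tt$p.value, tolerance = 1e-12)
  ps <- posthoc_t(x, y, "two-sample", var_equal = TRUE)
  ts <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(ps$t, unname(ts$statistic), tolerance = 1e-12)
  pw <- posthoc_t(x, y, "two-sample", var_equal = FALSE)
  tw <- stats::t.test(x, y)
  expect_equal(pw$t, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(pw$df, unname(tw$parameter), tolerance = 1e-12)
  # identical pairs: zero difference and zero variance
  pz <- posthoc_t(c(1, 2, 3), c(1, 2, 3), "paired")
  expect_true(is.nan(pz$t))
  expect_true(pz$degenerate)
  # constant unit shift: infinite paired t, flagged not crashed
  pi_ <- posthoc_t(c(2, 3, 4), c(1, 2, 3), "paired")
  expect_true(is.infinite(pi_$t))
  expect_true(pi_$degenerate)
  expect_equal(pi_$p, 0)
})

test_that("MANOVA on difference vectors matches the scatter-matrix oracle", {
  set.seed(20)
  # identical groups: Lambda 1, F 0
  d0 <- matrix(stats::rnorm(8 * 3), 8, 3)
  tab0 <- data.frame(subject_id = rep(sprintf("s%d", 1:16), 2),
                     group = rep(rep(c("a", "b"), each = 8), 2),
                     session = rep(c("T0", "T1"), each = 16),
                     hr_bpm = c(rep(0, 16), rbind(d0, d0)[, 1]),
                     rmssd_ms = c(rep(0, 16), rbind(d0, d0)[, 2]),
                     vt_power_w = c(rep(0, 16), rbind(d0, d0)[, 3]))
  m0 <- manova_group_time(tab0)
  expect_equal(m0$wilks, 1, tolerance = 1e-12)
  expect_equal(m0$F, 0, tolerance = 1e-12)
  # random cohorts match the explicit det(E)/det(E+H) oracle
  for (i in 1:10) {
    n <- 17
    g <- rep(c("exercise", "control"), c(9, 8))
    t0v <- matrix(stats::rnorm(n * 3, 50, 5), n, 3)
    d <- matrix(stats::rnorm(n * 3), n, 3)
    d[g == "exercise", 1] <- d[g == "exercise", 1] + 1
    tab <- data.frame(subject_id = rep(sprintf("s%d", 1:n), 2),
                      group = rep(g, 2),
                      session = rep(c("T0", "T1"), each = n),
                      hr_bpm = c(t0v[, 1], t0v[, 1] + d[, 1]),
                      rmssd_ms = c(t0v[, 2], t0v[, 2] + d[, 2]),
                      vt_power_w = c(t0v[, 3], t0v[, 3] + d[, 3]))
    got <- manova_group_time(tab)
    orc <- wilks_oracle(d, g)
    expect_equal(got$wilks, orc$wilks, tolerance = 1e-10)
    expect_equal(got$F, orc$F, tolerance = 1e-10)
  }
  # single variable reduces to the univariate ANOVA F
  m1 <- manova_group_time(tab, variables = "hr_bpm")
  F_uni <- stats::anova(stats::lm(d[, 1] ~ factor(g)))$`F value`[1]
  expect_equal(m1$F, F_uni, tolerance = 1e-10)
})

test_that("delta correlation is exact on a perfect linear relation", {
  fc <- make_fc_cohort(5, c(3, 3, 2), seed = 30)
  vox <- 1:4
  slope <- -0.05
  dscal <- seq_len(5) * 2
  # rebuild z1 so cluster-mean change is exactly linear in the scalar change
  for (i in 1:5) {
    fc$z1[vox, i] <- fc$z0[vox, i] + slope * dscal[i]
  }
  dc <- delta_correlation(fc, vox, dscal)
  expect_equal(dc$r, -1, tolerance = 1e-12)
  expect_equal(dc$n, 5)
  expect_error(delta_correlation(fc, integer(0), dscal), "empty cluster")
  fc2 <- make_fc_cohort(2, c(3, 3, 2), seed = 31)
  expect_error(delta_correlation(fc2, vox, c(1, 2)), "at least 3")
})

test_that("an fc cohort stacked from maps feeds the whole inference chain", {
  ph <- phantom_spec(shape = c(8, 8, 5), n_volumes = 40, coupling_r = 0.3, seed = 2)
  co <- gen_bold_cohort(ph, cohort_spec(n_per_group = 4, seed = 13))
  fc <- cohort_zmaps(co)
  expect_equal(dim(fc$z0), c(prod(ph$shape), 8))
  expect_equal(levels(fc$group), c("exercise", "control"))
  im <- interaction_map(fc)
  expect_equal(im$df, 6)
  expect_true(all(is.finite(im$t)))
})
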