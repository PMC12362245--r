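test_that("Welch t matches the closed form, t.test, and degenerate conventions", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)  # -3.674
  expect_equal(r$df, 4, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.0213)
  # identical groups
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # degenerate conventions: zero variance in both groups
  expect_equal(welch_t(c(0, 0), c(1, 1))$p, 0)
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  # random cases against stats::t.test
  set.seed(31)
  for (i in 1:30) {
    a <- rnorm(sample(2:9, 1)); b <- rnorm(sample(2:9, 1), mean = runif(1, -2, 2))
    ref <- t.test(a, b)
    got <- welch_t(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Wilcoxon rank-sum matches exact enumeration and the corrected approximation", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 2 / choose(6, 3) * 1)        # 2/20 = 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p, 1)  # all tied
  set.seed(32)
  # exact path against wilcox.test exact
  for (i in 1:20) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
    got <- wilcoxon_rank_sum(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$W, unname(ref$statistic))
  }
  # tie path against wilcox.test normal approximation with corrections
  for (i in 1:20) {
    a <- sample(1:4, 8, replace = TRUE); b <- sample(1:4, 9, replace = TRUE)
    got <- wilcoxon_rank_sum(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # exact and approximate p agree closely for n = 8 vs 8
  set.seed(33)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    pex <- wilcoxon_rank_sum(a, b)$p
    pap <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                        correct = TRUE)$p.value)
    expect_lt(abs(pex - pap), 0.02)
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(34)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  # order equivariance
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-15)
})

test_that("expected tests reduce correctly for K = 1 and duplicated instances", {
  cm <- toy_counts(d = 10L, n = 6L, conditions = rep(c("A", "B"), each = 3))
  cd <- sample_compositions(cm, n_instances = 1L, seed = 5L)
  sad <- apply_scale(cd, default_scale(cd, gamma = 0, seed = 5L))
  et1 <- expected_tests(sad, cm$conditions)
  x <- sad[, , 1L]
  p_ref <- apply(x, 1L, function(z) t.test(z[4:6], z[1:3])$p.value)
  expect_equal(et1$ep_t, unname(p_ref), tolerance = 1e-10)
  expect_equal(et1$eq_t, unname(p.adjust(p_ref, "BH")), tolerance = 1e-10)
  # duplicated instance: mean of identical values
  sad2 <- array(c(x, x), dim = c(dim(x), 2L))
  et2 <- expected_tests(sad2, cm$conditions)
  expect_equal(et2$ep_t, et1$ep_t, tolerance = 1e-14)
  expect_equal(et2$eq_w, et1$eq_w, tolerance = 1e-14)
  # expected q never falls below expected p, feature-wise
  expect_true(all(et1$eq_t >= et1$ep_t - 1e-12))
})

test_that("effect sizes honour location invariances and recover a known shift", {
  cond <- factor(rep(c("A", "B"), each = 10), levels = c("A", "B"))
  # constant equal groups: zero difference and effect
  sadc <- array(5, dim = c(3, 20, 4))
  esc <- effect_sizes(sadc, cond, seed = 2L)
  expect_true(all(esc$diff_btw == 0))
  expect_true(all(esc$effect == 0))
  # shifting both groups leaves everything unchanged
  set.seed(41)
  sad <- array(rnorm(30 * 20 * 8), dim = c(30, 20, 8))
  e1 <- effect_sizes(sad, cond, seed = 3L)
  e2 <- effect_sizes(sad + 11.5, cond, seed = 3L)
  expect_equal(e1$diff_btw, e2$diff_btw, tolerance = 1e-9)
  expect_equal(e1$diff_win, e2$diff_win, tolerance = 1e-9)
  expect_equal(e1$effect, e2$effect, tolerance = 1e-9)
  # N(0,1) vs N(2,1): recover difference near 2 with positive effect
  set.seed(42)
  sad2 <- array(NA_real_, dim = c(50, 40, 16))
  cond2 <- factor(rep(c("A", "B"), each = 20), levels = c("A", "B"))
  sad2[, 1:20, ] <- rnorm(50 * 20 * 16)
  sad2[, 21:40, ] <- rnorm(50 * 20 * 16, mean = 2)
  e3 <- effect_sizes(sad2, cond2, seed = 4L)
  expect_true(all(abs(e3$diff_btw - 2) < 0.3 + 0.6))  # per-feature medians
  expect_lt(abs(median(e3$diff_btw) - 2), 0.3)
  expect_true(all(e3$effect > 0))
})

test_that("label swap negates differences and effects but keeps p-values", {
  # spiked data so the effects span a real range, not just pairing noise
  bb <- nb_backbone(D = 80L, n_per_group = 5L, seed = 66L)
  cm <- spike_thinning(bb$counts, tp_fraction = 0.3, effect_sd = 2,
                       seed = 66L)$counts
  rt_ab <- run_da(cm, scale = 0.3, n_instances = 64L, seed = 6L)
  cm_swap <- cm
  cm_swap$conditions <- factor(cm$conditions, levels = c("grpB", "grpA"))
  rt_ba <- run_da(cm_swap, scale = 0.3, n_instances = 64L, seed = 6L)
  expect_equal(rt_ba$ep_t, rt_ab$ep_t, tolerance = 1e-12)
  expect_equal(rt_ba$eq_w, rt_ab$eq_w, tolerance = 1e-12)
  # medians of sign-flipped pairing draws: antisymmetric up to pairing noise
  expect_equal(rt_ba$diff_btw, -rt_ab$diff_btw, tolerance = 0.2)
  expect_gt(cor(rt_ba$effect, -rt_ab$effect), 0.98)
})

test_that("the full pipeline is deterministic and matches an independent CLR oracle at gamma 0", {
  cm <- toy_counts(d = 60L, n = 10L, lambda = 80,
                   conditions = rep(c("ctl", "trt"), each = 5))
  rt1 <- run_da(cm, scale = 0, n_instances = 12L, seed = 17L)
  rt2 <- run_da(cm, scale = 0, n_instances = 12L, seed = 17L)
  expect_identical(rt1, rt2)
  # independent oracle: explicit CLR + per-instance t/wilcoxon + BH, averaged
  cd <- sample_compositions(cm, n_instances = 12L, seed = 17L)
  ep <- eq <- epw <- eqw <- numeric(60)
  for (k in 1:12) {
    clr <- apply(cd$values[, , k], 2L, function(v) log2(v) - mean(log2(v)))
    p <- apply(clr, 1L, function(z) t.test(z[6:10], z[1:5])$p.value)
    pw <- apply(clr, 1L, function(z)
      suppressWarnings(wilcox.test(z[6:10], z[1:5], exact = TRUE)$p.value))
    ep <- ep + p / 12; eq <- eq + p.adjust(p, "BH") / 12
    epw <- epw + pw / 12; eqw <- eqw + p.adjust(pw, "BH") / 12
  }
  expect_equal(rt1$ep_t, unname(ep), tolerance = 1e-9)
  expect_equal(rt1$eq_t, unname(eq), tolerance = 1e-9)
  expect_equal(rt1$ep_w, unname(epw), tolerance = 1e-9)
  expect_equal(rt1$eq_w, unname(eqw), tolerance = 1e-9)
})

test_that("dual cutoff selects on both q-value and difference", {
  rt <- data.frame(feature_id = c("a", "b", "c"),
                   diff_btw = c(2, 0.5, 3),
                   eq_t = c(0.01, 0.01, 0.2),
                   eq_w = c(0.01, 0.01, 0.2))
  expect_identical(dual_cutoff(rt, 0.05, 1.4), "a")
  expect_identical(dual_cutoff(rt, 0.05, 0), c("a", "b"))
  expect_identical(dual_cutoff(rt, 1, 0), c("a", "b", "c"))
  # the conventional 1.4 log2 line is about a 2.6-fold change
  expect_equal(2^1.4, 2.639, tolerance = 5e-4)
})

test_that("null data with scale uncertainty yield no discoveries", {
  # both groups drawn from one distribution; property over seeded runs
  hits <- vapply(1:5, function(s) {
    cm <- toy_counts(d = 500L, n = 16L, lambda = 100, seed = 100L + s,
                     conditions = rep(c("A", "B"), each = 8))
    rt <- run_da(cm, scale = 0.5, n_instances = 24L, seed = s, tests = "t")
    sum(rt$eq_t <= 0.05)
  }, numeric(1))
  expect_true(mean(hits == 0) >= 0.8)
})
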