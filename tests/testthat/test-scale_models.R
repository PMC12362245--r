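test_that("gamma = 0 default scale reproduces the CLR assumption exactly", {
  cm <- toy_counts(d = 10L, n = 6L, conditions = rep(c("A", "B"), each = 3))
  cd <- sample_compositions(cm, n_instances = 12L, seed = 3L)
  sd0 <- default_scale(cd, gamma = 0, seed = 3L)
  expect_identical(unname(sd0$log2_values), unname(-t(cd$log2_geo_mean)))
  # applied: closed-form CLR of a 3-part composition
  comp <- c(0.5, 0.25, 0.25)
  clr <- log2(comp) - mean(log2(comp))
  expect_equal(clr, c(2 / 3, -1 / 3, -1 / 3))
  sad <- apply_scale(cd, sd0)
  k1 <- sad[, , 1L]
  clr1 <- apply(cd$values[, , 1L], 2L, function(v) log2(v) - mean(log2(v)))
  expect_equal(unname(k1), unname(clr1), tolerance = 1e-12)
})

test_that("scale noise has the requested spread and per-column additivity", {
  cm <- toy_counts(d = 8L, n = 5L, conditions = c("A", "A", "A", "B", "B"))
  cd <- sample_compositions(cm, n_instances = 2000L, seed = 5L)
  sdg <- default_scale(cd, gamma = 0.5, seed = 5L)
  eps <- sdg$log2_values - (-t(cd$log2_geo_mean))
  expect_lt(abs(sd(eps) - 0.5), 3 * 0.5 / sqrt(2 * length(eps)))
  # per-sample column of scaled output minus the CLR column is constant
  sad <- apply_scale(cd, sdg)
  sad0 <- apply_scale(cd, default_scale(cd, gamma = 0, seed = 5L))
  delta <- sad[, , 7L] - sad0[, , 7L]
  expect_equal(unname(apply(delta, 2L, function(v) diff(range(v)))),
               rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(delta[1L, ]), unname(eps[7L, ]), tolerance = 1e-12)
})

test_that("gamma outside the realistic band triggers an advisory", {
  expect_silent(scale_model("default", gamma = 0.3))
  expect_silent(scale_model("default", gamma = 0.5))
  expect_message(scale_model("default", gamma = 1.5), "advisory")
  expect_error(scale_model("default", gamma = -0.1), "non-negative")
})

test_that("make_scale_matrix encodes log2 mu group means and mu ratios are identifiable", {
  cond <- factor(rep(c("A", "B"), each = 4), levels = c("A", "B"))
  s1 <- make_scale_matrix(c(A = 1, B = 1), gamma = 0, conditions = cond,
                          n_instances = 10L, seed = 1L)
  expect_true(all(s1$log2_values == 0))
  s2 <- make_scale_matrix(c(A = 1, B = 1.14), gamma = 1e-9,
                          conditions = cond, n_instances = 200L, seed = 1L)
  expect_equal(mean(s2$log2_values[, cond == "B"]), log2(1.14),
               tolerance = 1e-6)
  expect_equal(mean(s2$log2_values[, cond == "A"]), 0, tolerance = 1e-6)
  # scaling every mu by a constant changes nothing, bit for bit
  s3 <- make_scale_matrix(c(A = 3, B = 3 * 1.14), gamma = 1e-9,
                          conditions = cond, n_instances = 200L, seed = 1L)
  expect_identical(s2$log2_values, s3$log2_values)
  expect_error(make_scale_matrix(c(A = 1, C = 2), gamma = 0,
                                 conditions = cond, n_instances = 2L),
               "absent")
})

test_that("naive scale estimates summarize draws and recover worked group values", {
  # group means taken from a published metatranscriptome readout, used as
  # direct inputs: H = 17.41, BV = 14.59
  cond <- factor(c("BV", "BV", "H", "H"), levels = c("BV", "H"))
  lv <- matrix(rep(c(14.59, 14.59, 17.41, 17.41), each = 50), 50, 4)
  sdc <- structure(list(log2_values = lv,
                        spec = scale_model("user", gamma = 0),
                        seed = 1L),
                   class = "ssda_scale_draws")
  est <- naive_scale_estimate(sdc, cond)
  expect_equal(est$per_group, c(BV = 14.59, H = 17.41))
  expect_equal(est$diff_log2, 2.82)
  expect_equal(est$fold, 7.06, tolerance = 0.005)
  # constant draws: difference 0, fold 1
  sdk <- structure(list(log2_values = matrix(3.7, 20, 4),
                        spec = scale_model("user", gamma = 0), seed = 1L),
                   class = "ssda_scale_draws")
  estk <- naive_scale_estimate(sdk, cond)
  expect_equal(unname(estk$per_sample), rep(3.7, 4))
  expect_equal(estk$diff_log2, 0)
  expect_equal(estk$fold, 1)
})

test_that("reference-feature mu estimation reduces to the naive estimate on the full set", {
  cm <- toy_counts(d = 10L, n = 6L, conditions = rep(c("A", "B"), each = 3))
  est_ref <- estimate_mu_from_reference(cm, rownames(cm$counts),
                                        gamma = 1e-3, n_instances = 24L,
                                        seed = 9L)
  cd <- sample_compositions(cm, n_instances = 24L, seed = 9L)
  est_full <- naive_scale_estimate(default_scale(cd, gamma = 1e-3, seed = 9L),
                                   cm$conditions)
  expect_equal(est_ref$diff_log2, est_full$diff_log2, tolerance = 1e-12)
  expect_error(estimate_mu_from_reference(cm, "g01"), "two reference")
  expect_error(estimate_mu_from_reference(cm, c("nope1", "nope2")),
               "not in count table")
})

test_that("lvha reference selection matches brute-force quantile arithmetic", {
  # 8 features built so exactly two are low-variance AND high-abundance
  m <- rbind(
    hk1  = c(900, 905, 895, 900),
    hk2  = c(800, 798, 802, 800),
    var1 = c(400, 50, 380, 60),
    var2 = c(50, 400, 60, 380),
    low1 = c(5, 6, 5, 6),
    low2 = c(3, 3, 4, 3),
    mid1 = c(60, 200, 70, 180),
    mid2 = c(200, 60, 180, 70))
  cm <- ssda_counts(m)
  got <- lvha_reference(cm, var_quantile = 0.25, abund_quantile = 0.75)
  # brute-force recomputation of the rule
  p <- sweep(m + 0.5, 2, colSums(m + 0.5), "/")
  clr <- log2(p) - rep(colMeans(log2(p)), each = nrow(p))
  v <- apply(clr, 1, var); a <- rowMeans(p)
  manual <- rownames(m)[v <= quantile(v, 0.25) & a >= quantile(a, 0.75)]
  expect_identical(got, manual)
  expect_setequal(got, c("hk1", "hk2"))
  # vacuous thresholds keep everything; all-equal counts tie at the boundary
  expect_setequal(lvha_reference(cm, 1, 0), rownames(m))
  cm_tie <- ssda_counts(matrix(7L, 4, 3,
                        dimnames = list(paste0("g", 1:4), paste0("s", 1:3))))
  expect_setequal(lvha_reference(cm_tie, 0.25, 0.75), paste0("g", 1:4))
})

test_that("median dispersion is non-decreasing in gamma", {
  cm <- toy_counts(d = 40L, n = 10L, lambda = 200,
                   conditions = rep(c("A", "B"), each = 5))
  cd <- sample_compositions(cm, n_instances = 32L, seed = 13L)
  med_win <- vapply(c(0, 0.2, 0.5, 1), function(g) {
    rt <- suppressMessages(
      run_da_cd(cd, cm$conditions, scale_model("default", gamma = g),
                seed = 13L, tests = "t"))
    median(rt$diff_win)
  }, numeric(1))
  expect_true(all(diff(med_win) >= 0))
})
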