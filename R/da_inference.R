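# Expected-value hypothesis tests and nonparametric effect estimators
# computed across the Monte-Carlo instances.

#' Welch's unequal-variance t test
#'
#' Closed-form Welch statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. Degenerate inputs (both group variances zero) use the
#' documented convention p = 1 when the means are equal and p = 0 when they
#' differ.
#'
#' @param groupA,groupB numeric vectors of length >= 2.
#' @return list with `t`, `df` and `p`. `t` is computed as mean(groupA) -
#'   mean(groupB) divided by the standard error.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
welch_t <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  r <- welch_t_rows(matrix(groupA, nrow = 1L), matrix(groupB, nrow = 1L))
  list(t = r$t[1L], df = r$df[1L], p = r$p[1L])
}

#' Row-wise Welch t (features in rows)
#' @noRd
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- row_vars(a); vb <- row_vars(b)
  sa <- va / na; sb <- vb / nb
  se2 <- sa + sb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  if (any(deg)) {
    t[deg] <- 0
    df[deg] <- na + nb - 2
    p[deg] <- ifelse(ma[deg] == mb[deg], 1, 0)
  }
  list(t = t, df = df, p = p)
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p-value when the smaller group has at most 10
#' observations and there are no ties; Normal approximation with continuity
#' and tie corrections otherwise. All values tied gives p = 1.
#'
#' @param groupA,groupB numeric vectors of length >= 2.
#' @return list with `W` (rank-sum statistic of `groupA`, shifted as in
#'   Mann-Whitney U) and `p`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  r <- wilcoxon_rows(matrix(groupA, nrow = 1L), matrix(groupB, nrow = 1L))
  list(W = r$W[1L], p = r$p[1L])
}

#' Row-wise Wilcoxon rank-sum (features in rows), vectorized over features
#'
#' Midranks are computed by column-wise comparison counts: the rank of
#' x[i, j] within row i is (number below) + (number equal + 1) / 2, and the
#' tie correction sum(t^3 - t) equals rowSums(eq^2 - 1).
#' @noRd
wilcoxon_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  x <- cbind(a, b)
  d <- nrow(x); n <- na + nb
  lt <- matrix(0, d, n); eq <- matrix(0, d, n)
  for (j in seq_len(n)) {
    lt[, j] <- rowSums(x < x[, j])
    eq[, j] <- rowSums(x == x[, j])
  }
  ranks <- lt + (eq + 1) / 2
  w <- rowSums(ranks[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  tiesum <- rowSums(eq^2 - 1)
  mu <- na * nb / 2
  sigma2 <- (na * nb / 12) * ((n + 1) - tiesum / (n * (n - 1)))
  z <- w - mu
  z <- z - sign(z) * 0.5                      # continuity correction
  p <- pmin(1, 2 * stats::pnorm(-abs(z) / pmax(sqrt(sigma2), 1e-300)))
  p[sigma2 <= 0] <- 1                         # all values tied
  if (min(na, nb) <= 10L) {
    no_ties <- tiesum == 0
    if (any(no_ties)) {
      wi <- w[no_ties]
      hi <- wi > mu
      pex <- numeric(length(wi))
      pex[hi] <- 2 * stats::pwilcox(wi[hi] - 1, na, nb, lower.tail = FALSE)
      pex[!hi] <- 2 * stats::pwilcox(wi[!hi], na, nb)
      p[no_ties] <- pmin(1, pex)
    }
  }
  list(W = w, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (delegates to
#' [stats::p.adjust()]); kept as an explicit operation so every per-instance
#' correction goes through one audited path.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Expected p- and q-values across Monte-Carlo instances
#'
#' For each instance the Welch t and/or Wilcoxon test is run per feature and
#' Benjamini-Hochberg corrected across features; the expected values are the
#' means over instances of the per-instance p and per-instance q. Averaging
#' q (rather than adjusting the averaged p) matches the expected-value
#' reporting of the Monte-Carlo framework.
#'
#' @param sad D x N x K array of log2-scaled abundance draws from
#'   [apply_scale()].
#' @param conditions two-level factor of length N (reference level first).
#' @param tests `"both"`, `"t"` or `"wilcoxon"`.
#' @return data frame with columns among ep_t, eq_t, ep_w, eq_w (absent
#'   tests are NA), one row per feature.
#' @export
expected_tests <- function(sad, conditions, tests = c("both", "t", "wilcoxon")) {
  tests <- match.arg(tests)
  conditions <- encode_conditions(conditions)
  gi <- group_indices(conditions)
  dm <- dim(sad)
  d <- dm[1L]; k <- dm[3L]
  acc <- matrix(0, d, 4L)
  for (kk in seq_len(k)) {
    x <- sad[, , kk]
    xa <- x[, gi$alt, drop = FALSE]   # non-reference (x = 1)
    xr <- x[, gi$ref, drop = FALSE]
    if (tests != "wilcoxon") {
      pt_ <- welch_t_rows(xa, xr)$p
      acc[, 1L] <- acc[, 1L] + pt_
      acc[, 2L] <- acc[, 2L] + bh_adjust(pt_)
    }
    if (tests != "t") {
      pw <- wilcoxon_rows(xa, xr)$p
      acc[, 3L] <- acc[, 3L] + pw
      acc[, 4L] <- acc[, 4L] + bh_adjust(pw)
    }
  }
  acc <- acc / k
  out <- data.frame(ep_t = acc[, 1L], eq_t = acc[, 2L],
                    ep_w = acc[, 3L], eq_w = acc[, 4L])
  if (tests == "t") out$ep_w <- out$eq_w <- NA_real_
  if (tests == "wilcoxon") out$ep_t <- out$eq_t <- NA_real_
  rownames(out) <- dimnames(sad)[[1L]]
  out
}

#' Nonparametric difference, dispersion and effect size
#'
#' Per instance, samples from the two groups are paired at random (indices
#' recycled to m = max(nA, nB)): the between-group difference is the paired
#' difference of the non-reference minus the reference group; the
#' within-group dispersion is the elementwise maximum of the absolute
#' differences of two random pairings within each group. Pooling over all
#' instances, `diff_btw` and `diff_win` are medians of those draws and
#' `effect` is the median standardized ratio, with the denominator floored
#' at 1e-8. Pairing permutations use a dedicated random sub-stream keyed on
#' `(seed, "effect", k)` so they are reproducible independently of the
#' sampling stages.
#'
#' @param sad D x N x K array of log2 abundance draws.
#' @param conditions two-level factor (reference level first).
#' @param seed integer seed for the pairing sub-stream.
#' @return data frame with diff_btw, diff_win, effect (one row per feature).
#' @export
effect_sizes <- function(sad, conditions, seed = 1L) {
  conditions <- encode_conditions(conditions)
  gi <- group_indices(conditions)
  dm <- dim(sad)
  d <- dm[1L]; k <- dm[3L]
  na <- length(gi$alt); nr <- length(gi$ref)
  m <- max(na, nr)
  btw <- matrix(NA_real_, d, m * k)
  win <- matrix(NA_real_, d, m * k)
  for (kk in seq_len(k)) {
    set.seed(stream_seed(seed, "effect", kk))
    x <- sad[, , kk]
    xa <- x[, gi$alt, drop = FALSE]
    xr <- x[, gi$ref, drop = FALSE]
    ia <- sample(rep_len(seq_len(na), m))
    ir <- sample(rep_len(seq_len(nr), m))
    cols <- ((kk - 1L) * m + 1L):(kk * m)
    btw[, cols] <- xa[, ia, drop = FALSE] - xr[, ir, drop = FALSE]
    wa <- abs(xa[, sample(rep_len(seq_len(na), m)), drop = FALSE] -
              xa[, sample(rep_len(seq_len(na), m)), drop = FALSE])
    wr <- abs(xr[, sample(rep_len(seq_len(nr), m)), drop = FALSE] -
              xr[, sample(rep_len(seq_len(nr), m)), drop = FALSE])
    win[, cols] <- pmax(wa, wr)
  }
  data.frame(
    diff_btw = row_medians(btw),
    diff_win = row_medians(win),
    effect = row_medians(btw / pmax(win, 1e-8)),
    row.names = dimnames(sad)[[1L]]
  )
}

#' Run a scale-simulation differential abundance analysis
#'
#' Orchestrates the full pipeline: Dirichlet composition sampling, scale
#' draws under the requested scale model, conversion to log2 abundances,
#' expected-value tests and nonparametric effect sizes.
#'
#' @param cm `ssda_counts` with conditions attached (or supply
#'   `conditions`).
#' @param scale a [scale_model()] specification, or a single number taken
#'   as the gamma of the default model, or an `ssda_scale_draws` object /
#'   K x N matrix of user log2 scale draws.
#' @param conditions optional two-level labels if not attached to `cm`.
#' @param n_instances Monte-Carlo instances K (default 128).
#' @param prior Dirichlet pseudo-count (default 0.5).
#' @param seed integer seed.
#' @param tests which hypothesis tests to run (`"both"`, `"t"`,
#'   `"wilcoxon"`).
#' @return an `ssda_result` data frame with columns feature_id, diff_btw,
#'   diff_win, effect, ep_t, eq_t, ep_w, eq_w, mean_log2_abundance, and a
#'   `provenance` attribute recording all parameters and seeds.
#' @examples
#' cm <- ssda_counts(matrix(rpois(80, 50), 10, 8,
#'                   dimnames = list(paste0("g", 1:10), paste0("s", 1:8))),
#'                   conditions = rep(c("A", "B"), each = 4))
#' rt <- run_da(cm, scale = 0.5, n_instances = 16, seed = 1)
#' head(rt)
#' @export
run_da <- function(cm, scale = scale_model("default", gamma = 0.5),
                   conditions = NULL, n_instances = 128L, prior = 0.5,
                   seed = 1L, tests = c("both", "t", "wilcoxon")) {
  tests <- match.arg(tests)
  stopifnot(inherits(cm, "ssda_counts"))
  if (!is.null(conditions)) cm$conditions <- encode_conditions(conditions)
  if (is.null(cm$conditions))
    stop("no condition labels attached", call. = FALSE)
  if (is.numeric(scale) && length(scale) == 1L)
    scale <- scale_model("default", gamma = scale)
  cd <- sample_compositions(cm, n_instances = n_instances, prior = prior,
                            seed = seed)
  run_da_cd(cd, cm$conditions, scale, seed = seed, tests = tests)
}

#' Run the post-sampling pipeline on existing composition draws
#'
#' Exposed so a gamma grid (see [sen_analysis()]) can reuse one set of
#' Dirichlet draws, isolating the effect of the scale model.
#'
#' @inheritParams run_da
#' @param cd `ssda_compositions`.
#' @return `ssda_result` data frame.
#' @export
run_da_cd <- function(cd, conditions, scale, seed = 1L,
                      tests = c("both", "t", "wilcoxon")) {
  tests <- match.arg(tests)
  conditions <- encode_conditions(conditions)
  dm <- dim(cd$values)
  if (inherits(scale, "ssda_scale_draws")) {
    sd_ <- scale
  } else if (is.matrix(scale)) {
    if (!all(dim(scale) == c(dm[3L], dm[2L])))
      stop("user scale matrix must be K x N = ", dm[3L], " x ", dm[2L],
           call. = FALSE)
    sd_ <- structure(list(log2_values = scale,
                          spec = scale_model("user", gamma = NA_real_),
                          seed = NA_integer_),
                     class = "ssda_scale_draws")
  } else if (inherits(scale, "ssda_scale_model")) {
    sd_ <- switch(scale$mode,
      naive = default_scale(cd, gamma = 1e-3, seed = seed),
      default = default_scale(cd, gamma = scale$gamma, seed = seed,
                              conditions = conditions,
                              asymmetric = scale$asymmetric),
      informed = {
        base <- default_scale(cd, gamma = scale$gamma, seed = seed,
                              conditions = conditions,
                              asymmetric = scale$asymmetric)
        if (is.null(scale$mu))
          stop("informed mode needs mu", call. = FALSE)
        off <- make_scale_matrix(scale$mu, gamma = 0, conditions = conditions,
                                 n_instances = dm[3L], seed = seed)
        base$log2_values <- base$log2_values + off$log2_values
        base$spec <- scale
        base
      },
      user = stop("mode 'user' requires passing scale draws directly",
                  call. = FALSE)
    )
  } else {
    stop("unrecognized scale argument", call. = FALSE)
  }
  sad <- apply_scale(cd, sd_)
  et <- expected_tests(sad, conditions, tests = tests)
  es <- effect_sizes(sad, conditions, seed = seed)
  # mean CLR abundance for plot exports, independent of the scale model
  mean_log2_ab <- rowMeans(log2(cd$values), dims = 1L) -
    mean(cd$log2_geo_mean)
  rt <- data.frame(feature_id = cd$feature_ids,
                   diff_btw = es$diff_btw, diff_win = es$diff_win,
                   effect = es$effect,
                   ep_t = et$ep_t, eq_t = et$eq_t,
                   ep_w = et$ep_w, eq_w = et$eq_w,
                   mean_log2_abundance = mean_log2_ab,
                   row.names = NULL)
  class(rt) <- c("ssda_result", "data.frame")
  attr(rt, "provenance") <- list(
    scale_mode = sd_$spec$mode, gamma = sd_$spec$gamma, mu = sd_$spec$mu,
    n_instances = dm[3L], prior = cd$prior, seed = cd$seed, tests = tests,
    n_features = dm[1L], n_samples = dm[2L],
    reference_level = levels(conditions)[1L]
  )
  rt
}

#' Dual-cutoff feature selection
#'
#' The conventional volcano-plot filter: a feature is selected when its
#' expected q-value is at most `q_max` AND its absolute between-group log2
#' difference is at least `min_abs_diff`. Provided for comparison with
#' scale-uncertainty-based selection, which replaces the fold-change arm.
#'
#' @param rt `ssda_result`.
#' @param q_max q-value threshold in (0, 1].
#' @param min_abs_diff non-negative log2 difference threshold (the
#'   conventional 1.4 corresponds to a 2^1.4 = 2.6-fold change).
#' @param test `"t"` (default) or `"wilcoxon"`: which expected q column to
#'   threshold.
#' @return character vector of selected feature IDs.
#' @export
dual_cutoff <- function(rt, q_max = 0.05, min_abs_diff = 1.4,
                        test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(q_max > 0, q_max <= 1, min_abs_diff >= 0)
  q <- if (test == "t") rt$eq_t else rt$eq_w
  rt$feature_id[q <= q_max & abs(rt$diff_btw) >= min_abs_diff]
}

#' @export
print.ssda_result <- function(x, ...) {
  pr <- attr(x, "provenance")
  if (!is.null(pr))
    cat(sprintf("ssda_result: %d features (scale mode %s, gamma %g, K %d)\n",
                nrow(x), pr$scale_mode, pr$gamma, pr$n_instances))
  NextMethod()
}
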