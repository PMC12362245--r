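# Synthetic backbones, label permutation, binomial-thinning signal spiking,
# and FDR/sensitivity scoring against known truth.

#' Negative-binomial synthetic count backbone
#'
#' Generates a two-group feature-by-sample count table with no differential
#' features (the null backbone on which signal is implanted by
#' [spike_thinning()]). Per-feature abundances are drawn log-uniformly over
#' `log2_abundance_range`; library sizes log-uniformly over
#' `lib_size_range`; counts are negative-binomial around each sample's
#' depth-scaled composition (near-Poisson as `dispersion` approaches 0).
#'
#' A true between-group scale offset can be injected: the second group's
#' total abundance is multiplied by `2^group_scale_log2_offset`, carried by
#' a small set of high-abundance "scale carrier" features (dominant
#' transcripts) whose multiplier is solved so the total ratio is exact.
#' Concentrating the extra mass in a few features leaves the geometric mean
#' anchored by the unchanged majority, which is what makes the hidden offset
#' recoverable by composition-based scale estimates; a proportional change
#' to every feature would be invisible to any composition-based method.
#' The first `n_invariant` non-carrier features are designated as a
#' housekeeping-like invariant reference set.
#'
#' @param D number of features (default 2000).
#' @param n_per_group samples per group (default 10).
#' @param log2_abundance_range range of per-feature log2 mean abundances
#'   (default c(0, 8)).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts. Default 0.5.
#' @param lib_size_range sequencing-depth range (default c(5e5, 2e6)).
#' @param group_scale_log2_offset true log2 total-scale difference of the
#'   non-reference group (default 0).
#' @param n_invariant size of the designated invariant feature set
#'   (default 50).
#' @param n_scale_carriers number of high-abundance features carrying the
#'   scale offset (default 25).
#' @param seed integer seed.
#' @return list of class `ssda_backbone`: `counts` (`ssda_counts` with
#'   conditions "grpA" (reference) / "grpB"), `true_totals` (per-sample
#'   totals before depth resampling), `invariant_ids`, `carrier_ids`,
#'   `params`.
#' @export
nb_backbone <- function(D = 2000L, n_per_group = 10L,
                        log2_abundance_range = c(0, 8), dispersion = 0.5,
                        lib_size_range = c(5e5, 2e6),
                        group_scale_log2_offset = 0,
                        n_invariant = 50L, n_scale_carriers = 25L,
                        seed = 1L) {
  stopifnot(D >= 1L, n_per_group >= 2L, dispersion >= 0,
            diff(range(log2_abundance_range)) >= 0,
            all(lib_size_range > 0),
            n_invariant + n_scale_carriers <= D)
  set.seed(stream_seed(seed, "backbone", 0L))
  n <- 2L * as.integer(n_per_group)
  lambda <- 2^stats::runif(D, log2_abundance_range[1L],
                           log2_abundance_range[2L])
  carrier <- integer(0)
  if (n_scale_carriers > 0L) {
    carrier <- (D - n_scale_carriers + 1L):D
    lambda[carrier] <- 2^stats::runif(n_scale_carriers,
                                      log2_abundance_range[2L],
                                      log2_abundance_range[2L] + 3)
  }
  if (n_invariant > 0L) {
    # housekeeping-like features are constitutively and solidly expressed:
    # draw them from the upper half of the abundance range
    inv <- seq_len(n_invariant)
    lambda[inv] <- 2^stats::runif(n_invariant,
                                  mean(log2_abundance_range),
                                  log2_abundance_range[2L])
  }
  w_a <- lambda
  w_b <- lambda
  r <- 2^group_scale_log2_offset
  if (group_scale_log2_offset != 0) {
    if (n_scale_carriers == 0L)
      stop("a nonzero scale offset needs scale carrier features",
           call. = FALSE)
    s_car <- sum(lambda[carrier])
    s_tot <- sum(lambda)
    f <- (r * s_tot - (s_tot - s_car)) / s_car
    if (f <= 0)
      stop("scale offset too negative for the carrier mass; increase ",
           "n_scale_carriers or the offset", call. = FALSE)
    w_b[carrier] <- lambda[carrier] * f
  }
  conditions <- rep(c("grpA", "grpB"), each = n_per_group)
  lib <- 2^stats::runif(n, log2(lib_size_range[1L]), log2(lib_size_range[2L]))
  counts <- matrix(0L, D, n)
  for (j in seq_len(n)) {
    w <- if (conditions[j] == "grpA") w_a else w_b
    mu <- lib[j] * w / sum(w)
    counts[, j] <- if (dispersion == 0) {
      stats::rpois(D, mu)
    } else {
      stats::rnbinom(D, mu = mu, size = 1 / dispersion)
    }
  }
  dimnames(counts) <- list(sprintf("F%04d", seq_len(D)),
                           sprintf("S%02d", seq_len(n)))
  invariant <- setdiff(seq_len(D), carrier)[seq_len(n_invariant)]
  list_out <- list(
    counts = ssda_counts(counts, conditions = conditions),
    true_totals = stats::setNames(
      ifelse(conditions == "grpA", sum(w_a), sum(w_b)), colnames(counts)),
    invariant_ids = rownames(counts)[invariant],
    carrier_ids = rownames(counts)[carrier],
    params = list(D = D, n_per_group = n_per_group,
                  log2_abundance_range = log2_abundance_range,
                  dispersion = dispersion, lib_size_range = lib_size_range,
                  group_scale_log2_offset = group_scale_log2_offset,
                  n_invariant = n_invariant,
                  n_scale_carriers = n_scale_carriers, seed = seed)
  )
  structure(list_out, class = "ssda_backbone")
}

#' Technical-replicate regime with widespread small effects
#'
#' Emulates highly replicated technical (wet-lab) replication designs:
#' near-Poisson counts (dispersion 0.001), deep narrow-range libraries
#' (5-6 million reads), 20 samples per group, and small log2 fold changes
#' (SD 0.1) implanted by binomial thinning into half the features. In this
#' regime per-sample dispersions are tiny, so at gamma = 0 many features
#' with negligible differences reach significance; a small amount of scale
#' uncertainty removes most of them.
#'
#' @param D number of features (default 1000).
#' @param seed integer seed.
#' @return list with `counts` (spiked `ssda_counts`) and `truth`
#'   (`ssda_truth`), as returned by [spike_thinning()].
#' @export
technical_replicate_data <- function(D = 1000L, seed = 1L) {
  bb <- nb_backbone(D = D, n_per_group = 20L, dispersion = 0.001,
                    lib_size_range = c(5e6, 6e6), seed = seed)
  spike_thinning(bb$counts, tp_fraction = 0.5, effect_sd = 0.1, seed = seed)
}

#' Randomly permute condition labels
#'
#' Uniform random reassignment of the two-group labels preserving group
#' sizes; counts are untouched. The permuted table is a null dataset: any
#' discovery on it is a false positive.
#'
#' @param cm `ssda_counts` with conditions.
#' @param seed integer seed.
#' @return `ssda_counts` with permuted conditions.
#' @export
permute_labels <- function(cm, seed = 1L) {
  stopifnot(inherits(cm, "ssda_counts"), !is.null(cm$conditions),
            ncol(cm$counts) >= 4L)
  set.seed(stream_seed(seed, "permute", 0L))
  out <- cm
  out$conditions <- cm$conditions[sample(length(cm$conditions))]
  out
}

#' Implant known effects by binomial thinning
#'
#' Selects `round(tp_fraction * D)` features as true positives, draws their
#' modeled log2 fold changes `b ~ Normal(0, effect_sd^2)`, and thins counts
#' binomially with per-cell keep probability
#' `q = 2^(b * x_n - max(0, b))`, which lies in (0, 1] for either sign of b
#' and yields an expected between-group log2 fold change of exactly b.
#' Non-TP features are untouched (bit-identical). Thinning subsamples real
#' counts, so the semi-synthetic data keep the noise structure of the
#' backbone.
#'
#' @param cm `ssda_counts` with conditions.
#' @param tp_fraction fraction of features modeled as true positives
#'   (default 0.05).
#' @param effect_sd SD of the modeled log2 fold changes (default 2).
#' @param seed integer seed.
#' @return list: `counts` (thinned `ssda_counts`), `truth` (class
#'   `ssda_truth`: `tp_ids`, `b` named per-feature log2 fold changes, zero
#'   off the TP set, `design` 0/1 per sample, `params`).
#' @export
spike_thinning <- function(cm, tp_fraction = 0.05, effect_sd = 2,
                           seed = 1L) {
  stopifnot(inherits(cm, "ssda_counts"), !is.null(cm$conditions),
            tp_fraction > 0, tp_fraction < 1, effect_sd > 0)
  d <- nrow(cm$counts)
  set.seed(stream_seed(seed, "thin", 0L))
  n_tp <- round(tp_fraction * d)
  tp <- sort(sample(d, n_tp))
  b <- stats::rnorm(n_tp, 0, effect_sd)
  x <- as.integer(cm$conditions == levels(cm$conditions)[2L])
  out <- cm
  for (i in seq_along(tp)) {
    qv <- 2^(b[i] * x - max(0, b[i]))
    out$counts[tp[i], ] <- stats::rbinom(length(x), cm$counts[tp[i], ], qv)
  }
  bfull <- stats::setNames(numeric(d), rownames(cm$counts))
  bfull[tp] <- b
  truth <- structure(list(tp_ids = rownames(cm$counts)[tp], b = bfull,
                          design = stats::setNames(x, colnames(cm$counts)),
                          params = list(tp_fraction = tp_fraction,
                                        effect_sd = effect_sd, seed = seed)),
                     class = "ssda_truth")
  list(counts = out, truth = truth)
}

#' Score a call set against implanted truth
#'
#' Overall and stratified false discovery proportion and sensitivity.
#' At minimum modeled difference threshold tau, the true-positive set is
#' restricted to features with `|b| >= tau` and called features below the
#' threshold count as false positives (they are modeled to have effects
#' smaller than the analyst cares about). FDR of an empty call set is 0 by
#' convention; `n_calls` is reported so this cannot mask anything. Both an
#' absolute-value and a signed (`b >= tau`) stratification are emitted.
#'
#' @param calls character vector of called feature IDs.
#' @param truth `ssda_truth`.
#' @param min_abs_b_grid thresholds for the stratified curves
#'   (default c(0, 0.5, 1, 1.5, 2)).
#' @return list of class `ssda_score`: `fdr`, `sensitivity`, `n_calls`,
#'   `strata` (data frame over `min_abs_b_grid`), `strata_signed`.
#' @export
score_calls <- function(calls, truth, min_abs_b_grid = c(0, 0.5, 1, 1.5, 2)) {
  stopifnot(inherits(truth, "ssda_truth"))
  all_ids <- names(truth$b)
  if (!all(calls %in% all_ids))
    stop("call(s) not in the feature universe: ",
         paste(utils::head(setdiff(calls, all_ids), 3L), collapse = ", "),
         call. = FALSE)
  score_one <- function(tp_set) {
    ncalls <- length(calls)
    fdr <- if (ncalls == 0L) 0 else length(setdiff(calls, tp_set)) / ncalls
    sens <- if (length(tp_set) == 0L) 0 else
      length(intersect(calls, tp_set)) / length(tp_set)
    c(fdr = fdr, sensitivity = sens)
  }
  overall <- score_one(truth$tp_ids)
  strat <- function(tp_fun) {
    do.call(rbind, lapply(min_abs_b_grid, function(tau) {
      s <- score_one(tp_fun(tau))
      data.frame(min_b = tau, fdr = s[["fdr"]],
                 sensitivity = s[["sensitivity"]])
    }))
  }
  strata <- strat(function(tau)
    truth$tp_ids[abs(truth$b[truth$tp_ids]) >= tau])
  strata_signed <- strat(function(tau)
    truth$tp_ids[truth$b[truth$tp_ids] >= tau])
  structure(list(fdr = unname(overall[["fdr"]]),
                 sensitivity = unname(overall[["sensitivity"]]),
                 n_calls = length(calls),
                 strata = strata, strata_signed = strata_signed),
            class = "ssda_score")
}

#' @export
print.ssda_score <- function(x, ...) {
  cat(sprintf("ssda_score: FDR %.3f, sensitivity %.3f (%d calls)\n",
              x$fdr, x$sensitivity, x$n_calls))
  invisible(x)
}

#' Permutation + thinning benchmark of the caller
#'
#' For each replicate: permute the backbone's labels (erasing any real
#' group structure), implant known effects by binomial thinning, run the
#' analysis at each gamma, call features at `eq <= q_max`, and score
#' against truth. Reports per-gamma means and standard errors of FDR and
#' sensitivity, plus mean stratified curves.
#'
#' @param cm `ssda_counts` with conditions (a synthetic backbone from
#'   [nb_backbone()], or any real two-group count table).
#' @param n_reps number of permutation replicates (default 10).
#' @param tp_fraction,effect_sd forwarded to [spike_thinning()].
#' @param gammas gamma values to benchmark (default c(0, 0.2, 0.5)).
#' @param q_max call threshold on the expected q-value (default 0.05).
#' @param n_instances,prior,seed forwarded to the pipeline.
#' @param test `"t"` or `"wilcoxon"` call column.
#' @param min_abs_b_grid stratification thresholds.
#' @return list of class `ssda_benchmark`: `summary` (data frame: gamma,
#'   mean/se FDR, mean/se sensitivity, mean n_calls), `strata` (data frame
#'   of mean stratified metrics per gamma), `scores` (per-replicate,
#'   per-gamma `ssda_score` list), `params`.
#' @export
run_benchmark <- function(cm, n_reps = 10L, tp_fraction = 0.05,
                          effect_sd = 2, gammas = c(0, 0.2, 0.5),
                          q_max = 0.05, n_instances = 128L, prior = 0.5,
                          seed = 1L, test = c("t", "wilcoxon"),
                          min_abs_b_grid = c(0, 0.5, 1, 1.5, 2)) {
  test <- match.arg(test)
  if (inherits(cm, "ssda_backbone")) cm <- cm$counts
  stopifnot(inherits(cm, "ssda_counts"), !is.null(cm$conditions),
            n_reps >= 1L)
  qcol <- if (test == "t") "eq_t" else "eq_w"
  tst <- if (test == "t") "t" else "wilcoxon"
  scores <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- stream_seed(seed, "benchrep", r)
    perm <- permute_labels(cm, seed = rep_seed)
    sp <- spike_thinning(perm, tp_fraction = tp_fraction,
                         effect_sd = effect_sd, seed = rep_seed)
    cd <- sample_compositions(sp$counts, n_instances = n_instances,
                              prior = prior, seed = rep_seed)
    scores[[r]] <- lapply(seq_along(gammas), function(i) {
      rt <- run_da_cd(cd, sp$counts$conditions,
                      scale_model("default", gamma = gammas[i]),
                      seed = stream_seed(rep_seed, "benchgamma", i),
                      tests = tst)
      calls <- rt$feature_id[rt[[qcol]] <= q_max]
      score_calls(calls, sp$truth, min_abs_b_grid = min_abs_b_grid)
    })
  }
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  summary_df <- do.call(rbind, lapply(seq_along(gammas), function(i) {
    fdr <- vapply(scores, function(s) s[[i]]$fdr, numeric(1))
    sens <- vapply(scores, function(s) s[[i]]$sensitivity, numeric(1))
    ncl <- vapply(scores, function(s) s[[i]]$n_calls, numeric(1))
    data.frame(gamma = gammas[i], mean_fdr = mean(fdr), se_fdr = se(fdr),
               mean_sensitivity = mean(sens), se_sensitivity = se(sens),
               mean_n_calls = mean(ncl))
  }))
  strata_df <- do.call(rbind, lapply(seq_along(gammas), function(i) {
    st <- lapply(scores, function(s) s[[i]]$strata)
    out <- st[[1L]]
    out$fdr <- rowMeans(vapply(st, function(x) x$fdr,
                               numeric(nrow(out))))
    out$sensitivity <- rowMeans(vapply(st, function(x) x$sensitivity,
                                       numeric(nrow(out))))
    cbind(gamma = gammas[i], out)
  }))
  structure(list(summary = summary_df, strata = strata_df, scores = scores,
                 params = list(n_reps = n_reps, tp_fraction = tp_fraction,
                               effect_sd = effect_sd, gammas = gammas,
                               q_max = q_max, n_instances = n_instances,
                               prior = prior, seed = seed, test = test)),
            class = "ssda_benchmark")
}

#' @export
print.ssda_benchmark <- function(x, ...) {
  cat(sprintf("ssda_benchmark: %d replicate(s)\n", x$params$n_reps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
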