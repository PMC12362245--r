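# Probabilistic models of the per-sample total scale.
#
# The measured counts identify only the composition; the total scale of the
# system each sample came from is supplied by a model. The centred log-ratio
# (CLR) corresponds to the point-mass assumption log2 Wtot = -log2 G_n.
# The models here keep that mean but add log-normal uncertainty (gamma, the
# SD of the noise on the log2 scale) and, in the informed configuration,
# per-group location multipliers mu whose ratio encodes a believed scale
# difference between conditions.

#' Specify a scale model
#'
#' @param mode one of `"default"` (CLR mean plus log2-scale noise of SD
#'   `gamma`), `"naive"` (`gamma` forced to 1e-3, mu = 1: numerically the
#'   plain CLR), `"informed"` (default model shifted by per-group log2 mu
#'   offsets), `"user"` (draws replace the CLR term entirely; built with
#'   [make_scale_matrix()] or supplied as a matrix).
#' @param gamma non-negative SD of the scale noise on the log2 scale. Values
#'   in [0.2, 0.5] are realistic for most designs; gamma = 0 reproduces the
#'   CLR exactly. A value above 1 triggers an advisory.
#' @param mu named per-group positive scale multipliers (dimensionless; only
#'   the ratio between groups is identifiable). Default 1 for both groups.
#' @param asymmetric if `TRUE`, scale noise is drawn only for the
#'   non-reference (x = 1) group, reproducing the one-group form of the
#'   model; by default noise is drawn for every sample.
#' @return an object of class `ssda_scale_model`.
#' @export
scale_model <- function(mode = c("default", "naive", "informed", "user"),
                        gamma = 0.5, mu = NULL, asymmetric = FALSE) {
  mode <- match.arg(mode)
  if (mode == "naive") {
    gamma <- 1e-3
    mu <- NULL
  }
  if (!is.null(mu)) {
    if (any(mu <= 0)) stop("all mu must be positive", call. = FALSE)
  }
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  check_gamma(gamma)
  structure(list(mode = mode, gamma = gamma, mu = mu,
                 asymmetric = isTRUE(asymmetric)),
            class = "ssda_scale_model")
}

#' @noRd
check_gamma <- function(gamma) {
  if (any(gamma > 1))
    message("advisory: gamma > 1 adds more scale uncertainty than is ",
            "typically realistic (0.2-0.5 for most designs)")
  invisible(gamma)
}

#' @export
print.ssda_scale_model <- function(x, ...) {
  cat(sprintf("ssda_scale_model: mode=%s gamma=%g", x$mode, x$gamma))
  if (!is.null(x$mu))
    cat(" mu=", paste(sprintf("%s:%g", names(x$mu), x$mu), collapse = ","))
  if (x$asymmetric) cat(" (noise on non-reference group only)")
  cat("\n")
  invisible(x)
}

#' Default scale model: CLR mean with log-normal uncertainty
#'
#' Draws log2 total-scale values whose mean is the CLR assumption
#' `-log2 G_n(k)` for each composition instance, with independent
#' Normal(0, gamma^2) noise per sample and instance. gamma = 0 reproduces
#' the CLR exactly.
#'
#' @param cd an `ssda_compositions` object.
#' @param gamma non-negative noise SD on the log2 scale.
#' @param seed integer seed for the noise sub-stream.
#' @param conditions optional two-level factor; only needed with
#'   `asymmetric = TRUE`.
#' @param asymmetric draw noise only for the non-reference group.
#' @return an object of class `ssda_scale_draws`: list with `log2_values`
#'   (K x N matrix, instances in rows), `spec`, `seed`.
#' @export
default_scale <- function(cd, gamma = 0.5, seed = 1L, conditions = NULL,
                          asymmetric = FALSE) {
  stopifnot(inherits(cd, "ssda_compositions"), gamma >= 0)
  check_gamma(gamma)
  lgm <- cd$log2_geo_mean                    # N x K
  n <- nrow(lgm); k <- ncol(lgm)
  eps <- scale_noise(k, n, gamma, seed)
  if (isTRUE(asymmetric)) {
    if (is.null(conditions))
      stop("asymmetric noise needs conditions", call. = FALSE)
    gi <- group_indices(encode_conditions(conditions))
    eps[, gi$ref] <- 0
  }
  log2_values <- -t(lgm) + eps               # K x N
  colnames(log2_values) <- cd$sample_ids
  structure(list(log2_values = log2_values,
                 spec = scale_model("default", gamma = gamma,
                                    asymmetric = asymmetric),
                 seed = as.integer(seed)),
            class = "ssda_scale_draws")
}

#' @noRd
scale_noise <- function(k, n, gamma, seed) {
  eps <- matrix(0, k, n)
  if (gamma > 0) {
    for (j in seq_len(n)) {
      set.seed(stream_seed(seed, "scale", j))
      eps[, j] <- stats::rnorm(k, 0, gamma)
    }
  }
  eps
}

#' Build a scale-draw matrix from per-group multipliers
#'
#' Encodes an informed or user scale model as a log-normal distribution:
#' `log2_values[k, n] ~ Normal(log2 mu[group(n)], gamma^2)`. Only the ratio
#' between the group multipliers is identifiable, so mu is normalized
#' internally to the reference group (`mu_ref = 1`); scaling all mu by a
#' common factor leaves every downstream statistic bit-identical.
#'
#' @param mu positive per-group multipliers: either a named vector
#'   (names = condition levels) or unnamed length-2 in the order
#'   (reference, non-reference). Per-sample vectors (length N, named by
#'   sample) are also accepted.
#' @param gamma non-negative noise SD on the log2 scale.
#' @param conditions two-level factor of length N (reference level first).
#' @param n_instances number of Monte-Carlo instances K.
#' @param seed integer seed.
#' @return `ssda_scale_draws` with mode `"user"`.
#' @examples
#' cond <- factor(c("BV", "BV", "H", "H"))
#' sd <- make_scale_matrix(c(BV = 1, H = 1.14), gamma = 0.5,
#'                         conditions = cond, n_instances = 64, seed = 7)
#' @export
make_scale_matrix <- function(mu, gamma, conditions, n_instances = 128L,
                              seed = 1L) {
  conditions <- encode_conditions(conditions)
  if (any(mu <= 0)) stop("all mu must be positive", call. = FALSE)
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  check_gamma(gamma)
  lev <- levels(conditions)
  n <- length(conditions); k <- as.integer(n_instances)
  if (length(mu) == n && !is.null(names(mu)) &&
      !all(names(mu) %in% lev)) {
    mu_sample <- mu                       # per-sample multipliers
  } else {
    if (is.null(names(mu))) {
      if (length(mu) != 2L)
        stop("unnamed mu must have length 2 (reference, non-reference)",
             call. = FALSE)
      names(mu) <- lev
    }
    if (!all(lev %in% names(mu)))
      stop("group label(s) absent from mu: ",
           paste(setdiff(lev, names(mu)), collapse = ", "), call. = FALSE)
    mu_sample <- mu[as.character(conditions)]
  }
  # ratio identifiability: anchor the reference group at log2 mu = 0 by
  # dividing through before taking logs (keeps c * mu bit-identical to mu)
  ref_mu <- mu_sample[conditions == lev[1L]]
  if (length(unique(ref_mu)) == 1L) {
    offset <- log2(mu_sample / ref_mu[1L])
  } else {
    offset <- log2(mu_sample) - mean(log2(ref_mu))
  }
  log2_values <- matrix(rep(offset, each = k), k, n) +
    scale_noise(k, n, gamma, seed)
  colnames(log2_values) <- names(conditions) %||% colnames(log2_values)
  structure(list(log2_values = log2_values,
                 spec = scale_model("user", gamma = gamma,
                                    mu = stats::setNames(2^c(0, offset[match(lev[2L], conditions)]), lev)),
                 seed = as.integer(seed)),
            class = "ssda_scale_draws")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine composition and scale draws into log2 abundances
#'
#' The model is multiplicative, `W = Wcomp * Wtot`, hence additive in logs:
#' `out[d, n, k] = log2 cd$values[d, n, k] + sd$log2_values[k, n]`.
#'
#' @param cd an `ssda_compositions` object.
#' @param sd an `ssda_scale_draws` object with matching K and N.
#' @return D x N x K array of log2-scaled abundance draws.
#' @export
apply_scale <- function(cd, sd) {
  stopifnot(inherits(cd, "ssda_compositions"),
            inherits(sd, "ssda_scale_draws"))
  dm <- dim(cd$values)
  if (!all(dim(sd$log2_values) == c(dm[3L], dm[2L])))
    stop("scale draws are ", nrow(sd$log2_values), " x ",
         ncol(sd$log2_values), " but compositions need K x N = ",
         dm[3L], " x ", dm[2L], call. = FALSE)
  out <- log2(cd$values)
  # add the per-(n, k) scale term across all features
  shift <- aperm(array(t(sd$log2_values), dim = c(dm[2L], dm[3L], dm[1L])),
                 c(3L, 1L, 2L))
  out + shift
}

#' Summarize scale draws into per-sample and per-group estimates
#'
#' Averages the log2 scale draws over Monte-Carlo instances per sample,
#' then over samples per group. With the model run at a tiny gamma
#' (mode `"naive"`, gamma = 1e-3) this reads out the scale estimate the CLR
#' normalization implicitly makes, exposing e.g. a hidden group difference
#' in microbial load. The group difference is reported on the log2 scale
#' and as a 2^difference fold change (non-reference minus reference).
#'
#' @param sd an `ssda_scale_draws` object.
#' @param conditions two-level factor of length N.
#' @return list with `per_sample` (named numeric), `per_group` (named
#'   numeric), `diff_log2` and `fold`.
#' @export
naive_scale_estimate <- function(sd, conditions) {
  stopifnot(inherits(sd, "ssda_scale_draws"))
  conditions <- encode_conditions(conditions)
  stopifnot(length(conditions) == ncol(sd$log2_values))
  per_sample <- colMeans(sd$log2_values)
  if (is.null(names(per_sample)))
    names(per_sample) <- paste0("S", seq_along(per_sample))
  gi <- group_indices(conditions)
  per_group <- c(mean(per_sample[gi$ref]), mean(per_sample[gi$alt]))
  names(per_group) <- gi$levels
  diff_log2 <- per_group[2L] - per_group[1L]
  list(per_sample = per_sample, per_group = per_group,
       diff_log2 = unname(diff_log2), fold = unname(2^diff_log2))
}

#' Estimate group scale multipliers from presumed-invariant features
#'
#' Housekeeping genes/functions are expected to be invariant in absolute
#' abundance between conditions, so their share of each sample's composition
#' tracks 1 / (total scale). The reference set therefore serves as the
#' denominator: scale draws are built as minus the mean log2 composition of
#' the reference features (computed within the full-sample Dirichlet draws)
#' plus Normal(0, gamma^2) noise. Group means of those draws are converted
#' to mu ratios with the reference condition anchored at mu = 1, suitable
#' for [make_scale_matrix()].
#'
#' @param cm `ssda_counts` with conditions attached.
#' @param reference_ids character vector of at least two feature IDs
#'   presumed invariant (e.g. housekeeping genes or [lvha_reference()]).
#' @param gamma non-negative noise SD of the readout draws (default 1e-3:
#'   the estimate is a location readout, so scale uncertainty belongs in
#'   the downstream model built from the estimated mu, not in the estimate
#'   itself).
#' @param n_instances,prior,seed forwarded to [sample_compositions()].
#' @return list with `mu` (named per-group multipliers, reference = 1),
#'   `diff_log2`, `fold`, and the underlying `scale_draws`.
#' @export
estimate_mu_from_reference <- function(cm, reference_ids, gamma = 1e-3,
                                       n_instances = 128L, prior = 0.5,
                                       seed = 1L) {
  stopifnot(inherits(cm, "ssda_counts"))
  if (is.null(cm$conditions)) stop("conditions required", call. = FALSE)
  if (length(reference_ids) < 2L)
    stop("need at least two reference features", call. = FALSE)
  missing <- setdiff(reference_ids, rownames(cm$counts))
  if (length(missing) > 0L)
    stop("reference feature(s) not in count table: ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  cd <- sample_compositions(cm, n_instances = n_instances, prior = prior,
                            seed = seed)
  idx <- match(reference_ids, cd$feature_ids)
  # log2 geometric mean of the reference features within the full composition
  lgm_ref <- colMeans(log2(cd$values[idx, , , drop = FALSE]), dims = 1L)
  k <- dim(cd$values)[3L]; n <- dim(cd$values)[2L]
  log2_values <- -t(lgm_ref) + scale_noise(k, n, gamma, seed)
  colnames(log2_values) <- cd$sample_ids
  sdref <- structure(list(log2_values = log2_values,
                          spec = scale_model("default", gamma = gamma),
                          seed = as.integer(seed)),
                     class = "ssda_scale_draws")
  est <- naive_scale_estimate(sdref, cm$conditions)
  lev <- levels(cm$conditions)
  mu <- stats::setNames(c(1, 2^est$diff_log2), lev)
  list(mu = mu, diff_log2 = est$diff_log2, fold = est$fold,
       scale_draws = sdref)
}

#' Select a low-variance, high-abundance (LVHA) reference feature set
#'
#' Identifies features usable as an internal reference denominator: CLR
#' variance (computed on a single point estimate with the pseudo-count
#' prior) at or below the `var_quantile` quantile AND mean relative
#' abundance at or above the `abund_quantile` quantile. Ties at either
#' boundary are included. Deterministic.
#'
#' @param cm `ssda_counts`.
#' @param var_quantile upper quantile bound for CLR variance (default 0.25).
#' @param abund_quantile lower quantile bound for mean relative abundance
#'   (default 0.75).
#' @param prior pseudo-count used for the point estimate (default 0.5).
#' @return character vector of feature IDs.
#' @export
lvha_reference <- function(cm, var_quantile = 0.25, abund_quantile = 0.75,
                           prior = 0.5) {
  stopifnot(inherits(cm, "ssda_counts"),
            var_quantile > 0, var_quantile <= 1,
            abund_quantile >= 0, abund_quantile < 1)
  y <- cm$counts + prior
  p <- sweep(y, 2L, colSums(y), "/")
  clr <- log2(p) - rep(colMeans(log2(p)), each = nrow(p))
  v <- row_vars(clr)
  a <- rowMeans(p)
  keep <- v <= stats::quantile(v, var_quantile) &
    a >= stats::quantile(a, abund_quantile)
  ids <- rownames(cm$counts)[keep]
  if (length(ids) == 0L)
    stop("no feature satisfies both quantile bounds; loosen var_quantile ",
         "or abund_quantile", call. = FALSE)
  ids
}
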