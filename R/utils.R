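# Internal helpers shared across modules.

#' Derive a deterministic sub-stream seed
#'
#' Every source of randomness in the package draws from its own sub-stream,
#' keyed on the user seed, a character tag naming the stage, and an index
#' (sample, instance or replicate). This keeps stages independently
#' reproducible: e.g. the Dirichlet draws are identical across a gamma grid
#' while the scale noise is resampled.
#'
#' @param seed integer user seed.
#' @param tag character stage tag.
#' @param i non-negative integer index within the stage.
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @keywords internal
#' @noRd
stream_seed <- function(seed, tag, i = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 104729
  # all products stay far below 2^53, so the arithmetic is exact in doubles
  s <- (abs(as.numeric(seed)) %% 1e6) * 1009 + h * 31013 + as.numeric(i) * 7919
  as.integer(s %% 2147483645) + 1L
}

#' @noRd
is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

#' @noRd
row_medians <- function(m) apply(m, 1L, stats::median)

#' @noRd
row_vars <- function(m) {
  ctr <- m - rowMeans(m)
  rowSums(ctr * ctr) / (ncol(m) - 1)
}

#' Split sample indices by condition
#'
#' @return list with `ref` (reference level) and `alt` index vectors plus the
#'   level names; `alt` is the x = 1 group, `ref` the x = 0 group.
#' @noRd
group_indices <- function(conditions) {
  stopifnot(is.factor(conditions), nlevels(conditions) == 2L)
  lev <- levels(conditions)
  list(
    ref = which(conditions == lev[1L]),
    alt = which(conditions == lev[2L]),
    levels = lev
  )
}
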