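# Dirichlet Monte-Carlo sampling of the underlying composition.

#' Monte-Carlo draws of the composition underlying a count table
#'
#' Sequencing retains only relative information, and a count column is one
#' multinomial realization of the sample's composition. The posterior
#' uncertainty in that composition is modelled by drawing, for every sample n
#' and Monte-Carlo instance k, a probability vector from
#' Dirichlet(Y[, n] + prior). Draws are generated per-sample from dedicated
#' random sub-streams keyed on `(seed, n)`, so results do not depend on how
#' instances are chunked and the same seed always yields identical arrays.
#'
#' @param cm an [ssda_counts] object.
#' @param n_instances number of Monte-Carlo instances K (default 128).
#' @param prior per-cell pseudo-count added to the Dirichlet parameters;
#'   must be positive when any sample contains zero counts. Default 0.5
#'   (a half-count uniform prior).
#' @param seed integer seed.
#' @return an object of class `ssda_compositions`: list with `values`
#'   (D x N x K array, every (n, k) column on the simplex), `log2_geo_mean`
#'   (N x K matrix of per-draw log2 geometric means), `prior`, `seed`,
#'   `feature_ids`, `sample_ids`.
#' @examples
#' cm <- ssda_counts(matrix(c(9, 0, 3, 4, 4, 4), 3, 2,
#'                   dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
#' cd <- sample_compositions(cm, n_instances = 16, seed = 1)
#' colSums(cd$values[, 1, ])   # every draw sums to 1
#' @export
sample_compositions <- function(cm, n_instances = 128L, prior = 0.5,
                                seed = 1L) {
  stopifnot(inherits(cm, "ssda_counts"), n_instances >= 1L, prior >= 0)
  y <- cm$counts
  d <- nrow(y); n <- ncol(y); k <- as.integer(n_instances)
  if (prior == 0 && any(colSums(y) == 0))
    stop("sample with zero total count and prior = 0: Dirichlet is degenerate",
         call. = FALSE)
  if (prior == 0 && any(y == 0))
    stop("zero counts with prior = 0 give degenerate (zero-mass) components; ",
         "use a positive prior", call. = FALSE)
  values <- array(NA_real_, dim = c(d, n, k))
  for (j in seq_len(n)) {
    set.seed(stream_seed(seed, "dirichlet", j))
    g <- matrix(stats::rgamma(d * k, shape = y[, j] + prior, rate = 1), d, k)
    values[, j, ] <- sweep(g, 2L, colSums(g), "/")
  }
  dimnames(values) <- list(rownames(y), colnames(y), NULL)
  lgm <- colMeans(log2(values), dims = 1L)
  structure(list(values = values, log2_geo_mean = lgm, prior = prior,
                 seed = as.integer(seed), feature_ids = rownames(y),
                 sample_ids = colnames(y)),
            class = "ssda_compositions")
}

#' Per-draw log2 geometric means
#'
#' Returns the N x K matrix of log2 G (the log2 geometric mean over features
#' of each sample-instance composition draw); 1/G is the implicit total
#' assumed by the centred log-ratio normalization.
#'
#' @param cd an `ssda_compositions` object.
#' @return N x K numeric matrix.
#' @export
geo_means <- function(cd) {
  stopifnot(inherits(cd, "ssda_compositions"))
  cd$log2_geo_mean
}

#' @export
print.ssda_compositions <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("ssda_compositions: %d features x %d samples x %d instances (prior %g, seed %d)\n",
              dm[1L], dm[2L], dm[3L], x$prior, x$seed))
  invisible(x)
}
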