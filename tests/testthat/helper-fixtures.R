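# Shared fixtures, all generated in code.

toy_counts <- function(d = 12L, n = 8L, lambda = 50, seed = 42L,
                       conditions = rep(c("A", "B"), each = n / 2)) {
  set.seed(seed)
  m <- matrix(rpois(d * n, lambda), d, n,
              dimnames = list(sprintf("g%02d", seq_len(d)),
                              sprintf("s%02d", seq_len(n))))
  ssda_counts(m, conditions = conditions)
}

write_toy_tsv <- function(cm, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  counts_path <- file.path(dir, "counts.tsv")
  cond_path <- file.path(dir, "cond.tsv")
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(colnames(cm$counts), as.character(cm$conditions)),
              cond_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(counts = counts_path, conditions = cond_path, dir = dir)
}

# independent brute-force step-up BH oracle (quadratic, by the definition)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  q
}

# independent Dirichlet sampler via gamma normalization, for mean/var checks
dirichlet_brute <- function(alpha, k, seed) {
  set.seed(seed)
  t(vapply(seq_len(k), function(i) {
    g <- rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }, numeric(length(alpha))))
}
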