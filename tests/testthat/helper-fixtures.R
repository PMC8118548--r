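# Small fixture builders shared across test files.

# independent standard-normal expression matrix with gene names
rand_expr <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("g", seq_len(p))
  x
}

# exactly uncorrelated columns (zero-mean, orthogonal), unit SD
orthogonal_expr <- function(n, p, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  # columns are orthogonal to the intercept (mean zero) and to each other
  x <- sweep(q, 2, apply(q, 2, sd), "/")
  colnames(x) <- paste0("g", seq_len(p))
  attr(x, "standardized") <- TRUE
  x
}

# brute-force concordance probability: P(score_pos > score_neg) + P(tie)/2
concordance_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  grid <- outer(sp, sn, `-`)
  (sum(grid > 0) + 0.5 * sum(grid == 0)) / length(grid)
}

# a toy edge-record data frame
toy_edges <- function() {
  data.frame(
    gene_a = c("g1", "g1", "g2"),
    gene_b = c("g2", "g3", "g3"),
    q = c(0.5, 0.5, 0.2),
    q_signed = c(0.5, -0.5, 0.2),
    type = c("type_I", "type_II", "type_I"),
    stringsAsFactors = FALSE
  )
}
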