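# Independent oracles used across tests: kept deliberately naive.

# all permutations of 1..n as rows (recursive construction, n <= 7)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1))
  p <- perm_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

# brute-force exact null of Spearman's r for tie-free ranks, n <= 7
oracle_null_r <- function(n) {
  p <- perm_matrix(n)
  apply(p, 1, function(v) cor(v, seq_len(n)))
}

# naive Spearman via the 1 - 6*sum(d^2)/(n(n^2-1)) formula (tie-free only)
oracle_spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# brute-force Benjamini-Hochberg from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# tiny expression dataset built by hand: values per (line, probe) recycled
# over replicates, with optional per-replicate jitter
make_expr <- function(line_means, n_replicates = 3, calls = NULL,
                      jitter = 0, seed = 1) {
  set.seed(seed)
  n_lines <- ncol(line_means)
  lines <- colnames(line_means)
  if (is.null(lines)) lines <- paste0("L", seq_len(n_lines))
  m <- line_means[, rep(seq_len(n_lines), each = n_replicates), drop = FALSE]
  if (jitter > 0) m <- m + matrix(rnorm(length(m), 0, jitter), nrow(m))
  m <- pmax(m, 0)
  colnames(m) <- paste(rep(lines, each = n_replicates),
                       rep(seq_len(n_replicates), n_lines), sep = "_")
  if (is.null(calls))
    calls <- matrix("P", nrow(m), ncol(m), dimnames = dimnames(m))
  expression_dataset(m, calls, rep(lines, each = n_replicates))
}

switch_config <- function(seed, n_probes = 2000) {
  sim_config(n_probes = n_probes, planted_markers = list(
    planted_marker("P00001",
                   c(ectoderm = 0.9, mesoderm = -0.9, endoderm = -0.9),
                   gene = "SWITCH1")),
    seed = seed)
}
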