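# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (per-cell loops, full subset enumeration) so they stay independent
# of the vectorised implementation paths they check.

# alignment from a list of column character vectors
aln_from_cols <- function(cols, ids = NULL) {
  mat <- do.call(cbind, cols)
  n <- nrow(mat)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  as_alignment(apply(mat, 1, paste, collapse = ""), ids = ids)
}

random_alignment <- function(n, L, p_missing = 0.05) {
  symbols <- c("A", "C", "G", "T")
  mat <- matrix(sample(symbols, n * L, replace = TRUE), n, L)
  miss <- matrix(stats::runif(n * L) < p_missing, n, L)
  mat[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
  as_alignment(apply(mat, 1, paste, collapse = ""),
               ids = paste0("s", seq_len(n)))
}

# naive per-column classification: loops over cells, no shared code with
# classify_columns()
oracle_classify <- function(aln) {
  mat <- unclass(aln)
  vapply(seq_len(ncol(mat)), function(j) {
    obs <- mat[, j][mat[, j] %in% c("A", "C", "G", "T")]
    tab <- table(obs)
    c(variable = length(tab) >= 2, pis = sum(tab >= 2) >= 2)
  }, logical(2))
}

# brute-force minimal diagnostic set: enumerate every subset of positions,
# count OPUs with a unique restricted profile, report the minimum subset
# size attaining the full-matrix unique count
oracle_minimal <- function(profiles) {
  k <- ncol(profiles)
  uniq <- function(S) {
    if (length(S) == 0) return(0L)
    key <- apply(profiles[, S, drop = FALSE], 1, paste, collapse = "/")
    sum(table(key)[key] == 1)
  }
  target <- uniq(seq_len(k))
  if (target == 0L) return(list(size = 0L, target = 0L))
  best <- k
  for (mask in seq_len(2^k - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(S) < best && uniq(S) == target) best <- length(S)
  }
  list(size = best, target = target)
}

random_profile_matrix <- function(n_opu, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_opu * k, replace = TRUE,
                     prob = c(0.4, 0.4, 0.1, 0.1)),
              n_opu, k, dimnames = list(paste0("opu", seq_len(n_opu)), NULL))
  cladebar:::new_diag_matrix(m, region = rep("r", k), pos1 = seq_len(k))
}
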