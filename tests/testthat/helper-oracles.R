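# Independent oracles used against the package implementations.

# all-pairs brute-force overlap: the reference for find_overlaps()
brute_force_overlaps <- function(query, subject) {
  res <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] != subject$chrom[j]) next
    ov <- min(query$end[i], subject$end[j]) - max(query$start[i], subject$start[j])
    if (ov > 0)
      res[[length(res) + 1]] <- data.frame(query_idx = i, subject_idx = j,
                                           overlap_bp = ov)
  }
  if (!length(res))
    return(data.frame(query_idx = integer(), subject_idx = integer(),
                      overlap_bp = numeric()))
  do.call(rbind, res)
}

# the same all-pairs brute force, vectorized over the full index grid so
# large random instances stay cheap; still O(n * m) work
brute_force_overlaps_vec <- function(query, subject) {
  g <- expand.grid(query_idx = seq_len(nrow(query)),
                   subject_idx = seq_len(nrow(subject)))
  ov <- pmin(query$end[g$query_idx], subject$end[g$subject_idx]) -
    pmax(query$start[g$query_idx], subject$start[g$subject_idx])
  same <- query$chrom[g$query_idx] == subject$chrom[g$subject_idx]
  keep <- same & ov > 0
  data.frame(query_idx = g$query_idx[keep], subject_idx = g$subject_idx[keep],
             overlap_bp = ov[keep])
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(50, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# textbook Pearson chi-square on a 2x2 table: sum (O - E)^2 / E
chisq_oracle <- function(a, ta, b, tb) {
  tab <- rbind(c(a, ta - a), c(b, tb - b))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all rank
# assignments of the smaller group
wilcoxon_exact_oracle <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combs <- utils::combn(n, length(x))
  w_all <- apply(combs, 2, function(idx)
    sum(seq_len(n)[idx]) - length(x) * (length(x) + 1) / 2)
  mu <- length(x) * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# sort-based depth percentile (type-7 linear interpolation), written out
percentile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# tiny deterministic gene table on one chromosome
toy_genes <- function() {
  data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
             start = c(10000, 40000), end = c(15000, 46000),
             strand = c("+", "-"), tss = c(10000, 46000),
             tes = c(15000, 40000), stringsAsFactors = FALSE)
}
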