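# Epigenetic divergence of duplicate gene pairs: z-scored promoter
# fold-enrichments, Pearson correlation / dissimilarity of promoter
# histone-mark profiles, chromatin-state count correlations in the 2-kb
# upstream window, and Wilcoxon rank-sum comparisons across fate classes.

#' Z-score a vector of log2 fold-enrichment ratios
#'
#' `z = (x - mean) / sd` with the population (n-denominator) standard
#' deviation, so the output has mean 0 and population sd exactly 1.
#'
#' @param log2_ratios Numeric vector over genes (>= 2 distinct values).
#' @return Numeric z-score vector.
#' @export
zscore_enrichment <- function(log2_ratios) {
  if (length(log2_ratios) < 2) stop("need at least 2 values")
  mu <- mean(log2_ratios)
  sd_pop <- sqrt(mean((log2_ratios - mu)^2))
  if (sd_pop == 0) stop("zero standard deviation: z-scores undefined")
  (log2_ratios - mu) / sd_pop
}

#' Correlation and dissimilarity of two promoter profiles
#'
#' Pearson r over the paired vectors and the dissimilarity index 1 - r.
#' Zero variance in either vector makes r undefined (NA, flagged).
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return List: `r`, `dissimilarity`, `degenerate`.
#' @export
pair_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  if (length(a) < 2) stop("need at least 2 profile entries")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, dissimilarity = NA_real_, degenerate = TRUE))
  r <- stats::cor(a, b)
  list(r = r, dissimilarity = 1 - r, degenerate = FALSE)
}

#' Binned mark-coverage profiles of gene promoters
#'
#' For each gene the 2-kb (by default) window immediately upstream of the
#' TSS (strand-aware) is split into `n_bins` bins, oriented 5' -> 3'
#' toward the TSS; each bin records the fraction of its bases covered by
#' the mark's peaks. Per-mark blocks are concatenated columnwise.
#'
#' @param genes Gene table.
#' @param peaks_by_mark Named list: mark -> peak interval data.frame.
#' @param window Upstream window in bp (default 2000).
#' @param n_bins Bins per mark (default 10).
#' @return Numeric matrix genes x (marks * n_bins), rownames = gene_id.
#' @export
promoter_epi_profile <- function(genes, peaks_by_mark, window = 2000,
                                 n_bins = 10) {
  if (window %% n_bins != 0) stop("window must be a multiple of n_bins")
  bw <- window / n_bins
  ng <- nrow(genes)
  plus <- genes$strand == "+"
  # upstream window: [tss - window, tss) on +, [tss, tss + window) on -
  gidx <- rep(seq_len(ng), each = n_bins)
  b <- rep(seq_len(n_bins) - 1, ng)  # 0 = most upstream bin
  left <- ifelse(plus[gidx], genes$tss[gidx] - window + b * bw,
                 genes$tss[gidx] + window - (b + 1) * bw)
  bins <- data.frame(chrom = genes$chrom[gidx], start = pmax(0, left),
                     end = pmax(0, left) + bw)
  marks <- names(peaks_by_mark)
  out <- matrix(0, ng, length(marks) * n_bins,
                dimnames = list(genes$gene_id, paste(
                  rep(marks, each = n_bins), rep(seq_len(n_bins), length(marks)),
                  sep = "_bin")))
  for (k in seq_along(marks)) {
    p <- merge_intervals(peaks_by_mark[[k]])
    if (!nrow(p)) next
    ov <- find_overlaps(bins, p)
    if (!nrow(ov)) next
    cov <- tapply(ov$overlap_bp, ov$query_idx, sum) / bw
    rows <- gidx[as.integer(names(cov))]
    cols <- (k - 1) * n_bins + b[as.integer(names(cov))] + 1
    out[cbind(rows, cols)] <- as.numeric(cov)
  }
  out
}

#' State-count correlation and shared counts for duplicate pairs
#'
#' For each pair, the number of segments of each of the 10 chromatin
#' states intersecting the 2-kb (default) upstream window of each copy;
#' the pair's correlation is the Pearson r of the two 10-dimensional count
#' vectors, and the per-state shared count is `min(count_d1, count_d2)`,
#' aggregated by fate category.
#'
#' @param pairs data.frame with columns d1, d2 (gene IDs) and fate.
#' @param genes Gene table containing all the IDs.
#' @param track State track data.frame.
#' @param window Upstream window in bp (default 2000).
#' @return List: `per_pair` (d1, d2, fate, r, uninformative) and
#'   `shared_by_fate` (fate, state, mean shared count).
#' @export
state_count_correlation <- function(pairs, genes, track, window = 2000) {
  rownames(genes) <- genes$gene_id
  count_window <- function(ids) {
    g <- genes[ids, , drop = FALSE]
    plus <- g$strand == "+"
    win <- data.frame(chrom = g$chrom,
                      start = pmax(0, ifelse(plus, g$tss - window, g$tss)),
                      end = ifelse(plus, g$tss, g$tss + window))
    win$end <- pmax(win$end, win$start)  # degenerate at chrom edge
    m <- matrix(0L, length(ids), 10, dimnames = list(ids, chromatin_states()))
    ok <- win$end > win$start
    if (any(ok)) {
      ov <- find_overlaps(win[ok, , drop = FALSE], track)
      if (nrow(ov)) {
        st <- track$state[ov$subject_idx]
        tab <- table(factor(which(ok)[ov$query_idx], levels = seq_along(ids)),
                     factor(st, levels = chromatin_states()))
        m <- m + as.matrix(tab)
      }
    }
    m
  }
  c1 <- count_window(pairs$d1)
  c2 <- count_window(pairs$d2)
  r <- numeric(nrow(pairs)); uninf <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (sum(c1[i, ]) == 0 && sum(c2[i, ]) == 0) {
      r[i] <- NA_real_; uninf[i] <- TRUE
    } else if (stats::sd(c1[i, ]) == 0 || stats::sd(c2[i, ]) == 0) {
      r[i] <- NA_real_; uninf[i] <- TRUE
    } else r[i] <- stats::cor(c1[i, ], c2[i, ])
  }
  shared <- pmin(c1, c2)
  sb <- do.call(rbind, lapply(split(seq_len(nrow(pairs)), pairs$fate),
    function(idx) data.frame(
      fate = pairs$fate[idx[1]], state = chromatin_states(),
      mean_shared = colMeans(shared[idx, , drop = FALSE]),
      stringsAsFactors = FALSE)))
  rownames(sb) <- NULL
  list(per_pair = data.frame(d1 = pairs$d1, d2 = pairs$d2, fate = pairs$fate,
                             r = r, uninformative = uninf,
                             stringsAsFactors = FALSE),
       shared_by_fate = sb)
}

#' Wilcoxon rank-sum comparison of two categories
#'
#' Exact enumeration when both groups together have at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with midrank ties and continuity correction. Two identical constant
#' groups return p = 1.
#'
#' @param values_a,values_b Numeric vectors (each >= 2).
#' @param exact_max Largest combined n for the exact mode (default 12).
#' @return List: `statistic` (rank-sum W of group a, Mann-Whitney form),
#'   `p_value`, `exact`.
#' @export
wilcoxon_category_compare <- function(values_a, values_b, exact_max = 12) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  if (length(unique(c(values_a, values_b))) == 1)
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1, exact = FALSE))
  ties <- any(duplicated(c(values_a, values_b)))
  use_exact <- !ties && (length(values_a) + length(values_b)) <= exact_max
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = use_exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = use_exact)
}
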