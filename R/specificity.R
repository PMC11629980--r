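# Tissue-specific gene calling from a TPM matrix and the mark/state
# specificity contrasts around the TSS of specific vs silenced genes.

#' Call tissue-specific genes from a TPM matrix
#'
#' A gene is specific to a tissue when either (i) its TPM is at least
#' 10-fold the *sum* of its TPM in all other tissues (`fold10` rule), or
#' (ii) its TPM is >= 1 while every other tissue is exactly zero
#' (`one_vs_zero` rule). Each specific gene is additionally flagged as
#' "silenced" in every other tissue, the contrast set used downstream.
#'
#' @param tpm Numeric matrix, genes x tissues, gene IDs as rownames.
#' @param fold_cutoff Fold threshold for the first rule (default 10).
#' @return data.frame of calls: gene_id, tissue, rule, fold (NA for
#'   one_vs_zero). The silenced contrast is in `attr(, "silenced")`
#'   (gene_id, tissue pairs).
#' @export
call_tissue_specific <- function(tpm, fold_cutoff = 10) {
  if (is.null(rownames(tpm))) stop("tpm needs gene IDs as rownames")
  if (ncol(tpm) < 2) stop("need at least 2 tissues")
  if (any(tpm < 0)) stop("negative TPM value")
  tissues <- colnames(tpm)
  total <- rowSums(tpm)
  calls <- list(); silenced <- list()
  for (j in seq_along(tissues)) {
    v <- tpm[, j]
    rest <- total - v
    fold <- ifelse(rest > 0, v / rest, Inf)
    f10 <- rest > 0 & fold >= fold_cutoff
    ovz <- rest == 0 & v >= 1
    hit <- f10 | ovz
    if (any(hit)) {
      calls[[j]] <- data.frame(
        gene_id = rownames(tpm)[hit], tissue = tissues[j],
        rule = ifelse(ovz[hit], "one_vs_zero", "fold10"),
        fold = ifelse(ovz[hit], NA_real_, fold[hit]),
        stringsAsFactors = FALSE)
      silenced[[j]] <- data.frame(
        gene_id = rep(rownames(tpm)[hit], each = length(tissues) - 1),
        tissue = rep(setdiff(tissues, tissues[j]), sum(hit)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene_id = character(), tissue = character(),
               rule = character(), fold = numeric())
  rownames(out) <- NULL
  attr(out, "silenced") <- if (length(silenced)) do.call(rbind, silenced) else
    data.frame(gene_id = character(), tissue = character())
  out
}

#' Relative abundance of marks unique to specific vs silenced genes
#'
#' For each tissue-specific gene, a mark "uniquely exists" at the gene when
#' exactly one tissue's peak set for that mark overlaps the +/- `window`
#' TSS window. Unique occurrences in the specific tissue count toward the
#' specific set; unique occurrences in a tissue where the gene is silenced
#' count toward the silenced set. Counts are normalized by the mark's
#' genome-wide peak total in the corresponding tissue, then summed over
#' tissues.
#'
#' @param calls Output of [call_tissue_specific()].
#' @param peaks_by_tissue Named list: tissue -> named list: mark -> interval
#'   data.frame.
#' @param genes Gene table.
#' @param window Half-window around the TSS in bp (default 3000).
#' @return data.frame per mark: n_specific, n_silenced (raw unique counts)
#'   and rel_specific, rel_silenced (normalized relative abundances).
#' @export
unique_marks_near_specific_genes <- function(calls, peaks_by_tissue, genes,
                                             window = 3000) {
  tissues <- names(peaks_by_tissue)
  marks <- unique(unlist(lapply(peaks_by_tissue, names)))
  win <- flank_tss(genes, window, window)
  rownames(win) <- win$gene_id
  totals <- sapply(marks, function(m) sapply(tissues, function(t) {
    p <- peaks_by_tissue[[t]][[m]]
    if (is.null(p)) NA_integer_ else nrow(p)
  }), simplify = FALSE)
  res <- lapply(marks, function(m) {
    n_spec <- 0; n_sil <- 0; rel_spec <- 0; rel_sil <- 0
    for (k in seq_len(nrow(calls))) {
      g <- calls$gene_id[k]; spec_t <- calls$tissue[k]
      w <- win[g, , drop = FALSE]
      hit_t <- character()
      for (t in tissues) {
        p <- peaks_by_tissue[[t]][[m]]
        if (is.null(p)) next
        if (nrow(find_overlaps(w, p))) hit_t <- c(hit_t, t)
      }
      if (length(hit_t) == 1) {
        tot <- totals[[m]][hit_t]
        if (is.na(tot) || tot == 0) next
        if (hit_t == spec_t) {
          n_spec <- n_spec + 1; rel_spec <- rel_spec + 1 / tot
        } else {
          n_sil <- n_sil + 1; rel_sil <- rel_sil + 1 / tot
        }
      }
    }
    data.frame(mark = m, n_specific = n_spec, n_silenced = n_sil,
               rel_specific = rel_spec, rel_silenced = rel_sil,
               stringsAsFactors = FALSE)
  })
  missing <- unlist(lapply(tissues, function(t)
    setdiff(marks, names(peaks_by_tissue[[t]]))))
  if (length(missing))
    warning("mark(s) missing in some tissue and skipped there: ",
            paste(unique(missing), collapse = ", "))
  do.call(rbind, res)
}

#' Pearson chi-square for specific vs silenced mark counts
#'
#' A 2x2 test (count vs remainder in each condition) without continuity
#' correction, 1 degree of freedom.
#'
#' @param count_specific,total_specific Count and total in the specific set.
#' @param count_silenced,total_silenced Count and total in the silenced set.
#' @return List with `statistic`, `p_value`, and `low_expected` (TRUE when
#'   any expected cell is below 1).
#' @export
chi_square_specific_vs_silenced <- function(count_specific, total_specific,
                                            count_silenced, total_silenced) {
  if (total_specific <= 0 || total_silenced <= 0) stop("totals must be > 0")
  if (count_specific > total_specific || count_silenced > total_silenced)
    stop("count exceeds total")
  tab <- rbind(c(count_specific, total_specific - count_specific),
               c(count_silenced, total_silenced - count_silenced))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin)")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(tab == expected))
    return(list(statistic = 0, p_value = 1, low_expected = any(expected < 1)))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       low_expected = any(expected < 1))
}

#' Feature density near the TSS versus expression level
#'
#' Per gene, either the number of feature intervals overlapping the
#' +/- `window` TSS window (`type = "count"`) or the fraction of window
#' bases covered (`type = "fraction"`, the state convention). Genes are
#' binned by log10 TPM (zeros replaced by a pseudocount) into equal-width
#' bins, and a simple linear fit of density on log10 TPM gives the R^2.
#'
#' @param features Interval data.frame (peaks or state segments).
#' @param genes Gene table.
#' @param tpm Named numeric vector of TPM, names = gene_id.
#' @param window Half-window in bp (default 3000).
#' @param type "count" or "fraction".
#' @param n_bins Number of expression bins (default 20).
#' @param pseudo Pseudocount replacing zero TPM (default 0.01).
#' @return List: `per_gene` (gene_id, log10_tpm, density), `bins`
#'   (bin mean log10 TPM, mean density, n), `r_squared`, `slope`,
#'   `p_value`.
#' @export
density_vs_expression <- function(features, genes, tpm, window = 3000,
                                  type = c("count", "fraction"),
                                  n_bins = 20, pseudo = 0.01) {
  type <- match.arg(type)
  tpm <- tpm[genes$gene_id]
  if (anyNA(tpm)) stop("tpm missing for some genes")
  win <- flank_tss(genes, window, window)
  dens <- numeric(nrow(genes))
  ov <- find_overlaps(win, features)
  if (nrow(ov)) {
    if (type == "count") {
      cnt <- table(ov$query_idx)
      dens[as.integer(names(cnt))] <- as.numeric(cnt)
    } else {
      # covered-base fraction: merge features first so bases count once
      ov2 <- find_overlaps(win, merge_intervals(features))
      agg <- tapply(ov2$overlap_bp, ov2$query_idx, sum)
      dens[as.integer(names(agg))] <-
        as.numeric(agg) / (win$end - win$start)[as.integer(names(agg))]
    }
  }
  lt <- log10(ifelse(tpm == 0, pseudo, tpm))
  if (stats::var(dens) == 0) {
    # no variance to explain: flat fit, R^2 = 0 by convention
    fit <- NULL
    sm <- list(r.squared = 0, coefficients = matrix(nrow = 1, ncol = 4))
  } else {
    fit <- stats::lm(dens ~ lt)
    sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  }
  edges <- seq(min(lt), max(lt), length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(lt, edges, rightmost.closed = TRUE), 1), n_bins)
  counts <- tabulate(idx, n_bins)
  if (any(counts == 0)) warning(sum(counts == 0), " empty expression bin(s) dropped")
  bins <- data.frame(
    bin = which(counts > 0),
    mean_log10_tpm = tapply(lt, idx, mean)[as.character(which(counts > 0))],
    mean_density = tapply(dens, idx, mean)[as.character(which(counts > 0))],
    n = counts[counts > 0])
  rownames(bins) <- NULL
  list(per_gene = data.frame(gene_id = genes$gene_id, log10_tpm = lt,
                             density = dens, stringsAsFactors = FALSE),
       bins = bins,
       r_squared = sm$r.squared,
       slope = if (is.null(fit)) 0 else unname(stats::coef(fit)[2]),
       p_value = if (!is.null(fit) && nrow(sm$coefficients) > 1)
         sm$coefficients[2, 4] else NA_real_)
}
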