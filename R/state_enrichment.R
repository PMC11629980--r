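# Base-level fold enrichment of chromatin states against genomic elements,
# per-state track summaries, and state density meta-profiles around TSSs.

#' Fold enrichment of a chromatin state in a set of elements
#'
#' The statistic is `(C/A) / (B/D)` where A is the number of bases in the
#' state, B the bases in the element set, C the bases overlapping between
#' the two, and D the genome size. Element intervals are merged before B and
#' C are counted, so each base counts once; a value of 1 means no
#' enrichment. When the state or element covers zero bases the fold is
#' undefined and reported as `NA`.
#'
#' @param track State track data.frame (chrom, start, end, state).
#' @param elements Interval data.frame of the element set.
#' @param genome A [genome_model()].
#' @param state State label to score; `NULL` scores every state present in
#'   the 10-state vocabulary.
#' @return data.frame with columns state, A, B, C, D, fold.
#' @export
fold_enrichment <- function(track, elements, genome, state = NULL) {
  validate_intervals(track, "track")
  validate_intervals(elements, "elements")
  states <- if (is.null(state)) chromatin_states() else state
  elem <- merge_intervals(elements)
  B <- sum(elem$end - elem$start)
  D <- genome$D
  out <- lapply(states, function(s) {
    seg <- track[track$state == s, , drop = FALSE]
    A <- if (nrow(seg)) interval_bases(seg) else 0
    C <- if (nrow(seg) && nrow(elem)) {
      ov <- find_overlaps(seg, elem)
      sum(ov$overlap_bp)
    } else 0
    fold <- if (A == 0 || B == 0) NA_real_ else (C / A) / (B / D)
    data.frame(state = s, A = A, B = B, C = C, D = D, fold = fold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize a chromatin-state track
#'
#' Per-state segment count, percentage of the genome covered, and mean and
#' median segment length. When the track is not a complete tiling of the
#' genome the percentages are still reported against the genome size, with
#' a warning.
#'
#' @param track State track data.frame.
#' @param genome A [genome_model()].
#' @return data.frame with state, count, pct_genome, mean_length,
#'   median_length; states absent from the track get zero rows.
#' @export
state_summary <- function(track, genome) {
  validate_intervals(track, "track")
  len <- track$end - track$start
  covered <- sum(len)
  if (abs(covered - genome$D) > 1e-6)
    warning("track covers ", covered, " of ", genome$D,
            " bases; percentages are relative to genome size")
  out <- lapply(chromatin_states(), function(s) {
    li <- len[track$state == s]
    data.frame(state = s,
               count = length(li),
               pct_genome = 100 * sum(li) / genome$D,
               mean_length = if (length(li)) mean(li) else NA_real_,
               median_length = if (length(li)) stats::median(li) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Density of each chromatin state relative to the TSS
#'
#' For each offset bin in `[-window, +window)` the profile reports the
#' fraction of genes whose bin is covered (any overlap) by the state, with
#' strand-aware orientation: negative offsets are upstream of the TSS.
#'
#' @param track State track data.frame.
#' @param genes Gene table.
#' @param window Half-window in bp (default 5000).
#' @param bin Bin width in bp; must divide `window`.
#' @param states States to profile (default: all present in the track).
#' @return data.frame with state, offset (bin left edge, bp relative to
#'   TSS) and density in [0, 1].
#' @export
state_density_profile <- function(track, genes, window = 5000, bin = 100,
                                  states = NULL) {
  if (!nrow(genes)) stop("no genes supplied")
  if (window %% bin != 0) stop("window must be a multiple of bin")
  if (is.null(states)) states <- intersect(chromatin_states(),
                                           unique(track$state))
  offsets <- seq(-window, window - bin, by = bin)
  nb <- length(offsets)
  tssb <- .tss_base(genes)
  plus <- genes$strand == "+"
  # genomic left edge of each (gene, bin): for minus-strand genes upstream
  # bins mirror toward larger coordinates
  gene_idx <- rep(seq_len(nrow(genes)), each = nb)
  off <- rep(offsets, times = nrow(genes))
  left <- ifelse(plus[gene_idx], tssb[gene_idx] + off,
                 tssb[gene_idx] - off - bin + 1)
  bins <- data.frame(chrom = genes$chrom[gene_idx],
                     start = pmax(0, left), end = left + bin)
  keep <- bins$start < bins$end & bins$start >= 0
  out <- lapply(states, function(s) {
    seg <- track[track$state == s, , drop = FALSE]
    density <- numeric(nb)
    if (nrow(seg)) {
      hit <- rep(FALSE, nrow(bins))
      ov <- find_overlaps(bins[keep, , drop = FALSE], seg)
      hit[which(keep)[unique(ov$query_idx)]] <- TRUE
      density <- tapply(hit, off, mean)[as.character(offsets)]
    }
    data.frame(state = s, offset = offsets, density = as.numeric(density),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
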