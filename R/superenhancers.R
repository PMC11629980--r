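# ROSE-style super-enhancer detection: stitch H3K27ac peaks within 12.5 kb,
# rank stitched clusters by signal, and separate super-enhancers from
# conventional enhancers at the tangent-slope-1 point of the scaled ranked
# curve.

#' Stitch enhancer peaks into clusters
#'
#' Peaks whose nearest edges lie within `gap` bp of each other on the same
#' chromosome are clustered transitively; each cluster spans from the first
#' member's start to the last member's end and carries the summed signal.
#'
#' @param peaks Interval data.frame with a `signal` column (non-negative).
#' @param gap Maximum edge-to-edge gap in bp (default 12500).
#' @return data.frame chrom, start, end, signal, n_peaks; sorted by
#'   (chrom, start).
#' @export
stitch <- function(peaks, gap = 12500) {
  validate_intervals(peaks, "peaks")
  if (is.null(peaks$signal)) stop("peaks need a 'signal' column")
  if (any(peaks$signal < 0)) stop("negative peak signal")
  if (!nrow(peaks))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      signal = numeric(), n_peaks = integer()))
  p <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  n <- nrow(p)
  id <- integer(n)
  id[1] <- 1L
  cur_end <- p$end[1]
  if (n > 1) for (i in 2:n) {
    if (p$chrom[i] != p$chrom[i - 1] || p$start[i] - cur_end > gap) {
      id[i] <- id[i - 1] + 1L
      cur_end <- p$end[i]
    } else {
      id[i] <- id[i - 1]
      cur_end <- max(cur_end, p$end[i])
    }
  }
  out <- data.frame(
    chrom = tapply(p$chrom, id, `[`, 1),
    start = as.numeric(tapply(p$start, id, min)),
    end = as.numeric(tapply(p$end, id, max)),
    signal = as.numeric(tapply(p$signal, id, sum)),
    n_peaks = as.integer(tapply(p$start, id, length)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call super-enhancers on stitched clusters
#'
#' Clusters are sorted by ascending signal; ranks and signals are scaled to
#' `[0, 1]` and the tangent slope of the scaled curve is estimated by a
#' trailing finite difference over a smoothing half-window of
#' `max(1, round(n/100))` ranks (rank 1 uses a forward difference). The
#' cutoff rank is the last rank whose slope is <= `slope_cutoff`, and
#' super-enhancers are the clusters whose scaled signal exceeds the scaled
#' signal at that rank — the maximal high-signal tail where the curve rises
#' faster than the diagonal.
#'
#' @param clusters Output of [stitch()] (>= 3 rows).
#' @param slope_cutoff Tangent-slope threshold (default 1; slope <= cutoff
#'   is a conventional enhancer).
#' @return The clusters with rank, scaled_rank, scaled_signal, slope and
#'   is_super columns, in ascending signal order.
#' @export
call_superenhancers <- function(clusters, slope_cutoff = 1) {
  if (nrow(clusters) < 3) stop("need at least 3 stitched clusters")
  o <- order(clusters$signal, clusters$chrom, clusters$start, clusters$end)
  x <- clusters[o, , drop = FALSE]
  n <- nrow(x)
  x$rank <- seq_len(n)
  x$scaled_rank <- (x$rank - 1) / (n - 1)
  rng <- range(x$signal)
  if (diff(rng) == 0) {
    warning("all cluster signals equal; no super-enhancers called")
    x$scaled_signal <- 0; x$slope <- NA_real_; x$is_super <- FALSE
    rownames(x) <- NULL
    return(x)
  }
  x$scaled_signal <- (x$signal - rng[1]) / diff(rng)
  h <- max(1L, as.integer(round(n / 100)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- seq_len(n)
  hi[1] <- 1L + h  # forward difference at the first rank
  lo[1] <- 1L
  slope <- (x$scaled_signal[hi] - x$scaled_signal[lo]) /
    (x$scaled_rank[hi] - x$scaled_rank[lo])
  x$slope <- slope
  below <- which(slope <= slope_cutoff)
  if (!length(below)) {
    x$is_super <- TRUE
  } else {
    i_star <- max(below)
    x$is_super <- x$scaled_signal > x$scaled_signal[i_star]
  }
  rownames(x) <- NULL
  x
}

#' Merge super-enhancers across tissues
#'
#' Single-linkage merging: two SEs are linked when their overlap is at
#' least `min_overlap_frac` of the shorter SE's length (or of both lengths
#' with `reciprocal = TRUE`); connected components become nonredundant SEs
#' spanning the union of their members.
#'
#' @param se_by_tissue Named list: tissue -> interval data.frame of SEs.
#' @param min_overlap_frac Overlap fraction threshold (default 0.5).
#' @param reciprocal Require the fraction of both SEs, not just the shorter.
#' @return List: `merged` (chrom, start, end, n_members, n_tissues,
#'   tissues) and `sharing` (logical matrix, merged SE x tissue).
#' @export
merge_across_tissues <- function(se_by_tissue, min_overlap_frac = 0.5,
                                 reciprocal = FALSE) {
  tissues <- names(se_by_tissue)
  all_se <- do.call(rbind, lapply(tissues, function(t) {
    x <- se_by_tissue[[t]]
    if (!nrow(x)) return(NULL)
    data.frame(chrom = x$chrom, start = x$start, end = x$end, tissue = t,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_se) || !nrow(all_se))
    return(list(merged = data.frame(), sharing = matrix(logical(), 0, 0)))
  n <- nrow(all_se)
  ov <- find_overlaps(all_se, all_se)
  ov <- ov[ov$query_idx < ov$subject_idx, , drop = FALSE]
  len <- all_se$end - all_se$start
  shorter <- pmin(len[ov$query_idx], len[ov$subject_idx])
  longer <- pmax(len[ov$query_idx], len[ov$subject_idx])
  ref <- if (reciprocal) longer else shorter
  keep <- ov$overlap_bp >= min_overlap_frac * ref
  # union-find over linked SEs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in which(keep)) {
    a <- find(ov$query_idx[k]); b <- find(ov$subject_idx[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n), find, 1L)
  comp <- match(comp, unique(comp))
  merged <- data.frame(
    chrom = tapply(all_se$chrom, comp, `[`, 1),
    start = as.numeric(tapply(all_se$start, comp, min)),
    end = as.numeric(tapply(all_se$end, comp, max)),
    n_members = as.integer(tapply(comp, comp, length)),
    stringsAsFactors = FALSE)
  sharing <- matrix(FALSE, nrow(merged), length(tissues),
                    dimnames = list(NULL, tissues))
  for (k in seq_len(n)) sharing[comp[k], all_se$tissue[k]] <- TRUE
  merged$n_tissues <- rowSums(sharing)
  merged$tissues <- apply(sharing, 1, function(r)
    paste(tissues[r], collapse = ","))
  o <- order(merged$chrom, merged$start, merged$end)
  list(merged = merged[o, , drop = FALSE], sharing = sharing[o, , drop = FALSE])
}

#' Assign super-enhancers to nearby genes
#'
#' An SE is assigned to every gene whose body extended by `window` bp on
#' both sides intersects it. Assignments are annotated by the gene's
#' expression class in the SE's tissue context: expressed (TPM >
#' `expressed_tpm`), repressed (TPM < `repressed_tpm`) or intermediate.
#'
#' @param ses SE interval data.frame.
#' @param genes Gene table.
#' @param tpm Named TPM vector for the relevant tissue (names = gene_id).
#' @param window Gene-body extension in bp (default 10000).
#' @param expressed_tpm,repressed_tpm Class thresholds (defaults 2 and 0.2).
#' @return List: `assignments` (se_idx, gene_id, tpm, class) and `summary`
#'   (n_assigned_se, n_genes, n_se_expressed, n_se_repressed).
#' @export
assign_genes <- function(ses, genes, tpm, window = 10000,
                         expressed_tpm = 2, repressed_tpm = 0.2) {
  ext <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$start - window),
                    end = genes$end + window)
  ov <- find_overlaps(ses, ext)
  if (!nrow(ov)) {
    assignments <- data.frame(se_idx = integer(), gene_id = character(),
                              tpm = numeric(), class = character())
  } else {
    gid <- genes$gene_id[ov$subject_idx]
    gt <- tpm[gid]
    cls <- ifelse(gt > expressed_tpm, "expressed",
                  ifelse(gt < repressed_tpm, "repressed", "intermediate"))
    assignments <- data.frame(se_idx = ov$query_idx, gene_id = gid,
                              tpm = as.numeric(gt), class = cls,
                              stringsAsFactors = FALSE)
  }
  list(assignments = assignments,
       summary = data.frame(
         n_assigned_se = length(unique(assignments$se_idx)),
         n_genes = length(unique(assignments$gene_id)),
         n_se_expressed = length(unique(
           assignments$se_idx[assignments$class == "expressed"])),
         n_se_repressed = length(unique(
           assignments$se_idx[assignments$class == "repressed"]))))
}
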