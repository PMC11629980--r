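# Per-CpG methylation levels from bisulfite counts, depth filtering, and
# meta-profiles around TSSs and chromatin-state bodies.

#' Add level and depth columns to a CpG site table
#'
#' The methylation level of a site is the number of reads calling C divided
#' by the total number of reads calling C and T; sites with zero depth get
#' an undefined (NA) level.
#'
#' @param sites data.frame with chrom, pos (0-based bp), reads_c, reads_t.
#' @return `sites` with `depth` and `level` columns.
#' @export
methylation_level <- function(sites) {
  if (any(sites$reads_c < 0 | sites$reads_t < 0)) stop("negative read count")
  sites$depth <- sites$reads_c + sites$reads_t
  sites$level <- ifelse(sites$depth > 0, sites$reads_c / sites$depth, NA_real_)
  sites
}

#' Depth-filter CpG sites
#'
#' Removes sites with depth below `min_depth` and sites whose depth exceeds
#' the sample's `max_quantile` depth percentile (computed on the unfiltered
#' table, linear-interpolation quantile), the standard guard against PCR
#' duplicates.
#'
#' @param sites CpG site table (one sample).
#' @param min_depth Minimum read depth (default 10).
#' @param max_quantile Upper depth quantile (default 0.999).
#' @return Filtered site table with level/depth columns.
#' @export
filter_sites <- function(sites, min_depth = 10, max_quantile = 0.999) {
  sites <- methylation_level(sites)
  if (!nrow(sites)) return(sites)
  qd <- stats::quantile(sites$depth, max_quantile, names = FALSE, type = 7)
  sites[sites$depth >= min_depth & sites$depth <= qd, , drop = FALSE]
}

#' Mean methylation profile around TSSs
#'
#' Strand-aware meta-profile: each site within `window` bp of a gene's TSS
#' contributes to the distance bin of that gene; levels are first averaged
#' per (gene, bin) and then across genes with equal gene weight, so
#' CpG-dense genes do not dominate. Negative offsets are upstream.
#'
#' @param sites Filtered CpG site table.
#' @param genes Gene table.
#' @param window Half-window in bp (default 10000).
#' @param bin Bin width in bp (default 100).
#' @return data.frame offset (bin left edge in bp relative to the TSS),
#'   mean_level, n_genes; bins with no data have NA mean_level.
#' @export
tss_methylation_profile <- function(sites, genes, window = 10000, bin = 100) {
  if (window %% bin != 0) stop("window must be a multiple of bin")
  sites <- methylation_level(sites)
  offsets <- seq(-window, window - bin, by = bin)
  tssb <- .tss_base(genes)
  wins <- data.frame(chrom = genes$chrom,
                     start = pmax(0, tssb - window),
                     end = tssb + window)
  sp <- data.frame(chrom = sites$chrom, start = sites$pos,
                   end = sites$pos + 1)
  ov <- find_overlaps(sp, wins)
  if (!nrow(ov))
    return(data.frame(offset = offsets, mean_level = NA_real_, n_genes = 0L))
  d <- ifelse(genes$strand[ov$subject_idx] == "+",
              sites$pos[ov$query_idx] - tssb[ov$subject_idx],
              tssb[ov$subject_idx] - sites$pos[ov$query_idx])
  keep <- d >= -window & d < window & !is.na(sites$level[ov$query_idx])
  dt <- data.table::data.table(
    gene = ov$subject_idx[keep],
    off = bin * floor(d[keep] / bin),
    level = sites$level[ov$query_idx[keep]])
  per_gene <- dt[, list(level = mean(level)), by = c("gene", "off")]
  prof <- per_gene[, list(mean_level = mean(level), n_genes = .N), by = "off"]
  out <- data.frame(offset = offsets)
  m <- match(out$offset, prof$off)
  out$mean_level <- prof$mean_level[m]
  out$n_genes <- ifelse(is.na(m), 0L, prof$n_genes[m])
  out
}

#' Mean methylation across scaled chromatin-state bodies
#'
#' Each state instance's body is rescaled to `n_body_bins` bins; the
#' `flank` bp on either side are binned at `flank_bin` bp resolution.
#' Site levels are averaged per bin across all instances of the state.
#'
#' @param sites Filtered CpG site table.
#' @param track State track data.frame.
#' @param flank Flank size in bp (default 2000).
#' @param n_body_bins Number of scaled body bins (default 20).
#' @param flank_bin Flank bin width in bp (default 100).
#' @param states States to profile (default: all present).
#' @return data.frame state, bin (integers; `-n_flank .. -1` left flank,
#'   `0 .. n_body_bins-1` body, `n_body_bins ..` right flank), mean_level,
#'   n_sites. States without instances are omitted with a warning.
#' @export
state_methylation_profile <- function(sites, track, flank = 2000,
                                      n_body_bins = 20, flank_bin = 100,
                                      states = NULL) {
  if (flank %% flank_bin != 0) stop("flank must be a multiple of flank_bin")
  sites <- methylation_level(sites)
  if (is.null(states)) states <- intersect(chromatin_states(),
                                           unique(track$state))
  sp <- data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1)
  out <- lapply(states, function(s) {
    seg <- track[track$state == s, , drop = FALSE]
    if (!nrow(seg)) {
      warning("state ", s, " has no instances; omitted")
      return(NULL)
    }
    ext <- data.frame(chrom = seg$chrom,
                      start = pmax(0, seg$start - flank),
                      end = seg$end + flank)
    ov <- find_overlaps(sp, ext)
    if (!nrow(ov)) return(NULL)
    pos <- sites$pos[ov$query_idx]
    st <- seg$start[ov$subject_idx]; en <- seg$end[ov$subject_idx]
    lvl <- sites$level[ov$query_idx]
    bin <- ifelse(pos < st, floor((pos - st) / flank_bin),
           ifelse(pos >= en, n_body_bins + floor((pos - en) / flank_bin),
                  floor((pos - st) / (en - st) * n_body_bins)))
    ok <- !is.na(lvl)
    dt <- data.table::data.table(bin = bin[ok], level = lvl[ok])
    prof <- dt[, list(mean_level = mean(level), n_sites = .N), by = "bin"]
    data.frame(state = s, bin = prof$bin, mean_level = prof$mean_level,
               n_sites = prof$n_sites, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(state = character(), bin = integer(),
                      mean_level = numeric(), n_sites = integer()))
  res <- res[order(res$state, res$bin), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Promoter methylation versus expression
#'
#' Per gene, the mean level of filtered sites within +/- `window` of the
#' TSS, correlated (Pearson) against log10 TPM with a pseudocount for zero
#' expression.
#'
#' @param sites Filtered CpG site table.
#' @param genes Gene table.
#' @param tpm Named TPM vector (names = gene_id) for the matched tissue.
#' @param window Half-window in bp (default 3000).
#' @param pseudo Pseudocount for zero TPM (default 0.01).
#' @return List: `per_gene` (gene_id, mean_level, log10_tpm), `r`,
#'   `r_squared`, `p_value`; `r` is NA (flagged `degenerate = TRUE`) when
#'   either variable has zero variance.
#' @export
methylation_expression_association <- function(sites, genes, tpm,
                                               window = 3000, pseudo = 0.01) {
  sites <- methylation_level(sites)
  win <- flank_tss(genes, window, window)
  sp <- data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1)
  ov <- find_overlaps(sp, win)
  lvl <- sites$level[ov$query_idx]
  ok <- !is.na(lvl)
  mean_level <- tapply(lvl[ok], ov$subject_idx[ok], mean)
  idx <- as.integer(names(mean_level))
  if (length(idx) < 3) stop("fewer than 3 genes with methylation data")
  gid <- genes$gene_id[idx]
  tv <- tpm[gid]
  lt <- log10(ifelse(tv == 0, pseudo, tv))
  per_gene <- data.frame(gene_id = gid, mean_level = as.numeric(mean_level),
                         log10_tpm = as.numeric(lt), stringsAsFactors = FALSE)
  if (stats::sd(per_gene$mean_level) == 0 || stats::sd(per_gene$log10_tpm) == 0)
    return(list(per_gene = per_gene, r = NA_real_, r_squared = NA_real_,
                p_value = NA_real_, degenerate = TRUE))
  ht <- stats::cor.test(per_gene$mean_level, per_gene$log10_tpm)
  list(per_gene = per_gene, r = unname(ht$estimate),
       r_squared = unname(ht$estimate)^2, p_value = ht$p.value,
       degenerate = FALSE)
}
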