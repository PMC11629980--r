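# QTL-regulatory element analysis: overlap of enhancer states with QTL,
# per-chromosome observed/expected enrichment, and the four-way
# SNP / QTL / enhancer / motif intersection with motif-family summaries.

#' Overlap of enhancer-state segments with QTL
#'
#' Every (enhancer segment, QTL) intersecting pair is counted; the summary
#' reports, per state, the number of distinct segments hit, the number of
#' pairs, mean and median pairwise overlap in bp, and the number of
#' chromosomes involved.
#'
#' @param track State track data.frame.
#' @param qtl QTL interval data.frame (optionally with `label` = trait).
#' @param states Enhancer states to score (default genic/strong/mid).
#' @return List: `summary` (per state) and `pairs` (segment and QTL row
#'   indices with overlap_bp and state).
#' @export
qtl_enhancer_overlap <- function(track, qtl, states = qtl_enhancer_states()) {
  validate_intervals(qtl, "qtl")
  pairs <- list()
  summ <- lapply(states, function(s) {
    seg <- track[track$state == s, , drop = FALSE]
    ov <- if (nrow(seg)) find_overlaps(seg, qtl) else
      data.frame(query_idx = integer(), subject_idx = integer(),
                 overlap_bp = numeric())
    if (nrow(ov))
      pairs[[s]] <<- data.frame(state = s,
                                segment_idx = which(track$state == s)[ov$query_idx],
                                qtl_idx = ov$subject_idx,
                                overlap_bp = ov$overlap_bp,
                                chrom = seg$chrom[ov$query_idx],
                                stringsAsFactors = FALSE)
    data.frame(state = s,
               n_segments = length(unique(ov$query_idx)),
               n_pairs = nrow(ov),
               mean_overlap = if (nrow(ov)) mean(ov$overlap_bp) else NA_real_,
               median_overlap = if (nrow(ov)) stats::median(ov$overlap_bp) else NA_real_,
               n_chroms = length(unique(seg$chrom[ov$query_idx])),
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, summ),
       pairs = if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE)) else
         data.frame(state = character(), segment_idx = integer(),
                    qtl_idx = integer(), overlap_bp = numeric(),
                    chrom = character()))
}

#' Per-chromosome fold enrichment (observed / expected)
#'
#' The expected count on a chromosome is the total observed count scaled by
#' the chromosome's share of the genome length; fold = observed/expected.
#' With `weight_by` a named vector (e.g. QTL bases per chromosome), the
#' expectation is proportional to those weights instead.
#'
#' @param observed Named integer vector of observed counts per chromosome.
#' @param genome A [genome_model()].
#' @param weight_by Optional named non-negative weights per chromosome.
#' @return data.frame chrom, observed, expected, fold (NA when expected 0).
#' @export
per_chromosome_fold <- function(observed, genome, weight_by = NULL) {
  chroms <- names(genome$chrom_sizes)
  obs <- stats::setNames(numeric(length(chroms)), chroms)
  obs[names(observed)] <- observed
  w <- if (is.null(weight_by)) genome$chrom_sizes else {
    ww <- stats::setNames(numeric(length(chroms)), chroms)
    ww[names(weight_by)] <- weight_by
    ww
  }
  total <- sum(obs)
  expected <- if (total == 0 || sum(w) == 0) rep(NA_real_, length(chroms)) else
    total * w / sum(w)
  data.frame(chrom = chroms, observed = as.numeric(obs),
             expected = as.numeric(expected),
             fold = ifelse(!is.na(expected) & expected > 0,
                           obs / expected, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read SNP positions from a minimal VCF or TSV
#'
#' VCF `#` header lines are skipped; the first three columns are CHROM,
#' POS (1-based) and ID. A TSV with header snp_id, chrom, pos is also
#' accepted.
#'
#' @param path File path.
#' @return data.frame snp_id, chrom, pos (1-based).
#' @export
read_snps <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = numeric()))
  first <- strsplit(body[1], "\t")[[1]]
  if (identical(tolower(first[1:3]), c("snp_id", "chrom", "pos"))) {
    df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    return(df[, c("snp_id", "chrom", "pos")])
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  data.frame(snp_id = vapply(parts, `[`, "", 3L),
             chrom = vapply(parts, `[`, "", 1L),
             pos = as.numeric(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' SNPs inside QTL, enhancer states and TF binding motifs
#'
#' A SNP is retained when its position (1-based, treated internally as a
#' 1-bp interval) lies inside at least one QTL, one segment labeled with an
#' enhancer state, and one motif occurrence. One hit row is emitted per
#' (SNP, QTL, segment, motif) combination; the family summary is computed
#' over deduplicated (SNP, family) pairs.
#'
#' @param snps data.frame snp_id, chrom, pos (1-based).
#' @param qtl QTL intervals (optional `label` = trait).
#' @param track State track.
#' @param motifs Motif intervals with `label` = motif id and a `tf_family`
#'   column.
#' @param states Enhancer states (default genic/strong/mid).
#' @return List: `hits` (one row per combination), `n_snps` (deduplicated
#'   SNP count), `n_hits` (combination count), `family_summary` (family,
#'   n_snps, pct over unique SNP-family pairs).
#' @export
intersect_snp_qtl_enhancer_motif <- function(snps, qtl, track, motifs,
                                             states = qtl_enhancer_states()) {
  if (is.null(motifs$tf_family)) stop("motifs need a 'tf_family' column")
  sp <- data.frame(chrom = snps$chrom, start = snps$pos - 1, end = snps$pos)
  seg <- track[track$state %in% states, , drop = FALSE]
  ov_q <- find_overlaps(sp, qtl)
  ov_e <- find_overlaps(sp, seg)
  ov_m <- find_overlaps(sp, motifs)
  empty <- data.frame(snp_id = character(), chrom = character(),
                      pos = numeric(), qtl_idx = integer(),
                      trait = character(), segment_state = character(),
                      motif_id = character(), tf_family = character())
  keep <- intersect(intersect(unique(ov_q$query_idx), unique(ov_e$query_idx)),
                    unique(ov_m$query_idx))
  if (!length(keep))
    return(list(hits = empty, n_snps = 0L, n_hits = 0L,
                family_summary = data.frame(tf_family = character(),
                                            n_snps = integer(),
                                            pct = numeric())))
  hits <- do.call(rbind, lapply(keep, function(i) {
    qi <- ov_q$subject_idx[ov_q$query_idx == i]
    ei <- ov_e$subject_idx[ov_e$query_idx == i]
    mi <- ov_m$subject_idx[ov_m$query_idx == i]
    combo <- expand.grid(qtl_idx = qi, seg_idx = ei, motif_idx = mi)
    data.frame(snp_id = snps$snp_id[i], chrom = snps$chrom[i],
               pos = snps$pos[i], qtl_idx = combo$qtl_idx,
               trait = if (!is.null(qtl$label)) qtl$label[combo$qtl_idx] else NA_character_,
               segment_state = seg$state[combo$seg_idx],
               motif_id = if (!is.null(motifs$label)) motifs$label[combo$motif_idx] else NA_character_,
               tf_family = motifs$tf_family[combo$motif_idx],
               stringsAsFactors = FALSE)
  }))
  sf <- unique(hits[, c("snp_id", "tf_family")])
  fam <- as.data.frame(table(sf$tf_family), stringsAsFactors = FALSE)
  names(fam) <- c("tf_family", "n_snps")
  fam$pct <- 100 * fam$n_snps / sum(fam$n_snps)
  list(hits = hits, n_snps = length(unique(hits$snp_id)), n_hits = nrow(hits),
       family_summary = fam[order(-fam$n_snps), , drop = FALSE])
}
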