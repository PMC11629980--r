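# Synthetic-data generator: every input the pipeline consumes, with planted
# ground truth, emulating the study design this package targets — 6
# tissues, a 10-state chromatin vocabulary, TPM expression tables, per-CpG
# bisulfite counts, QTL/SNP/motif tables and ohnolog triplets with known
# retention fates. Scales are desk-sized; shapes mirror the real data.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 6 tissues, 10 chromatin
#' states with dwell lengths matching the published per-state mean segment
#' lengths, a 75% methylation background dipping to 10% at the TSS, and a
#' retention-fate mix of 73.6/14.2/0.2/12 percent
#' (conserved/neo/sub/specialized).
#'
#' @param seed Master seed; every sub-generator derives its stream from it.
#' @param n_chroms,chrom_length Genome shape (bp).
#' @param n_genes Number of genes placed without overlap.
#' @param gene_length_range Min/max gene length in bp.
#' @param tissues Tissue names.
#' @param frac_specific Fraction of genes planted tissue-specific.
#' @param state_dwell Named mean segment length (bp) per state for the
#'   track filler.
#' @param state_coverage Named target genome-coverage fraction per state.
#' @param n_cpg Number of CpG sites in the simulated methylome.
#' @param mean_depth Mean Poisson read depth per CpG.
#' @param frac_low_depth Fraction of sites planted below depth 10.
#' @param n_high_depth Number of sites planted as extreme-coverage outliers.
#' @param methylation_background Background methylation level.
#' @param tss_hypomethylation_depth Methylation level at the TSS trough.
#' @param n_triplets,fate_mix,noise_sd,n_singletons Ohnolog-triplet design.
#' @param n_qtl,n_snps,frac_snp_planted,family_mix QTL/SNP/motif design.
#' @param n_se_genes Genes per tissue that receive a planted super-enhancer.
#' @return Validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 3,
                       chrom_length = 2e6,
                       n_genes = 450,
                       gene_length_range = c(1500, 4000),
                       tissues = c("brain", "liver", "spleen",
                                   "muscle", "intestine", "kidney"),
                       frac_specific = 0.08,
                       state_dwell = c(TssA = 1382, TssAFlnk = 1081,
                                       EnhG = 1008, Str.Enh = 1550,
                                       MidEnh = 993, EnhPois = 6295,
                                       `ATAC-CpG` = 1078, BivEnh = 574,
                                       ReprPC = 4762, Quies = 30000),
                       state_coverage = c(TssA = 0.007, TssAFlnk = 0.007,
                                          EnhG = 0.013, Str.Enh = 0.013,
                                          MidEnh = 0.013, EnhPois = 0.072,
                                          `ATAC-CpG` = 0.0725, BivEnh = 0.006,
                                          ReprPC = 0.0257, Quies = 0.771),
                       n_cpg = 20000,
                       mean_depth = 30,
                       frac_low_depth = 0.02,
                       n_high_depth = 15,
                       methylation_background = 0.75,
                       tss_hypomethylation_depth = 0.10,
                       n_triplets = 1000,
                       fate_mix = c(conserved = 0.736,
                                    neofunctionalized = 0.142,
                                    subfunctionalized = 0.002,
                                    specialized = 0.12),
                       noise_sd = 0.02,
                       n_singletons = 300,
                       n_qtl = 12,
                       n_snps = 300,
                       frac_snp_planted = 0.3,
                       family_mix = c(`C/EBP` = 0.7, GR = 0.3),
                       n_se_genes = 25) {
  cfg <- as.list(environment())
  stopifnot(n_chroms > 0, chrom_length > 0, n_genes > 0, n_cpg > 0,
            n_triplets > 0, n_qtl > 0, n_snps > 0,
            length(tissues) >= 2, noise_sd >= 0)
  if (abs(sum(fate_mix) - 1) > 1e-9) stop("fate_mix must sum to 1")
  if (abs(sum(family_mix) - 1) > 1e-9) stop("family_mix must sum to 1")
  if (!all(names(state_dwell) %in% chromatin_states()))
    stop("state_dwell has unknown state names")
  class(cfg) <- "sim_config"
  cfg
}

# derived, stage-local RNG stream
.stream <- function(cfg, offset) set.seed((cfg$seed * 97 + offset) %% 2147483647)

.rdirichlet <- function(n, k, alpha = 1) {
  m <- matrix(stats::rgamma(n * k, alpha), n, k)
  m / rowSums(m)
}

#' Simulate a genome model and non-overlapping gene table
#'
#' Genes are distributed round-robin over chromosomes, each placed at a
#' random offset within its own slot so no two genes overlap; strands are
#' random. Errors when the genes cannot fit.
#'
#' @param config A [sim_config()].
#' @return List: `genome` ([genome_model()]) and `genes` (gene table with
#'   tss/tes).
#' @export
simulate_genome <- function(config) {
  .stream(config, 1)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- genome_model(stats::setNames(
    rep(config$chrom_length, config$n_chroms), chroms))
  per_chrom <- table(factor(rep_len(chroms, config$n_genes), levels = chroms))
  max_len <- config$gene_length_range[2]
  rows <- list()
  gi <- 0
  for (ch in chroms) {
    k <- as.integer(per_chrom[ch])
    if (k == 0) next
    slot <- floor(config$chrom_length / k)
    if (slot <= max_len + 2)
      stop("genes cannot fit: ", k, " genes of up to ", max_len,
           " bp on a ", config$chrom_length, " bp chromosome")
    len <- sample(seq(config$gene_length_range[1], max_len), k, replace = TRUE)
    offset <- floor(stats::runif(k, 0, slot - len - 1))
    start <- (seq_len(k) - 1) * slot + offset
    rows[[ch]] <- data.frame(
      gene_id = sprintf("g%04d", gi + seq_len(k)),
      chrom = ch, start = start, end = start + len,
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE)
    gi <- gi + k
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  list(genome = genome, genes = genes)
}

#' Simulate a TPM expression matrix with planted tissue-specific genes
#'
#' Background expression is log-normal. A planted subset is made
#' tissue-specific by construction under the calling rules themselves
#' (>= 10-fold the sum of all other tissues, or >= 1 TPM with all other
#' tissues zero); every non-planted gene is adjusted so that neither rule
#' fires, making the planted labels the exact ground truth.
#'
#' @param config A [sim_config()].
#' @param genes Gene table from [simulate_genome()].
#' @return Numeric TPM matrix (genes x tissues); planted calls in
#'   `attr(, "truth")` (gene_id, tissue, rule).
#' @export
simulate_expression <- function(config, genes) {
  .stream(config, 2)
  nt <- length(config$tissues)
  ng <- nrow(genes)
  tpm <- matrix(stats::rlnorm(ng * nt, meanlog = 0.5, sdlog = 1.2), ng, nt,
                dimnames = list(genes$gene_id, config$tissues))
  n_spec <- round(config$frac_specific * ng)
  spec_idx <- if (n_spec > 0) sort(sample.int(ng, n_spec)) else integer()
  spec_tissue <- rep_len(seq_len(nt), n_spec)[sample.int(max(n_spec, 1), n_spec)]
  rule <- character(n_spec)
  for (k in seq_along(spec_idx)) {
    i <- spec_idx[k]; j <- spec_tissue[k]
    if (k %% 4 == 0) {           # one_vs_zero plant
      tpm[i, ] <- 0
      tpm[i, j] <- stats::runif(1, 1, 8)
      rule[k] <- "one_vs_zero"
    } else {                     # fold10 plant
      others <- stats::runif(nt - 1, 0.02, 0.3)
      tpm[i, -j] <- others
      tpm[i, j] <- max(1, sum(others) * stats::runif(1, 10, 15))
      rule[k] <- "fold10"
    }
  }
  # de-specify every non-planted gene: raise a second tissue to max/5 when
  # a rule accidentally fires
  other <- setdiff(seq_len(ng), spec_idx)
  for (i in other) {
    v <- tpm[i, ]
    jmax <- which.max(v)
    rest <- sum(v) - v[jmax]
    fires <- (rest > 0 && v[jmax] / rest >= config$fold_cutoff %||% 10) ||
      (rest == 0 && v[jmax] >= 1)
    if (fires) {
      j2 <- if (jmax == 1) 2 else 1
      tpm[i, j2] <- v[jmax] / 5
    }
  }
  truth <- data.frame(gene_id = genes$gene_id[spec_idx],
                      tissue = config$tissues[spec_tissue],
                      rule = rule, stringsAsFactors = FALSE)
  attr(tpm, "truth") <- truth
  tpm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-tissue chromatin-state tracks
#'
#' Per tissue and chromosome a complete, non-overlapping tiling: TssA is
#' planted at the TSS of genes expressed (TPM > 2) in that tissue, flanked
#' by TssAFlnk; Str.Enh is planted upstream of that tissue's planted
#' tissue-specific genes; the remainder is filled by segments drawn with
#' exponential dwell lengths and state probabilities matching the target
#' coverage fractions (Quies fills most of the genome).
#'
#' @param config A [sim_config()].
#' @param genes Gene table.
#' @param tpm TPM matrix from [simulate_expression()].
#' @param genome Genome model.
#' @return Named list tissue -> state track; planted placements in
#'   `attr(, "planted")` (tissue, chrom, start, end, state, gene_id).
#' @export
simulate_state_tracks <- function(config, genes, tpm, genome) {
  truth <- attr(tpm, "truth")
  fill_states <- chromatin_states()
  fill_p <- config$state_coverage[fill_states] /
    config$state_dwell[fill_states]
  fill_p <- fill_p / sum(fill_p)
  tracks <- list()
  planted_all <- list()
  for (ti in seq_along(config$tissues)) {
    tissue <- config$tissues[ti]
    .stream(config, 100 + ti)
    expressed <- genes$gene_id[tpm[genes$gene_id, tissue] > 2]
    specific <- truth$gene_id[truth$tissue == tissue]
    segs <- list(); planted <- list()
    for (ch in names(genome$chrom_sizes)) {
      L <- genome$chrom_sizes[[ch]]
      g <- genes[genes$chrom == ch, , drop = FALSE]
      tssb <- .tss_base(g)
      pl <- list()
      for (r in seq_len(nrow(g))) {
        if (g$gene_id[r] %in% expressed) {
          pl[[length(pl) + 1]] <- data.frame(
            start = c(tssb[r] - 1500, tssb[r] - 500, tssb[r] + 500),
            end = c(tssb[r] - 500, tssb[r] + 500, tssb[r] + 1500),
            state = c("TssAFlnk", "TssA", "TssAFlnk"),
            gene_id = g$gene_id[r], stringsAsFactors = FALSE)
        }
        if (g$gene_id[r] %in% specific) {
          pl[[length(pl) + 1]] <- data.frame(
            start = tssb[r] - 3000, end = tssb[r] - 1500,
            state = "Str.Enh", gene_id = g$gene_id[r],
            stringsAsFactors = FALSE)
        }
      }
      pl <- if (length(pl)) do.call(rbind, pl) else
        data.frame(start = numeric(), end = numeric(), state = character(),
                   gene_id = character())
      pl$start <- pmax(0, pl$start); pl$end <- pmin(L, pl$end)
      pl <- pl[pl$start < pl$end, , drop = FALSE]
      pl <- pl[order(pl$start, pl$end), , drop = FALSE]
      # resolve rare collisions by truncating to the previous kept end
      if (nrow(pl) > 1) {
        keep_end <- pl$end[1]
        for (r in 2:nrow(pl)) {
          if (pl$start[r] < keep_end) pl$start[r] <- keep_end
          keep_end <- max(keep_end, pl$end[r])
        }
        pl <- pl[pl$start < pl$end, , drop = FALSE]
      }
      # fill the gaps with a complete tiling
      bounds <- rbind(c(0, 0), cbind(pl$start, pl$end), c(L, L))
      filled <- list()
      for (r in seq_len(nrow(bounds) - 1)) {
        a <- bounds[r, 2]; b <- bounds[r + 1, 1]
        while (a < b) {
          s <- sample(fill_states, 1, prob = fill_p)
          len <- max(200, round(stats::rexp(1, 1 / config$state_dwell[[s]])))
          if (len > b - a) {
            # the remainder cannot hold a full draw; quiescent chromatin
            # absorbs boundaries so other states keep their dwell lengths
            len <- b - a
            s <- "Quies"
          }
          filled[[length(filled) + 1]] <- c(a, a + len, s)
          a <- a + len
        }
      }
      fdf <- if (length(filled)) {
        m <- do.call(rbind, filled)
        data.frame(start = as.numeric(m[, 1]), end = as.numeric(m[, 2]),
                   state = m[, 3], stringsAsFactors = FALSE)
      } else data.frame(start = numeric(), end = numeric(), state = character())
      seg <- rbind(fdf,
                   pl[, c("start", "end", "state")])
      seg$chrom <- ch
      seg <- seg[order(seg$start, seg$end), c("chrom", "start", "end", "state")]
      segs[[ch]] <- seg
      if (nrow(pl))
        planted[[ch]] <- data.frame(tissue = tissue, chrom = ch,
                                    pl[, c("start", "end", "state", "gene_id")],
                                    stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, segs)
    rownames(tr) <- NULL
    attr(tr, "tissue") <- tissue
    tracks[[tissue]] <- tr
    planted_all[[tissue]] <- if (length(planted)) do.call(rbind, planted) else NULL
  }
  attr(tracks, "planted") <- do.call(rbind, planted_all)
  tracks
}

#' Simulate histone-mark and accessibility peak calls
#'
#' Per tissue: H3K4me3 and H3K27ac peaks at the TSS of expressed genes;
#' H3K4me1 peaks planted only at that tissue's tissue-specific genes;
#' H3K27me3 peaks at genes silenced in that tissue (specific to another
#' tissue); plus uniform background peaks for every mark. The
#' highest-expressed `n_se_genes` genes per tissue receive a planted
#' cluster of high-signal H3K27ac peaks (the super-enhancer ground truth).
#'
#' @param config A [sim_config()].
#' @param genes Gene table.
#' @param tpm TPM matrix.
#' @param genome Genome model.
#' @return Named list tissue -> named list mark -> peak data.frame (with
#'   `signal`). Planted SE regions in `attr(, "se_truth")`.
#' @export
simulate_peaks <- function(config, genes, tpm, genome) {
  truth <- attr(tpm, "truth")
  out <- list(); se_truth <- list()
  for (ti in seq_along(config$tissues)) {
    tissue <- config$tissues[ti]
    .stream(config, 200 + ti)
    v <- tpm[genes$gene_id, tissue]
    expressed <- which(v > 2)
    specific <- which(genes$gene_id %in% truth$gene_id[truth$tissue == tissue])
    # repressive marks are planted in one designated silencing tissue per
    # specific gene (the cyclic successor of its specific tissue): a mark
    # present in every silencing tissue would never be tissue-unique
    succ <- config$tissues[match(truth$tissue, config$tissues) %%
                             length(config$tissues) + 1]
    silenced <- which(genes$gene_id %in% truth$gene_id[succ == tissue])
    tssb <- .tss_base(genes)
    mk_peaks <- function(idx, off_lo, off_hi, sig_mean) {
      if (!length(idx)) return(NULL)
      data.frame(chrom = genes$chrom[idx],
                 start = pmax(0, tssb[idx] + off_lo),
                 end = tssb[idx] + off_hi,
                 signal = stats::rlnorm(length(idx), log(sig_mean), 0.3),
                 stringsAsFactors = FALSE)
    }
    bg_peaks <- function(n, width, sig_mean) {
      ch <- sample(names(genome$chrom_sizes), n, replace = TRUE)
      st <- floor(stats::runif(n, 0, genome$chrom_sizes[ch] - width))
      data.frame(chrom = ch, start = st, end = st + width,
                 signal = stats::rlnorm(n, log(sig_mean), 0.3),
                 stringsAsFactors = FALSE)
    }
    # planted SE clusters at the top-expressed genes: 4 escalating-signal
    # peaks spanning ~9.3 kb upstream (stitch joins them; conventional
    # background enhancers stay far below)
    se_idx <- expressed[order(v[expressed], decreasing = TRUE)]
    se_idx <- se_idx[seq_len(min(config$n_se_genes, length(se_idx)))]
    se_peaks <- NULL
    if (length(se_idx)) {
      base_sig <- 150 * 1.6^(seq_along(se_idx) - 1)
      se_peaks <- do.call(rbind, lapply(seq_along(se_idx), function(k) {
        i <- se_idx[k]
        st <- pmax(0, tssb[i] - 10000 + c(0, 3000, 6000, 9000))
        data.frame(chrom = genes$chrom[i], start = st, end = st + 700,
                   signal = base_sig[k] * stats::runif(4, 0.8, 1.2) / 4,
                   stringsAsFactors = FALSE)
      }))
      se_truth[[tissue]] <- data.frame(
        tissue = tissue, chrom = genes$chrom[se_idx],
        start = pmax(0, tssb[se_idx] - 10000),
        end = pmax(0, tssb[se_idx] - 10000 + 9000) + 700,
        gene_id = genes$gene_id[se_idx], stringsAsFactors = FALSE)
    }
    marks <- list(
      H3K4me3 = rbind(mk_peaks(expressed, -700, 100, 8), bg_peaks(80, 700, 2)),
      H3K27ac = rbind(mk_peaks(expressed, -800, -200, 6), se_peaks,
                      bg_peaks(80, 600, 2)),
      H3K4me1 = rbind(mk_peaks(specific, -1200, -200, 6), bg_peaks(60, 450, 2)),
      H3K27me3 = rbind(mk_peaks(silenced, -900, 100, 5), bg_peaks(80, 580, 2)),
      ATAC = rbind(mk_peaks(expressed, -300, 300, 10), bg_peaks(120, 690, 2)))
    out[[tissue]] <- lapply(marks, function(p) {
      p <- p[order(p$chrom, p$start, p$end), , drop = FALSE]
      rownames(p) <- NULL
      p
    })
  }
  attr(out, "se_truth") <- do.call(rbind, c(se_truth, make.row.names = FALSE))
  out
}

#' Simulate a per-CpG bisulfite count table
#'
#' True methylation is `methylation_background` genome-wide, with a
#' Gaussian-shouldered trough centred 50 bp downstream of each TSS
#' (sigma 300 bp) reaching `tss_hypomethylation_depth`, and a ceiling of
#' 0.5 inside active chromatin states (1-5). Depths are Poisson
#' (`mean_depth`), with a planted fraction below depth 10 and a few
#' extreme-coverage outliers to exercise the filters; counts are binomial.
#'
#' @param config A [sim_config()].
#' @param genes Gene table.
#' @param genome Genome model.
#' @param track Optional state track supplying the active-state ceiling.
#' @return data.frame chrom, pos, strand, reads_c, reads_t; true levels and
#'   outlier flags in `attr(, "truth")`.
#' @export
simulate_methylome <- function(config, genes, genome, track = NULL) {
  .stream(config, 20)
  chroms <- names(genome$chrom_sizes)
  n_per <- table(factor(sample(chroms, config$n_cpg, replace = TRUE,
                               prob = genome$chrom_sizes / genome$D),
                        levels = chroms))
  sites <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(genome$chrom_sizes[[ch]], n_per[[ch]])) - 1
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  # distance to the nearest TSS trough centre (TSS base + 50)
  bg <- config$methylation_background
  dip <- config$tss_hypomethylation_depth
  # trough centre sits 50 bp downstream of the TSS in gene orientation
  centre_by_chrom <- split(.tss_base(genes) +
                             ifelse(genes$strand == "+", 50, -50),
                           genes$chrom)
  d <- rep(Inf, nrow(sites))
  for (ch in unique(sites$chrom)) {
    cts <- sort(centre_by_chrom[[ch]])
    if (is.null(cts) || !length(cts)) next
    i <- which(sites$chrom == ch)
    p <- sites$pos[i]
    k <- findInterval(p, cts)
    lo <- ifelse(k >= 1, abs(p - cts[pmax(k, 1)]), Inf)
    hi <- ifelse(k < length(cts), abs(cts[pmin(k + 1, length(cts))] - p), Inf)
    d[i] <- pmin(lo, hi)
  }
  level <- bg - (bg - dip) * exp(-(d / 300)^2)
  if (!is.null(track)) {
    act <- track[track$state %in% active_states(), , drop = FALSE]
    sp <- data.frame(chrom = sites$chrom, start = sites$pos,
                     end = sites$pos + 1)
    ov <- find_overlaps(sp, act)
    in_active <- rep(FALSE, nrow(sites))
    in_active[unique(ov$query_idx)] <- TRUE
    level <- ifelse(in_active, pmin(level, 0.5), level)
  }
  n <- nrow(sites)
  depth <- stats::rpois(n, config$mean_depth)
  depth[depth == 0] <- 1
  low_idx <- sample.int(n, round(config$frac_low_depth * n))
  depth[low_idx] <- sample(0:9, length(low_idx), replace = TRUE)
  high_idx <- sample(setdiff(seq_len(n), low_idx), config$n_high_depth)
  depth[high_idx] <- round(config$mean_depth * 50 * stats::runif(
    length(high_idx), 1, 2))
  reads_c <- stats::rbinom(n, depth, level)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, strand = "+",
                    reads_c = reads_c, reads_t = depth - reads_c,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(
    true_level = level, tss_distance = d,
    low_depth = seq_len(n) %in% low_idx,
    high_outlier = seq_len(n) %in% high_idx)
  out
}

# add simplex noise to a relative profile: i.i.d. Gaussian, clip at 0,
# renormalize
.noisy_profile <- function(p, sd) {
  if (sd == 0) return(p)
  q <- pmax(0, p + stats::rnorm(length(p), 0, sd))
  if (sum(q) == 0) q <- p
  q / sum(q)
}

# random relative profile at least `margin` from `ref`
.redraw_profile <- function(ref, margin) {
  repeat {
    q <- as.numeric(.rdirichlet(1, length(ref)))
    if (profile_distance(q, ref) > margin) return(q)
  }
}

#' Simulate ohnolog triplets with planted retention fates
#'
#' For each triplet an ancestral relative profile is drawn on the simplex
#' and the duplicates are generated per the assigned fate: conserved
#' copies track the ancestor; neofunctionalized redraws one copy (>= 0.35
#' from the ancestor); subfunctionalized partitions the ancestor's
#' expression between the copies (combined profile = ancestor);
#' specialized redraws both so that copies and combination all diverge.
#' Simplex noise (`noise_sd`) is added to every profile. Singleton pairs
#' (ancestor + noise on both sides) provide the divergence baseline.
#'
#' @param config A [sim_config()].
#' @return List: `d1`, `d2`, `anc` (absolute TPM matrices,
#'   triplets x tissues), `fates` (planted labels, directional for neo),
#'   `s1`, `s2` (singleton matrices).
#' @export
simulate_triplets <- function(config) {
  .stream(config, 30)
  nt <- length(config$tissues)
  if (nt < 2) stop("need at least 2 tissues for expression profiles")
  n <- config$n_triplets
  counts <- diff(round(c(0, cumsum(config$fate_mix)) * n))
  fates_base <- rep(names(config$fate_mix), counts)
  margin <- 0.35
  d1 <- matrix(0, n, nt); d2 <- matrix(0, n, nt); anc <- matrix(0, n, nt)
  fates <- character(n)
  sdn <- config$noise_sd
  # expression scale factors are powers of two: scaling and unscaling by
  # 2^k are exact in floating point, so at zero noise relative profiles
  # are recovered bitwise and planted distances are exactly zero
  rscale <- function() 2^round(stats::rnorm(1, 4, 1))
  for (i in seq_len(n)) {
    a <- as.numeric(.rdirichlet(1, nt))
    t_anc <- rscale()
    t1 <- rscale(); t2 <- rscale()
    f <- fates_base[i]
    if (f == "conserved") {
      d1[i, ] <- t1 * .noisy_profile(a, sdn)
      d2[i, ] <- t2 * .noisy_profile(a, sdn)
      fates[i] <- "conserved"
    } else if (f == "neofunctionalized") {
      nv <- .redraw_profile(a, margin)
      if (i %% 2 == 0) {
        d1[i, ] <- t1 * .noisy_profile(nv, sdn)
        d2[i, ] <- t2 * .noisy_profile(a, sdn)
        fates[i] <- "neofunctionalized_D1"
      } else {
        d1[i, ] <- t1 * .noisy_profile(a, sdn)
        d2[i, ] <- t2 * .noisy_profile(nv, sdn)
        fates[i] <- "neofunctionalized_D2"
      }
    } else if (f == "subfunctionalized") {
      # a near-degenerate ancestor admits no balanced partition (one half
      # always stays within the margin); redraw the ancestor in that case
      repeat {
        ok <- FALSE
        for (try in 1:20) {
          mask <- stats::runif(nt) < 0.5
          if (!any(mask) || all(mask)) next
          q1 <- a * mask; q2 <- a * (1 - mask)
          if (sum(q1) == 0 || sum(q2) == 0) next
          if (profile_distance(q1 / sum(q1), a) > margin &&
              profile_distance(q2 / sum(q2), a) > margin) { ok <- TRUE; break }
        }
        if (ok) break
        a <- as.numeric(.rdirichlet(1, nt))
      }
      if (sdn == 0) {
        # split the ancestor's absolute expression exactly: the combined
        # profile reproduces the ancestor bitwise
        d1[i, ] <- t_anc * q1
        d2[i, ] <- t_anc * q2
      } else {
        d1[i, ] <- (t_anc * sum(q1)) * .noisy_profile(q1 / sum(q1), sdn)
        d2[i, ] <- (t_anc * sum(q2)) * .noisy_profile(q2 / sum(q2), sdn)
      }
      fates[i] <- "subfunctionalized"
    } else {
      repeat {
        q1 <- .redraw_profile(a, margin)
        q2 <- .redraw_profile(a, margin)
        comb <- (t1 * q1 + t2 * q2) / (t1 + t2)
        if (profile_distance(comb / sum(comb), a) > margin) break
      }
      d1[i, ] <- t1 * .noisy_profile(q1, sdn)
      d2[i, ] <- t2 * .noisy_profile(q2, sdn)
      fates[i] <- "specialized"
    }
    anc[i, ] <- t_anc * a
  }
  colnames(d1) <- colnames(d2) <- colnames(anc) <- config$tissues
  rownames(d1) <- rownames(d2) <- sprintf("trip%04d", seq_len(n))
  rownames(anc) <- rownames(d1)
  m <- config$n_singletons
  s1 <- matrix(0, m, nt); s2 <- matrix(0, m, nt)
  for (i in seq_len(m)) {
    a <- as.numeric(.rdirichlet(1, nt))
    s1[i, ] <- rscale() * .noisy_profile(a, sdn)
    s2[i, ] <- rscale() * .noisy_profile(a, sdn)
  }
  colnames(s1) <- colnames(s2) <- config$tissues
  list(d1 = d1, d2 = d2, anc = anc, fates = fates, s1 = s1, s2 = s2)
}

#' Simulate QTL intervals, SNPs and TF-binding motifs
#'
#' A planted fraction of SNPs is placed inside enhancer-state segments that
#' overlap a QTL, each covered by its own motif with a family drawn from
#' `family_mix` (exact counts). The remaining SNPs are negative controls:
#' outside all QTL, inside a QTL but in a non-enhancer state, or inside a
#' QTL enhancer without any motif. Decoy motifs are placed outside QTL.
#'
#' @param config A [sim_config()].
#' @param track State track used to find enhancer segments.
#' @param genome Genome model.
#' @return List: `qtl` (with `label` = trait), `snps` (snp_id, chrom, pos
#'   1-based), `motifs` (with `label` and `tf_family`), and `truth`
#'   (planted snp_id + tf_family).
#' @export
simulate_qtl_snps <- function(config, track, genome) {
  .stream(config, 40)
  chroms <- names(genome$chrom_sizes)
  traits <- c("growth", "fillet quality", "BCWD")
  qlen <- stats::runif(config$n_qtl, 1e5, 3e5)
  qch <- sample(chroms, config$n_qtl, replace = TRUE)
  qst <- floor(stats::runif(config$n_qtl, 0, genome$chrom_sizes[qch] - qlen))
  qtl <- data.frame(chrom = qch, start = qst, end = qst + floor(qlen),
                    label = rep_len(traits, config$n_qtl),
                    stringsAsFactors = FALSE)
  enh <- track[track$state %in% qtl_enhancer_states(), , drop = FALSE]
  ov <- find_overlaps(enh, qtl)
  if (!nrow(ov)) stop("no enhancer segments overlap the QTL; enlarge n_qtl")
  n_planted <- round(config$frac_snp_planted * config$n_snps)
  fam_counts <- diff(round(c(0, cumsum(config$family_mix)) * n_planted))
  fams <- rep(names(config$family_mix), fam_counts)
  planted_pos <- data.frame(chrom = character(), pos = numeric())
  guard <- 0
  while (nrow(planted_pos) < n_planted && guard < 50 * n_planted) {
    guard <- guard + 1
    k <- sample.int(nrow(ov), 1)
    e <- enh[ov$query_idx[k], ]; q <- qtl[ov$subject_idx[k], ]
    lo <- max(e$start, q$start); hi <- min(e$end, q$end)
    if (hi - lo < 1) next
    pos <- floor(stats::runif(1, lo, hi))
    near <- planted_pos$chrom == e$chrom & abs(planted_pos$pos - pos) < 50
    if (any(near)) next
    planted_pos <- rbind(planted_pos,
                         data.frame(chrom = e$chrom, pos = pos,
                                    stringsAsFactors = FALSE))
  }
  n_planted <- nrow(planted_pos)
  fams <- fams[seq_len(n_planted)]
  motifs <- data.frame(chrom = planted_pos$chrom,
                       start = planted_pos$pos - 5,
                       end = planted_pos$pos + 7,
                       label = sprintf("motif%03d", seq_len(n_planted)),
                       tf_family = fams, stringsAsFactors = FALSE)
  # negative SNPs: outside QTL (decoy motifs may cover these), or inside a
  # QTL but not in an enhancer state, or in a QTL enhancer with no motif
  n_neg <- config$n_snps - n_planted
  neg <- data.frame(chrom = character(), pos = numeric())
  kinds <- rep_len(c("no_qtl", "no_enh", "no_motif"), n_neg)
  in_any <- function(chrom, pos, iv) {
    any(iv$chrom == chrom & iv$start <= pos & pos < iv$end)
  }
  guard <- 0
  while (nrow(neg) < n_neg && guard < 200 * n_neg) {
    guard <- guard + 1
    kind <- kinds[nrow(neg) + 1]
    if (kind == "no_qtl") {
      ch <- sample(chroms, 1)
      pos <- floor(stats::runif(1, 0, genome$chrom_sizes[[ch]]))
      if (in_any(ch, pos, qtl)) next
    } else if (kind == "no_enh") {
      q <- qtl[sample.int(nrow(qtl), 1), ]
      ch <- q$chrom
      pos <- floor(stats::runif(1, q$start, q$end))
      if (in_any(ch, pos, enh)) next
    } else {
      k <- sample.int(nrow(ov), 1)
      e <- enh[ov$query_idx[k], ]; q <- qtl[ov$subject_idx[k], ]
      lo <- max(e$start, q$start); hi <- min(e$end, q$end)
      if (hi - lo < 1) next
      ch <- e$chrom
      pos <- floor(stats::runif(1, lo, hi))
      if (in_any(ch, pos, motifs)) next
    }
    if (any(neg$chrom == ch & neg$pos == pos) ||
        any(planted_pos$chrom == ch & abs(planted_pos$pos - pos) < 10)) next
    neg <- rbind(neg, data.frame(chrom = ch, pos = pos,
                                 stringsAsFactors = FALSE))
  }
  # decoy motifs well away from any QTL
  decoys <- list(); guard <- 0
  while (length(decoys) < 40 && guard < 5000) {
    guard <- guard + 1
    ch <- sample(chroms, 1)
    pos <- floor(stats::runif(1, 0, genome$chrom_sizes[[ch]] - 12))
    if (in_any(ch, pos, qtl) || in_any(ch, pos + 11, qtl)) next
    decoys[[length(decoys) + 1]] <- data.frame(
      chrom = ch, start = pos, end = pos + 12,
      tf_family = sample(c(names(config$family_mix), "other"), 1),
      stringsAsFactors = FALSE)
  }
  dec <- do.call(rbind, decoys)
  dec$label <- sprintf("decoy%03d", seq_len(nrow(dec)))
  motifs <- rbind(motifs, dec[, names(motifs)])
  all_pos <- rbind(planted_pos, neg)
  snps <- data.frame(snp_id = sprintf("snp%04d", seq_len(nrow(all_pos))),
                     chrom = all_pos$chrom, pos = all_pos$pos + 1,
                     stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = snps$snp_id[seq_len(n_planted)],
                      tf_family = fams, stringsAsFactors = FALSE)
  list(qtl = qtl, snps = snps, motifs = motifs, truth = truth)
}

#' Simulate a ranked-enhancer signal set with a planted heavy tail
#'
#' `n_low` conventional clusters with uniform low signal plus `n_high`
#' planted super-enhancer clusters with geometrically escalating signal,
#' laid out disjointly on one chromosome. The planted flags are the ground
#' truth for the tangent-slope caller.
#'
#' @param n_low,n_high Cluster counts (defaults 95 and 5).
#' @param seed RNG seed.
#' @return data.frame chrom, start, end, signal, planted_super.
#' @export
simulate_se_signals <- function(n_low = 95, n_high = 5, seed = 1) {
  set.seed(seed)
  n <- n_low + n_high
  sig <- c(stats::runif(n_low, 5, 20), 200 * 2^(seq_len(n_high) - 1))
  start <- seq(0, by = 50000, length.out = n)
  data.frame(chrom = "chr1", start = start, end = start + 20000,
             signal = sig, planted_super = rep(c(FALSE, TRUE),
                                               c(n_low, n_high)),
             stringsAsFactors = FALSE)
}

#' Simulate promoter epigenetic profiles for duplicate pairs
#'
#' Pairs in each fate category share a latent promoter profile with a
#' category-specific correlation (conserved 0.9, specialized 0.5,
#' neofunctionalized 0.1 by default), emulating the planted ordering of
#' histone-profile similarity across retention fates.
#'
#' @param n_per_category Pairs per category.
#' @param n_dims Profile length (bins x marks).
#' @param rho Named correlations per category.
#' @param seed RNG seed.
#' @return List: `a`, `b` (matrices pairs x dims), `fate`.
#' @export
simulate_pair_epiprofiles <- function(n_per_category = 500, n_dims = 30,
                                      rho = c(conserved = 0.9,
                                              specialized = 0.5,
                                              neofunctionalized = 0.1),
                                      seed = 1) {
  set.seed(seed)
  n <- n_per_category * length(rho)
  a <- matrix(stats::rnorm(n * n_dims), n, n_dims)
  e <- matrix(stats::rnorm(n * n_dims), n, n_dims)
  fate <- rep(names(rho), each = n_per_category)
  r <- rho[fate]
  b <- a * r + e * sqrt(1 - r^2)
  list(a = a, b = b, fate = fate)
}
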