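# End-to-end orchestration: simulate all inputs, write them in their
# exchange formats, run every analysis stage in dependency order, and
# write deterministic outputs plus a manifest with parameter values and
# output checksums.

#' Write a full synthetic dataset to disk
#'
#' Emits every input the pipeline consumes in its exchange dialect
#' (chrom.sizes TSV, gene table TSV with TPM columns, per-tissue BED4
#' state tracks, per-tissue/mark BED peaks with signal, CpG TSV, QTL BED,
#' motif TSV, SNP TSV, triplet expression TSVs) plus the planted
#' ground-truth tables.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, the list of simulated objects.
#' @export
write_synthetic_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_all(config)
  p <- function(...) file.path(outdir, ...)
  write_chrom_sizes(sim$genome, p("genome.chrom.sizes"))
  write_gene_table(sim$genes, p("genes.tsv"), tpm = sim$tpm)
  for (t in config$tissues) {
    write_state_track(sim$tracks[[t]], p(paste0("states_", t, ".bed")))
    for (m in names(sim$peaks[[t]])) {
      pk <- sim$peaks[[t]][[m]]
      pk$label <- "."
      pk$score <- pk$signal
      write_bed(pk[, c("chrom", "start", "end", "label", "score")],
                p(paste0("peaks_", t, "_", m, ".bed")))
    }
  }
  utils::write.table(sim$methylome, p("cpg.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(sim$qtl$qtl, p("qtl.bed"))
  utils::write.table(sim$qtl$motifs, p("motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$qtl$snps, p("snps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in c("d1", "d2", "anc", "s1", "s2"))
    utils::write.table(sim$triplets[[nm]], p(paste0("expr_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = TRUE)
  utils::write.table(data.frame(triplet_id = rownames(sim$triplets$d1),
                                fate = sim$triplets$fates),
                     p("truth_fates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(attr(sim$tpm, "truth"), p("truth_specific.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$qtl$truth, p("truth_snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sim)
}

#' Run every simulator stage
#'
#' @param config A [sim_config()].
#' @return List with genome, genes, tpm, tracks, peaks, methylome,
#'   triplets, qtl.
#' @export
simulate_all <- function(config) {
  g <- simulate_genome(config)
  tpm <- simulate_expression(config, g$genes)
  tracks <- simulate_state_tracks(config, g$genes, tpm, g$genome)
  peaks <- simulate_peaks(config, g$genes, tpm, g$genome)
  methylome <- simulate_methylome(config, g$genes, g$genome,
                                  track = tracks[[1]])
  triplets <- simulate_triplets(config)
  qtl <- simulate_qtl_snps(config, tracks[[1]], g$genome)
  list(genome = g$genome, genes = g$genes, tpm = tpm, tracks = tracks,
       peaks = peaks, methylome = methylome, triplets = triplets, qtl = qtl)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a configuration
#'
#' Simulates (or, with `config$seed` fixed, re-simulates byte-identically)
#' all inputs and runs every stage in dependency order: state enrichment
#' and summary, tissue-specificity calling and the mark contrast,
#' super-enhancer detection with cross-tissue merging and gene assignment,
#' methylation filtering and profiles, QTL-enhancer-motif intersection,
#' triplet fate classification, and promoter epigenetic divergence. Stage
#' outputs are TSVs under `outdir`; `manifest.json` records the seed,
#' parameters and md5 checksums of every output.
#'
#' @param config A [sim_config()], or a path to a YAML file of
#'   [sim_config()] arguments.
#' @param outdir Run directory (created).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = sim_config(), outdir, quiet = FALSE) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    known <- names(formals(sim_config))
    bad <- setdiff(names(args), known)
    if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
    config <- do.call(sim_config, args)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[troutEpi] ", ...)
  p <- function(...) file.path(outdir, ...)
  out_files <- character()
  keep <- function(path) { out_files <<- c(out_files, path); path }

  say("simulate: generating inputs (seed ", config$seed, ")")
  sim <- write_synthetic_dataset(config, p("inputs"))
  t1 <- config$tissues[1]
  track1 <- sim$tracks[[t1]]

  say("enrich: state summaries and fold enrichment")
  keep(.write_tsv(state_summary(track1, sim$genome), p("state_summary.tsv")))
  gene_iv <- sim$genes[, c("chrom", "start", "end")]
  tssw <- flank_tss(sim$genes, 2000, 2000, sim$genome)
  enr <- rbind(
    cbind(element = "gene_body",
          fold_enrichment(track1, gene_iv, sim$genome)),
    cbind(element = "tss_2kb",
          fold_enrichment(track1, tssw[, c("chrom", "start", "end")],
                          sim$genome)),
    cbind(element = "qtl", fold_enrichment(track1, sim$qtl$qtl, sim$genome)))
  keep(.write_tsv(enr, p("fold_enrichment.tsv")))

  say("specificity: tissue-specific calls and mark contrast")
  calls <- call_tissue_specific(sim$tpm)
  keep(.write_tsv(calls, p("specific_calls.tsv")))
  um <- unique_marks_near_specific_genes(calls, sim$peaks, sim$genes)
  keep(.write_tsv(um, p("unique_marks.tsv")))
  dve <- density_vs_expression(sim$peaks[[t1]]$H3K4me3, sim$genes,
                               sim$tpm[, t1])
  keep(.write_tsv(dve$bins, p("density_vs_expression.tsv")))

  say("se: super-enhancer calling, merging, gene assignment")
  se_by_tissue <- lapply(config$tissues, function(t) {
    cl <- stitch(sim$peaks[[t]]$H3K27ac)
    called <- call_superenhancers(cl)
    called[called$is_super, c("chrom", "start", "end", "signal")]
  })
  names(se_by_tissue) <- config$tissues
  for (t in config$tissues)
    keep(.write_tsv(se_by_tissue[[t]], p(paste0("se_", t, ".tsv"))))
  mg <- merge_across_tissues(se_by_tissue)
  keep(.write_tsv(mg$merged, p("se_nonredundant.tsv")))
  asg <- assign_genes(mg$merged, sim$genes, sim$tpm[, t1])
  keep(.write_tsv(asg$summary, p("se_gene_summary.tsv")))

  say("methylation: filters and profiles")
  filt <- filter_sites(sim$methylome)
  prof <- tss_methylation_profile(filt, sim$genes)
  keep(.write_tsv(prof, p("methylation_tss_profile.tsv")))
  sprof <- state_methylation_profile(filt, track1,
                                     states = intersect(active_states(),
                                                        unique(track1$state)))
  keep(.write_tsv(sprof, p("methylation_state_profile.tsv")))
  assoc <- methylation_expression_association(filt, sim$genes, sim$tpm[, t1])
  keep(.write_tsv(data.frame(r = assoc$r, r_squared = assoc$r_squared,
                             p_value = assoc$p_value),
                  p("methylation_expression.tsv")))

  say("qtl: enhancer overlap and SNP intersection")
  qo <- qtl_enhancer_overlap(track1, sim$qtl$qtl)
  keep(.write_tsv(qo$summary, p("qtl_enhancer_overlap.tsv")))
  obs <- table(qo$pairs$chrom)
  pcf <- per_chromosome_fold(stats::setNames(as.numeric(obs), names(obs)),
                             sim$genome)
  keep(.write_tsv(pcf, p("qtl_per_chromosome_fold.tsv")))
  ix <- intersect_snp_qtl_enhancer_motif(sim$qtl$snps, sim$qtl$qtl, track1,
                                         sim$qtl$motifs)
  keep(.write_tsv(ix$hits, p("snp_hits.tsv")))
  keep(.write_tsv(ix$family_summary, p("snp_family_summary.tsv")))

  say("fate: triplet classification")
  tr <- sim$triplets
  bl <- baseline_cutoff(singleton_distances(tr$s1, tr$s2))
  cls <- classify_triplets(tr$d1, tr$d2, tr$anc, bl$cutoff,
                           ids = rownames(tr$d1))
  keep(.write_tsv(cls, p("fate_triplets.tsv")))
  keep(.write_tsv(fate_proportions(cls$fate), p("fate_proportions.tsv")))

  say("epidiv: promoter divergence by fate")
  ep <- simulate_pair_epiprofiles(n_per_category = 200,
                                  seed = config$seed + 7)
  r <- vapply(seq_len(nrow(ep$a)), function(i)
    pair_correlation(ep$a[i, ], ep$b[i, ])$r, numeric(1))
  wt <- wilcoxon_category_compare(r[ep$fate == "conserved"],
                                  r[ep$fate == "neofunctionalized"])
  agg <- data.frame(fate = unique(ep$fate),
                    mean_r = as.numeric(tapply(r, ep$fate, mean)[unique(ep$fate)]),
                    stringsAsFactors = FALSE)
  agg$wilcoxon_p_cons_vs_neo <- wt$p_value
  keep(.write_tsv(agg, p("epidivergence_by_fate.tsv")))

  say("manifest")
  md5 <- tools::md5sum(sort(out_files))
  names(md5) <- basename(names(md5))
  manifest <- list(
    package = "troutEpi",
    version = as.character(utils::packageVersion("troutEpi")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "seed")],
    outputs = as.list(md5))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(config = config, sim = sim, calls = calls,
                 se = se_by_tissue, merged = mg, fate = cls,
                 baseline = bl, snp = ix, manifest = manifest))
}
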