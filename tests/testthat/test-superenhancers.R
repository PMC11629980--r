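peaks_df <- function(start, end, signal, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, signal = signal,
             stringsAsFactors = FALSE)
}

test_that("stitching clusters peaks within the 12.5-kb edge gap", {
  p <- peaks_df(c(100, 10000), c(200, 10100), c(1, 2))
  s <- stitch(p)  # edge gap 9,800 <= 12,500
  expect_equal(nrow(s), 1)
  expect_equal(c(s$start, s$end), c(100, 10100))
  expect_equal(s$signal, 3)

  far <- stitch(peaks_df(c(0, 21000), c(500, 21500), c(1, 2)))
  expect_equal(nrow(far), 2)

  single <- stitch(peaks_df(5, 105, 7))
  expect_equal(single[, c("start", "end", "signal")],
               data.frame(start = 5, end = 105, signal = 7))

  expect_error(stitch(peaks_df(0, 10, -1)), "negative")
})

test_that("stitching is idempotent and respects chromosomes", {
  set.seed(12)
  p <- do.call(rbind, lapply(c("chr1", "chr2"), function(ch)
    peaks_df(sort(sample.int(5e5, 40)), NA, runif(40, 1, 5), ch)))
  p$end <- p$start + 500
  s1 <- stitch(p)
  s2 <- stitch(s1[, c("chrom", "start", "end", "signal")])
  expect_equal(s1[, c("chrom", "start", "end", "signal")],
               s2[, c("chrom", "start", "end", "signal")])
  expect_false(any(tapply(s1$start, s1$chrom, function(x) is.unsorted(x))))
})

test_that("tangent-slope calling flags the high-signal tail only", {
  cl <- peaks_df(seq(0, 8e5, by = 2e5), seq(0, 8e5, by = 2e5) + 1000,
                 c(1, 1, 1, 1, 100))
  r <- call_superenhancers(cl)
  expect_equal(sum(r$is_super), 1)
  expect_equal(r$signal[r$is_super], 100)

  # perfectly linear curve: slope 1 everywhere, nothing exceeds it
  lin <- peaks_df(seq(0, 9e5, by = 1e5), seq(0, 9e5, by = 1e5) + 1000, 1:10)
  expect_equal(sum(call_superenhancers(lin)$is_super), 0)

  flat <- peaks_df(c(0, 2e5, 4e5), c(1000, 2e5 + 1000, 4e5 + 1000),
                   c(5, 5, 5))
  expect_warning(rf <- call_superenhancers(flat), "equal")
  expect_equal(sum(rf$is_super), 0)

  expect_error(call_superenhancers(flat[1:2, ]), "at least 3")
})

test_that("SE count is monotone non-increasing in the slope cutoff", {
  set.seed(44)
  sig <- c(runif(80, 1, 30), rlnorm(20, 5, 1))
  cl <- peaks_df(seq(0, by = 5e4, length.out = 100),
                 seq(0, by = 5e4, length.out = 100) + 1000, sig)
  counts <- vapply(seq(0.5, 2, by = 0.1), function(ct)
    sum(call_superenhancers(cl, slope_cutoff = ct)$is_super), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted heavy-tail clusters are recovered exactly at zero noise", {
  hs <- simulate_se_signals(n_low = 95, n_high = 5, seed = 8)
  r <- call_superenhancers(hs[, c("chrom", "start", "end", "signal")])
  called <- sort(r$signal[r$is_super])
  planted <- sort(hs$signal[hs$planted_super])
  expect_equal(called, planted)  # precision = recall = 1
})

test_that("uniform signals rarely produce a large SE set", {
  flagged <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    n <- 100
    cl <- peaks_df(seq(0, by = 5e4, length.out = n),
                   seq(0, by = 5e4, length.out = n) + 1000, runif(n, 1, 100))
    mean(call_superenhancers(cl)$is_super)
  }, numeric(1))
  expect_gte(mean(flagged < 0.25), 0.95)
})

test_that("cross-tissue merging follows the 50%-of-shorter rule", {
  iv <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  # identical SE in two tissues -> one nonredundant SE shared by both
  m <- merge_across_tissues(list(brain = iv(100, 1100), liver = iv(100, 1100)))
  expect_equal(nrow(m$merged), 1)
  expect_equal(m$merged$n_tissues, 2)
  expect_true(all(m$sharing[1, ]))

  # 40% reciprocal overlap stays separate
  m2 <- merge_across_tissues(list(a = iv(0, 1000), b = iv(600, 1600)))
  expect_equal(nrow(m2$merged), 2)

  # single linkage: A~B (60%), B~C (60%), A and C disjoint -> one SE
  m3 <- merge_across_tissues(list(a = iv(0, 1000), b = iv(400, 1400),
                                  c = iv(800, 1800)))
  expect_equal(nrow(m3$merged), 1)
  expect_equal(m3$merged$start, 0)
  expect_equal(m3$merged$end, 1800)

  # the reciprocal flag tightens the rule
  m4 <- merge_across_tissues(list(a = iv(0, 10000), b = iv(0, 1000)),
                             reciprocal = TRUE)
  expect_equal(nrow(m4$merged), 2)
  m5 <- merge_across_tissues(list(a = iv(0, 10000), b = iv(0, 1000)))
  expect_equal(nrow(m5$merged), 1)
})

test_that("SEs are assigned to genes within 10 kb and classed by TPM", {
  genes <- toy_genes()  # gA [10000,15000) +, gB [40000,46000) -
  tpm <- c(gA = 5, gB = 0.1)
  ses <- data.frame(chrom = "chr1", start = c(20000, 70000),
                    end = c(21000, 71000))
  r <- assign_genes(ses, genes, tpm)
  # SE1 is 5 kb from gA's end -> assigned, expressed; SE2 is >> 10 kb away
  expect_equal(r$assignments$gene_id, "gA")
  expect_equal(r$assignments$class, "expressed")
  expect_equal(r$summary$n_assigned_se, 1)
  near_b <- assign_genes(data.frame(chrom = "chr1", start = 47000,
                                    end = 48000), genes, tpm)
  expect_equal(near_b$assignments$class, "repressed")
})

test_that("pipeline-simulated SE signal separates planted from background", {
  cfg <- sim_config(seed = 6, n_chroms = 2, chrom_length = 1e6,
                    n_genes = 80, n_se_genes = 8)
  g <- simulate_genome(cfg)
  tpm <- simulate_expression(cfg, g$genes)
  peaks <- simulate_peaks(cfg, g$genes, tpm, g$genome)
  truth <- attr(peaks, "se_truth")
  t1 <- names(peaks)[1]
  called <- call_superenhancers(stitch(peaks[[t1]]$H3K27ac))
  se <- called[called$is_super, c("chrom", "start", "end")]
  tt <- truth[truth$tissue == t1, c("chrom", "start", "end")]
  # every called SE overlaps a planted SE region
  expect_true(all(find_overlaps(se, tt)$query_idx %in% seq_len(nrow(se))))
  expect_gt(nrow(se), 0)
  expect_equal(length(unique(find_overlaps(se, tt)$query_idx)), nrow(se))
})
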