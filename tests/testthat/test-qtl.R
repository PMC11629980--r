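test_that("enhancer-QTL overlap counts pairs and summarizes lengths", {
  track <- data.frame(chrom = "chr1",
                      start = c(1000, 50000, 90000),
                      end = c(2000, 51000, 91000),
                      state = "Str.Enh")
  qtl <- data.frame(chrom = "chr1", start = 300, end = 1700)
  r <- qtl_enhancer_overlap(track, qtl)
  s <- r$summary[r$summary$state == "Str.Enh", ]
  expect_equal(s$n_segments, 1)
  expect_equal(s$mean_overlap, 700)
  expect_equal(s$median_overlap, 700)

  whole <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  r2 <- qtl_enhancer_overlap(track, whole)
  expect_equal(r2$summary$n_segments[r2$summary$state == "Str.Enh"], 3)
})

test_that("random enhancer placement matches the analytic expectation", {
  # expected hits = n * p where p is the chance a 1-kb segment touches the
  # QTL set (QTL bases + segment length - 1 per QTL, over the genome)
  set.seed(71)
  L <- 1e6
  qtl <- data.frame(chrom = "chr1", start = c(1e5, 6e5), end = c(2e5, 7e5))
  seg_len <- 1000
  p_hit <- sum(qtl$end - qtl$start + seg_len - 1) / L
  n_seg <- 50
  hits <- vapply(1:500, function(i) {
    st <- sample.int(L - seg_len, n_seg) - 1
    track <- data.frame(chrom = "chr1", start = st, end = st + seg_len,
                        state = "EnhG")
    qtl_enhancer_overlap(track, qtl)$summary$n_segments[1]
  }, numeric(1))
  expect_equal(mean(hits), n_seg * p_hit, tolerance = 0.03)
})

test_that("per-chromosome folds follow observed/expected arithmetic", {
  gm <- genome_model(c(chr1 = 1e6, chr2 = 1e6))
  r <- per_chromosome_fold(c(chr1 = 30, chr2 = 10), gm)
  expect_equal(r$fold, c(1.5, 0.5))

  prop <- per_chromosome_fold(c(chr1 = 20, chr2 = 60),
                              genome_model(c(chr1 = 1e6, chr2 = 3e6)))
  expect_equal(prop$fold, c(1, 1))

  single <- per_chromosome_fold(c(chrA = 7), genome_model(c(chrA = 5e5)))
  expect_equal(single$fold, 1)

  zero <- per_chromosome_fold(c(chr1 = 0, chr2 = 0), gm)
  expect_true(all(is.na(zero$fold)))
})

test_that("expected-weighted folds average to 1", {
  set.seed(72)
  sizes <- setNames(sample(1e5:1e6, 8), paste0("chr", 1:8))
  gm <- genome_model(sizes)
  obs <- setNames(rpois(8, 40), names(sizes))
  r <- per_chromosome_fold(obs, gm)
  expect_equal(sum(r$fold * r$expected) / sum(r$expected), 1)
})

test_that("SNP intersection requires QTL, enhancer state and motif", {
  track <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                      end = c(1000, 2000, 3000),
                      state = c("Str.Enh", "Quies", "EnhG"))
  qtl <- data.frame(chrom = "chr1", start = 0, end = 2500, label = "growth")
  motifs <- data.frame(chrom = "chr1", start = c(490, 1490, 2490),
                       end = c(510, 1510, 2510),
                       label = c("m1", "m2", "m3"),
                       tf_family = c("C/EBP", "GR", "GR"))
  snps <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                     chrom = "chr1", pos = c(501, 1501, 2501, 2900))
  r <- intersect_snp_qtl_enhancer_motif(snps, qtl, track, motifs)
  # s1: QTL + Str.Enh + motif -> kept; s2: Quies -> dropped
  # s3: outside the QTL (pos 2501 > 2500) -> dropped; s4: no motif
  expect_equal(r$hits$snp_id, "s1")
  expect_equal(r$hits$trait, "growth")
  expect_equal(r$n_snps, 1)
  expect_equal(r$family_summary$tf_family, "C/EBP")
  expect_equal(r$family_summary$pct, 100)
})

test_that("SNP intersection is stable under QTL interval splitting", {
  track <- data.frame(chrom = "chr1", start = seq(0, 9000, 1000),
                      end = seq(1000, 10000, 1000),
                      state = rep(c("EnhG", "MidEnh"), 5))
  motifs <- data.frame(chrom = "chr1", start = seq(100, 9100, 1000),
                       end = seq(120, 9120, 1000),
                       label = paste0("m", 1:10), tf_family = "GR")
  snps <- data.frame(snp_id = paste0("s", 1:10), chrom = "chr1",
                     pos = seq(111, 9111, 1000))
  q1 <- data.frame(chrom = "chr1", start = 0, end = 10000)
  q2 <- data.frame(chrom = "chr1", start = c(0, 4000), end = c(4000, 10000))
  r1 <- intersect_snp_qtl_enhancer_motif(snps, q1, track, motifs)
  r2 <- intersect_snp_qtl_enhancer_motif(snps, q2, track, motifs)
  expect_setequal(r1$hits$snp_id, r2$hits$snp_id)
  expect_equal(r1$n_snps, r2$n_snps)
  expect_lte(r1$n_snps, r1$n_hits)
})

test_that("planted SNPs and family mix are recovered exactly", {
  cfg <- sim_config(seed = 73, n_chroms = 2, chrom_length = 1e6,
                    n_genes = 80, n_snps = 200, n_qtl = 8)
  g <- simulate_genome(cfg)
  tpm <- simulate_expression(cfg, g$genes)
  tracks <- simulate_state_tracks(cfg, g$genes, tpm, g$genome)
  q <- simulate_qtl_snps(cfg, tracks[[1]], g$genome)
  r <- intersect_snp_qtl_enhancer_motif(q$snps, q$qtl, tracks[[1]], q$motifs)
  expect_setequal(r$hits$snp_id, q$truth$snp_id)
  planted <- table(q$truth$tf_family)
  got <- setNames(r$family_summary$n_snps, r$family_summary$tf_family)
  expect_equal(got[names(planted)], as.table(planted)[names(planted)],
               ignore_attr = TRUE)
})

test_that("SNP readers accept minimal VCF and TSV dialects", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT",
               "chr1\t101\trs1\tA\tG",
               "chr2\t202\trs2\tC\tT"), f)
  v <- read_snps(f)
  expect_equal(v$snp_id, c("rs1", "rs2"))
  expect_equal(v$pos, c(101, 202))

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchrom\tpos", "s1\tchr1\t500"), g)
  w <- read_snps(g)
  expect_equal(w$chrom, "chr1")
  expect_equal(w$pos, 500)
})
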