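make_track <- function(...) {
  segs <- list(...)
  do.call(rbind, lapply(segs, function(s)
    data.frame(chrom = s[[1]], start = as.numeric(s[[2]]),
               end = as.numeric(s[[3]]), state = s[[4]],
               stringsAsFactors = FALSE)))
}

test_that("fold enrichment reproduces the (C/A)/(B/D) arithmetic", {
  gm <- genome_model(c(chr1 = 10000))
  track <- make_track(list("chr1", 0, 1000, "TssA"))        # A = 1000
  element <- data.frame(chrom = "chr1", start = 500, end = 2500)  # B = 2000
  r <- fold_enrichment(track, element, gm, state = "TssA")
  expect_equal(r$A, 1000)
  expect_equal(r$B, 2000)
  expect_equal(r$C, 500)
  expect_equal(r$D, 10000)
  expect_equal(r$fold, 2.5)  # (500/1000)/(2000/10000)
})

test_that("whole-genome element gives fold 1 and absent state gives NA", {
  gm <- genome_model(c(chr1 = 10000))
  track <- make_track(list("chr1", 0, 1000, "TssA"))
  whole <- data.frame(chrom = "chr1", start = 0, end = 10000)
  r <- fold_enrichment(track, whole, gm, state = "TssA")
  expect_equal(r$fold, 1)
  r0 <- fold_enrichment(track, whole, gm, state = "EnhG")
  expect_equal(r0$A, 0)
  expect_true(is.na(r0$fold))
})

test_that("fold enrichment is invariant to splitting element intervals", {
  gm <- genome_model(c(chr1 = 50000))
  track <- make_track(list("chr1", 1000, 4000, "Str.Enh"),
                      list("chr1", 10000, 12000, "Str.Enh"))
  elem <- data.frame(chrom = "chr1", start = c(0, 11000), end = c(3000, 15000))
  split_elem <- data.frame(chrom = "chr1",
                           start = c(0, 1500, 11000, 12000, 11500),
                           end = c(1500, 3000, 12000, 15000, 13000))
  a <- fold_enrichment(track, elem, gm, "Str.Enh")
  b <- fold_enrichment(track, split_elem, gm, "Str.Enh")
  expect_equal(a, b)
})

test_that("state C values sum to element coverage on a complete tiling", {
  cfg <- sim_config(seed = 3, n_chroms = 2, chrom_length = 5e5, n_genes = 60)
  g <- simulate_genome(cfg)
  tpm <- simulate_expression(cfg, g$genes)
  tracks <- simulate_state_tracks(cfg, g$genes, tpm, g$genome)
  elem <- data.frame(chrom = c("chr1", "chr2"), start = c(10000, 50000),
                     end = c(90000, 170000))
  r <- fold_enrichment(tracks[[1]], elem, g$genome)
  expect_equal(sum(r$C), interval_bases(elem))
})

test_that("uniform random placement of a state has mean fold near 1", {
  # Monte-Carlo null: a fixed-size state placed uniformly in the genome
  # against a fixed element set should show no enrichment on average
  set.seed(202)
  gm <- genome_model(c(chr1 = 1e6))
  element <- data.frame(chrom = "chr1",
                        start = seq(0, 9e5, by = 1e5),
                        end = seq(0, 9e5, by = 1e5) + 40000)
  folds <- vapply(1:300, function(i) {
    st <- sort(sample.int(1e6 - 2000, 25) - 1)
    st <- st[c(TRUE, diff(st) > 2000)]  # keep disjoint
    track <- data.frame(chrom = "chr1", start = st, end = st + 2000,
                        state = "MidEnh")
    fold_enrichment(track, element, gm, "MidEnh")$fold
  }, numeric(1))
  expect_gt(mean(folds), 0.95)
  expect_lt(mean(folds), 1.05)
})

test_that("state_summary reports count, coverage and lengths", {
  gm <- genome_model(c(chr1 = 10000))
  track <- make_track(list("chr1", 0, 100, "TssA"),
                      list("chr1", 100, 400, "TssA"),
                      list("chr1", 400, 10000, "Quies"))
  s <- state_summary(track, gm)
  tssa <- s[s$state == "TssA", ]
  expect_equal(tssa$count, 2)
  expect_equal(tssa$mean_length, 200)
  expect_equal(tssa$median_length, 200)
  expect_equal(sum(s$pct_genome), 100, tolerance = 1e-9)
})

test_that("incomplete tilings warn and simulated dwell lengths are recovered", {
  gm <- genome_model(c(chr1 = 10000))
  partial <- make_track(list("chr1", 0, 1000, "TssA"))
  expect_warning(state_summary(partial, gm), "percentages")

  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length = 1e7,
                    n_genes = 100, tissues = c("brain", "liver"))
  g <- simulate_genome(cfg)
  tpm <- simulate_expression(cfg, g$genes)
  tracks <- simulate_state_tracks(cfg, g$genes, tpm, g$genome)
  s <- expect_silent(state_summary(tracks[[1]], g$genome))
  # filler states follow the configured exponential dwell; the min-length
  # clamp biases the realized mean up by ~2%, well within 10%
  mid <- s$mean_length[s$state == "MidEnh"]
  expect_gt(mid, 0.9 * cfg$state_dwell[["MidEnh"]])
  expect_lt(mid, 1.15 * cfg$state_dwell[["MidEnh"]])
})

test_that("density profiles peak where the state covers every TSS", {
  gm <- genome_model(c(chr1 = 1e6))
  set.seed(5)
  tss <- seq(20000, 900000, by = 45000)
  genes <- data.frame(gene_id = paste0("g", seq_along(tss)), chrom = "chr1",
                      start = tss, end = tss + 2000, strand = "+",
                      tss = tss, tes = tss + 2000)
  track <- data.frame(chrom = "chr1", start = tss - 50, end = tss + 50,
                      state = "TssA")
  prof <- state_density_profile(track, genes, window = 2000, bin = 100)
  expect_equal(prof$density[prof$offset == 0], 1)
  expect_equal(prof$density[prof$offset == -2000], 0)

  none <- state_density_profile(
    data.frame(chrom = "chr1", start = 0, end = 10, state = "BivEnh"),
    genes, window = 2000, bin = 100, states = "BivEnh")
  expect_true(all(none$density == 0))
})

test_that("planted TssA enrichment at expressed TSSs shows in the profile", {
  cfg <- sim_config(seed = 21, n_chroms = 2, chrom_length = 1e6, n_genes = 80)
  g <- simulate_genome(cfg)
  tpm <- simulate_expression(cfg, g$genes)
  tracks <- simulate_state_tracks(cfg, g$genes, tpm, g$genome)
  t1 <- names(tracks)[1]
  expressed <- g$genes[tpm[g$genes$gene_id, t1] > 2, ]
  prof <- state_density_profile(tracks[[1]], expressed, window = 5000,
                                bin = 500, states = "TssA")
  peak <- prof$density[prof$offset == 0]
  flank <- mean(prof$density[abs(prof$offset) >= 3000])
  expect_gt(peak, flank)
  expect_equal(peak, 1)  # every expressed TSS carries a planted TssA

  # genome-wide TssA base fraction is far below the at-TSS frequency
  s <- state_summary(tracks[[1]], g$genome)
  expect_gt(peak, s$pct_genome[s$state == "TssA"] / 100)
})
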