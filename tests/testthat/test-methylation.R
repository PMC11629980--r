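cpg <- function(pos, c, t, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos, reads_c = c,
             reads_t = t, stringsAsFactors = FALSE)
}

test_that("methylation level is C / (C + T) and scale-free", {
  x <- methylation_level(cpg(c(10, 20, 30), c(3, 0, 0), c(7, 5, 0)))
  expect_equal(x$level, c(0.3, 0, NA_real_))
  scaled <- methylation_level(cpg(c(10, 20), c(30, 0), c(70, 50)))
  expect_equal(scaled$level, c(0.3, 0))
  expect_error(methylation_level(cpg(1, -1, 5)), "negative")
})

test_that("depth filters drop shallow sites and extreme-coverage outliers", {
  x <- cpg(1:12, rep(5, 12), c(rep(15, 10), 4, 4995))  # depths 20,20,...,9,5000
  f <- filter_sites(x)
  expect_false(any(f$depth < 10))
  expect_false(any(f$depth == 5000))  # above the 99.9th percentile
  expect_equal(nrow(f), 10)

  all20 <- filter_sites(cpg(1:50, rep(10, 50), rep(10, 50)))
  expect_equal(nrow(all20), 50)  # degenerate distribution keeps everything

  expect_equal(nrow(filter_sites(cpg(numeric(), numeric(), numeric()))), 0)
})

test_that("the depth quantile matches a sort-based percentile oracle", {
  set.seed(61)
  x <- cpg(seq_len(10000), rpois(10000, 15), rpois(10000, 15))
  x$reads_c[7777] <- 100000  # one extreme outlier
  depth <- x$reads_c + x$reads_t
  q <- percentile_oracle(depth, 0.999)
  f <- filter_sites(x)
  expect_true(all(f$reads_c + f$reads_t <= q))
  expect_false(7777 %in% which(x$pos %in% f$pos & depth > q))
  removed_high <- x$pos[depth > q]
  expect_true(all(!removed_high %in% f$pos))
})

test_that("refiltering filtered sites is a (near) no-op", {
  # with ties spanning the percentile threshold the filter is exactly
  # idempotent
  set.seed(62)
  x <- cpg(seq_len(5000), sample(5:15, 5000, replace = TRUE), 10)
  f1 <- filter_sites(x)
  f2 <- filter_sites(f1[, c("chrom", "pos", "reads_c", "reads_t")])
  expect_equal(f1$pos, f2$pos)
  # on Poisson depths the tie mass at the 99.9th percentile is of the same
  # order as the tail itself, so a second pass can shave at most ~0.1% of
  # sites and never touches the min-depth rule
  y <- cpg(seq_len(20000), rpois(20000, 8), rpois(20000, 7))
  g1 <- filter_sites(y)
  g2 <- filter_sites(g1[, c("chrom", "pos", "reads_c", "reads_t")])
  expect_true(all(g2$pos %in% g1$pos))
  expect_lte(nrow(g1) - nrow(g2), ceiling(0.001 * nrow(g1)))
  expect_true(all(g2$depth >= 10))
})

test_that("TSS profiles are flat on a uniform methylome and track bins", {
  genes <- toy_genes()
  set.seed(63)
  pos <- sort(sample.int(60000, 3000))
  x <- cpg(pos, 75, 25)
  prof <- tss_methylation_profile(x, genes, window = 2000, bin = 200)
  expect_true(all(abs(prof$mean_level - 0.75) < 1e-12, na.rm = TRUE))

  # single gene, single site at +150 with level 0.4 -> bin [100,200) = 0.4
  g1 <- genes[1, ]
  one <- cpg(g1$tss + 150, 4, 6)
  p1 <- tss_methylation_profile(one, g1, window = 1000, bin = 100)
  expect_equal(p1$mean_level[p1$offset == 100], 0.4)
  expect_true(all(is.na(p1$mean_level[p1$offset != 100])))
  expect_equal(p1$n_genes[p1$offset == 100], 1)
})

test_that("TSS profiles are strand-aware (mirror symmetry)", {
  L <- 100000
  gp <- data.frame(gene_id = "g1", chrom = "chr1", start = 50000,
                   end = 52000, strand = "+", tss = 50000, tes = 52000)
  gm <- data.frame(gene_id = "g1", chrom = "chr1", start = L - 52000,
                   end = L - 50000, strand = "-", tss = L - 50000,
                   tes = L - 52000)
  set.seed(64)
  pos <- sort(sample(40000:60000, 500))
  lev_c <- rbinom(500, 20, 0.6)
  xp <- cpg(pos, lev_c, 20 - lev_c)
  xm <- cpg(rev(L - 1 - pos), rev(lev_c), rev(20 - lev_c))
  pp <- tss_methylation_profile(xp, gp, window = 2000, bin = 100)
  pm <- tss_methylation_profile(xm, gm, window = 2000, bin = 100)
  expect_equal(pm$mean_level, pp$mean_level)
})

test_that("planted TSS hypomethylation dip is located and sized correctly", {
  cfg <- sim_config(seed = 65, n_chroms = 2, chrom_length = 1e6,
                    n_genes = 100, n_cpg = 40000)
  g <- simulate_genome(cfg)
  me <- simulate_methylome(cfg, g$genes, g$genome)  # no active-state ceiling
  f <- filter_sites(me)
  prof <- tss_methylation_profile(f, g$genes)
  expect_equal(prof$offset[which.min(prof$mean_level)], 0)
  expect_equal(min(prof$mean_level, na.rm = TRUE),
               cfg$tss_hypomethylation_depth, tolerance = 0.15)
  far <- prof$mean_level[abs(prof$offset) > 6000]
  expect_equal(mean(far, na.rm = TRUE), cfg$methylation_background,
               tolerance = 0.02)
})

test_that("state-body methylation profiles aggregate scaled bins", {
  track <- data.frame(chrom = "chr1", start = 10000, end = 11000,
                      state = "TssA")
  one <- cpg(10400, 6, 4)  # 40% through the body -> bin 8 of 20
  p <- state_methylation_profile(one, track)
  expect_equal(p$bin, 8)
  expect_equal(p$mean_level, 0.6)

  # uniform methylome: body and flank means agree
  set.seed(66)
  pos <- sort(sample(5000:16000, 2000))
  unif <- cpg(pos, 15, 5)
  pu <- state_methylation_profile(unif, track)
  body <- pu$mean_level[pu$bin >= 0 & pu$bin < 20]
  flank <- pu$mean_level[pu$bin < 0 | pu$bin >= 20]
  expect_true(all(abs(c(body, flank) - 0.75) < 1e-12))

  empty_state <- track; empty_state$state <- "Quies"
  expect_warning(state_methylation_profile(one, empty_state,
                                           states = c("Quies", "TssA")),
                 "no instances")
})

test_that("planted active-state hypomethylation shows body < flank", {
  cfg <- sim_config(seed = 67, n_chroms = 2, chrom_length = 1e6,
                    n_genes = 80, n_cpg = 40000)
  g <- simulate_genome(cfg)
  tpm <- simulate_expression(cfg, g$genes)
  tracks <- simulate_state_tracks(cfg, g$genes, tpm, g$genome)
  me <- simulate_methylome(cfg, g$genes, g$genome, track = tracks[[1]])
  f <- filter_sites(me)
  p <- state_methylation_profile(f, tracks[[1]], states = "TssA")
  body <- mean(p$mean_level[p$bin >= 0 & p$bin < 20])
  flank <- mean(p$mean_level[p$bin < 0 | p$bin >= 20])
  expect_lt(body, flank)
})

test_that("methylation-expression coupling is recovered with correct sign", {
  set.seed(68)
  n <- 150
  tss <- seq(20000, by = 15000, length.out = n)
  genes <- data.frame(gene_id = paste0("g", 1:n), chrom = "chr1",
                      start = tss, end = tss + 1000, strand = "+",
                      tss = tss, tes = tss + 1000)
  lt <- runif(n, -1, 3)
  tpm <- setNames(10^lt, genes$gene_id)
  # planted coupling: promoter methylation decreases with expression
  level <- 0.8 - 0.15 * (lt + 1) / 4
  sites <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- tss[i] + seq(-2000, 2000, by = 250)
    c_reads <- rbinom(length(p), 40, level[i])
    cpg(p, c_reads, 40 - c_reads)
  }))
  r <- methylation_expression_association(sites, genes, tpm)
  expect_lt(r$r, 0)
  expect_gt(abs(r$r), 0.6)
  expect_lt(r$p_value, 0.001)

  const <- do.call(rbind, lapply(seq_len(n), function(i)
    cpg(tss[i] + 100, 30, 10)))
  rc <- methylation_expression_association(const, genes, tpm)
  expect_true(rc$degenerate)
  expect_true(is.na(rc$r))

  expect_error(methylation_expression_association(sites[1:3, ], genes[1:2, ],
                                                  tpm), "fewer than 3")
})
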