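test_that("segregation chi-square has no continuity correction and is symmetric", {
  expect_equal(chi_square_segregation(100, 100)$statistic, 0)
  r <- chi_square_segregation(60, 40)
  expect_equal(r$statistic, 4)          # 2 * 10^2 / 50
  expect_true(r$significant)
  for (s in 1:10) {
    set.seed(s)
    a <- sample.int(5000, 1); b <- sample.int(5000, 1)
    expect_equal(chi_square_segregation(a, b)$statistic,
                 chi_square_segregation(b, a)$statistic)
  }
  expect_error(chi_square_segregation(0, 0), "zero")
  expect_error(chi_square_segregation(-1, 5), "non-negative")
})

test_that("marker screening and binning match an exhaustive grouping oracle", {
  # 8 samples x 6 markers with known duplicate structure
  g <- cbind(c(0, 0, 1, 1, 0, 1, 0, 1),   # A
             c(0, 0, 1, 1, 0, 1, 0, 1),   # duplicate of A
             c(1, 1, 0, 0, 1, 0, 1, 0),   # complement (own bin)
             c(0, 0, 1, 1, 0, 1, 0, 1),   # duplicate of A
             c(0, NA, 1, 1, 0, 1, 0, 1),  # A with a missing call: own bin
             c(0, 1, 1, 1, 0, 1, 0, 1))   # distinct
  mk <- data.frame(id = paste0("m", 1:6), chrom = "chr1",
                   pos = seq(100, 600, 100))
  res <- screen_and_bin_markers(g, mk, max_missing = 0.2, min_maf = 0.05)
  # brute-force pairwise grouping
  key <- apply(g, 2, function(x) paste(ifelse(is.na(x), "m", x), collapse = ""))
  oracle <- split(mk$id, match(key, unique(key)))
  expect_equal(unname(res$bins[order(names(res$bins))]),
               unname(oracle[order(vapply(oracle, `[`, "", 1))]))
  expect_equal(res$representatives, c("m1", "m3", "m5", "m6"))
  # partition: every surviving marker in exactly one bin
  expect_setequal(unlist(res$bins), mk$id)
  expect_equal(sum(lengths(res$bins)), 6)

  # MAF filter: minor-allele count 2 of 100 is removed
  g2 <- cbind(rep(0:1, each = 50), c(rep(0, 98), 1, 1))
  mk2 <- data.frame(id = c("keep", "rare"), chrom = "chr1", pos = c(1, 2))
  res2 <- screen_and_bin_markers(g2, mk2)
  expect_equal(res2$representatives, "keep")
  # missing-rate filter
  g3 <- cbind(rep(0:1, 10), c(rep(NA, 5), rep(0:1, length.out = 15)))
  res3 <- screen_and_bin_markers(g3, data.frame(id = c("a", "b"),
                                                chrom = "chr1", pos = 1:2))
  expect_equal(res3$representatives, "a")
  expect_error(screen_and_bin_markers(g3 * NA, data.frame(
    id = c("a", "b"), chrom = "chr1", pos = 1:2)), "all markers removed")
})

test_that("LOD score: closed form at perfect cosegregation, zero at independence, monotone", {
  n <- 56
  ph <- rep(c("RT", "WT"), each = n / 2)
  g_perfect <- as.integer(ph == "RT")
  g_half <- c(rep(1L, 14), rep(0L, 14), rep(1L, 14), rep(0L, 14))  # r = n/2
  geno <- cbind(g_perfect, g_half)
  mk <- data.frame(id = c("linked", "free"), chrom = "chr1",
                   pos = c(1e6, 4e6))
  sc <- lod_scan(geno, ph, mk, n_perm = 200, seed = 3)
  expect_equal(sc$table$lod[1], 56 * log10(2), tolerance = 1e-12)
  expect_equal(sc$table$lod[2], 0)
  expect_true(all(sc$table$lod >= 0))
  # monotone decrease as r moves from 0 to n/2
  lods <- vapply(0:28, function(r) tetramap:::.lod_from_r(r, 56), 0)
  expect_true(all(diff(lods) < 0))
  expect_error(lod_scan(geno, rep("RT", n), mk), "both phenotype classes")
})

test_that("LOD peaks above the permutation threshold recover a planted locus and merge nearby peaks", {
  spec <- tiny_spec(n_markers = 120, seed = 8)
  p <- simulate_parents(spec)
  tets <- simulate_tetrads(p, 84, seed = 81)
  pop <- assemble_population(tets, p, seed = 82)
  mk <- data.frame(id = sprintf("M%03d", seq_len(nrow(p))), chrom = p$chrom,
                   pos = p$pos)
  sc <- lod_scan(pop$genotypes, pop$samples$phenotype, mk, n_perm = 500,
                 cm_per_mb = spec$recomb_rate, seed = 83)
  expect_gt(nrow(sc$peaks), 0)
  top <- sc$peaks[which.max(sc$peaks$lod), ]
  expect_equal(top$chrom, "chr1")
  expect_lte(top$support_start, spec$causal_pos)
  expect_gte(top$support_end, spec$causal_pos)
  # support interval contains its peak
  expect_true(all(sc$peaks$support_start <= sc$peaks$pos &
                  sc$peaks$support_end >= sc$peaks$pos))
  # markers tightly linked to the locus (all within 10 cM) yield one merged peak
  near <- which(p$chrom == "chr1" & abs(p$pos - spec$causal_pos) < 1e6)
  sc2 <- lod_scan(pop$genotypes[, near, drop = FALSE],
                  pop$samples$phenotype, mk[near, ], n_perm = 300,
                  cm_per_mb = spec$recomb_rate, seed = 84)
  expect_equal(nrow(sc2$peaks), 1)
})

test_that("recombinant narrowing reproduces the printed marker layout and is idempotent", {
  # one flanking marker with nine recombinants, three cosegregating markers
  set.seed(5)
  n <- 328
  ph <- rep(c("RT", "WT"), length.out = n)
  expected <- as.integer(ph == "RT")
  geno <- matrix(rep(expected, 4), n, 4)
  rec_samples <- sample(n, 9)
  geno[rec_samples, 1] <- 1L - geno[rec_samples, 1]
  rownames(geno) <- sprintf("F1-%03d", seq_len(n))
  mk <- data.frame(id = paste0("SNP", 1:4),
                   pos = c(41578129, 41900000, 42400000, 42900000))
  out <- narrow_by_recombinants(mk, geno, ph, prior = c(39700001, 43000000))
  expect_equal(unname(out$region), c(41578129, 43000000))
  expect_equal(round((out$region[["end"]] - out$region[["start"]]) / 1e6, 2),
               1.42)
  expect_setequal(out$recombinants$SNP1, rownames(geno)[rec_samples])
  expect_setequal(out$cosegregating, c("SNP2", "SNP3", "SNP4"))
  # idempotent: rerunning on the narrowed region changes nothing
  again <- narrow_by_recombinants(mk, geno, ph, prior = out$region)
  expect_equal(again$region, out$region)
  # no recombinants anywhere: prior returned unchanged
  g0 <- matrix(rep(expected, 4), n, 4)
  expect_equal(unname(narrow_by_recombinants(mk, g0, ph,
               c(39700001, 43000000))$region), c(39700001, 43000000))
  expect_error(narrow_by_recombinants(mk[c(2, 1, 3, 4), ], geno, ph,
               c(1, 2)), "ordered")
})

test_that("narrowing matches hand-enumerated toy crossovers and stays inside the prior", {
  # five markers; recombinants at the two outermost on each side
  ph <- rep(c("RT", "WT"), each = 10)
  e <- as.integer(ph == "RT")
  geno <- sapply(1:5, function(j) e)
  geno[1, 1] <- 1L - geno[1, 1]   # marker 1: recombinant
  geno[2, 2] <- 1L - geno[2, 2]   # marker 2: recombinant (innermost left)
  geno[3, 5] <- 1L - geno[3, 5]   # marker 5: recombinant (innermost right)
  mk <- data.frame(id = paste0("m", 1:5), pos = c(10, 20, 30, 40, 50) * 1e5)
  out <- narrow_by_recombinants(mk, geno, ph, prior = c(1, 6e6))
  expect_equal(unname(out$region), c(2e6, 5e6))
  expect_equal(out$cosegregating, c("m3", "m4"))
  expect_gte(out$region[["start"]], 1)
  expect_lte(out$region[["end"]], 6e6)
})
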