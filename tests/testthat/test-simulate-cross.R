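test_that("parental table: fixed biallelic differences, deterministic, validated", {
  spec <- tiny_spec(n_markers = 100)
  p <- simulate_parents(spec)
  expect_gte(nrow(p), 100)
  expect_true(all(p$ref != p$alt))
  expect_true(all(p$pos >= 1))
  expect_equal(sum(p$is_causal), 1)
  expect_equal(p$pos[p$is_causal], 2.5e6)
  # strictly increasing positions per chromosome
  for (ch in unique(p$chrom))
    expect_false(is.unsorted(p$pos[p$chrom == ch], strictly = TRUE))
  expect_identical(p, simulate_parents(tiny_spec(n_markers = 100)))
  expect_error(genome_spec(chrom_lengths = c(chr1 = 1e6), causal_chrom = "chr1",
                           causal_pos = 2e6), "outside")
  expect_error(genome_spec(n_markers = 0), "n_markers")
  expect_error(genome_spec(recomb_rate = -1), "recomb_rate")
})

test_that("tetrads: exact 2:2 segregation, zero-recombination limit", {
  spec <- tiny_spec(n_markers = 60, seed = 4)
  p <- simulate_parents(spec)
  tets <- simulate_tetrads(p, 200, seed = 11)
  for (t in tets)
    expect_true(all(colSums(t$genotypes) == 2L))
  # zero recombination on one chromosome: two products per parent
  # (chromosomes assort independently, so this is a per-chromosome property)
  p1c <- manual_parents(seq(1e5, 4e6, by = 1e5), chrom_len = 5e6)
  t0 <- simulate_tetrad(p1c, recomb_rate = 0, seed = 3)
  rows <- apply(t0$genotypes, 1, function(g) paste(g, collapse = ""))
  all0 <- paste(rep(0L, nrow(p1c)), collapse = "")
  all1 <- paste(rep(1L, nrow(p1c)), collapse = "")
  expect_equal(sum(rows == all0), 2)
  expect_equal(sum(rows == all1), 2)
  expect_error(simulate_tetrad(p, recomb_rate = -0.1), "non-negative")
})

test_that("recombinant fraction between two markers follows Haldane's map function", {
  # 50 cM apart: expected recombinant-product fraction 0.5 * (1 - exp(-1))
  p <- manual_parents(c(1, 10000001), chrom_len = 10000001, recomb_rate = 5)
  n <- 10000
  tets <- simulate_tetrads(p, n, seed = 6)
  frac <- mean(vapply(tets, function(t)
    mean(t$genotypes[, 1] != t$genotypes[, 2]), 0))
  expected <- 0.5 * (1 - exp(-2 * 0.5))
  # complement products share recombination status: 2 informative per tetrad
  se <- sqrt(expected * (1 - expected) / (2 * n))
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("sectors: phenotype equals causal allele, 1:1 segregation, blades are tetrad subsets", {
  spec <- tiny_spec(n_markers = 40, seed = 9)
  p <- simulate_parents(spec)
  n_tet <- 3600  # ~10,000 sectors
  tets <- simulate_tetrads(p, n_tet, seed = 21)
  pop <- assemble_population(tets, p, seed = 22)
  causal <- which(p$is_causal)
  expect_true(all((pop$genotypes[, causal] == 1L) ==
                  (pop$samples$phenotype == "RT")))
  n <- nrow(pop$samples)
  n_rt <- sum(pop$samples$phenotype == "RT")
  expect_lt(abs(n_rt - n / 2), 3 * sqrt(n * 0.25))
  # a 4-sector blade carries exactly the tetrad's four products
  b4 <- pop$samples$blade_id[pop$samples$sectors_in_blade == 4][1]
  idx <- which(pop$samples$blade_id == b4)
  expect_equal(length(idx), 4)
  tet <- tets[[as.integer(sub("B", "", b4))]]
  g_blade <- pop$genotypes[idx, , drop = FALSE]
  expect_equal(sort(unname(apply(g_blade, 1, paste, collapse = ""))),
               sort(apply(tet$genotypes, 1, paste, collapse = "")))
  expect_error(assemble_population(list(), p), "empty")
  expect_error(assemble_population(tets, p, sector_dist = c(1, 1, 0, 0)),
               "sum")
})

test_that("bulks: fixation at the causal locus, null at unlinked markers, binomial depth scaling", {
  spec <- tiny_spec(n_markers = 150, seed = 5)
  p <- simulate_parents(spec)
  tets <- simulate_tetrads(p, 300, seed = 31)
  pop <- assemble_population(tets, p, seed = 32)
  b <- build_bulks(pop, 56, 56, mean_depth = 100, seed = 33)
  causal <- which(p$is_causal)
  expect_equal(b$RT.alt[causal], b$RT.dp[causal])  # RT bulk fixed for alt
  expect_equal(b$WT.alt[causal], 0)
  # unlinked chromosome: pooled alt fraction near 0.5
  un <- which(b$chrom == "chr2")
  frac <- sum(b$RT.alt[un]) / sum(b$RT.dp[un])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 56))  # bulk composition dominates
  expect_error(build_bulks(pop, 10000, 10, 100), "not enough")
  expect_error(build_bulks(pop, 5, 5, 0), "mean_depth")

  # bulk allele-frequency variance shrinks with bulk size: p(1-p)/n
  un1 <- un[1]
  freq_at <- function(n_bulk, s) {
    bb <- build_bulks(pop, n_bulk, n_bulk, 100, seed = 1000 + s)
    mem <- attr(bb, "members")
    mean(pop$genotypes[match(mem$rt, pop$samples$sample_id), un1])
  }
  v24 <- stats::var(vapply(1:40, function(s) freq_at(24, s), 0))
  v56 <- stats::var(vapply(1:40, function(s) freq_at(56, s * 71), 0))
  expect_gt(v24, v56)
})

test_that("annotation: consistent ids, one non-synonymous SNP, in-frame CDS", {
  spec <- tiny_spec(n_markers = 50, seed = 2)
  td <- withr::local_tempdir()
  ann <- simulate_annotation_and_expression(
    spec, seed = 8, n_genes = 60, n_background_genes = 40,
    n_background_degs = 10,
    gff = file.path(td, "a.gff3"), cds_fasta = file.path(td, "c.fa"),
    expr = file.path(td, "e.tsv"), truth = file.path(td, "t.tsv"))
  expect_equal(length(ann$genes), 60)
  expect_equal(sum(ann$snps$class == "coding_nonsynonymous"), 1)
  expect_true(ann$candidate_gene %in% vapply(ann$genes, `[[`, "", "gene_id"))
  expect_true(ann$candidate_gene %in% ann$expression$gene_id)
  lens <- vapply(ann$genes, function(g) sum(g$segments$end - g$segments$start + 1), 0)
  expect_true(all(lens %% 3 == 0))
  expect_true(all(vapply(ann$genes, function(g) nchar(g$cds_seq), 0) == lens))
  # files round-trip with consistent ids
  genes <- read_gene_models(file.path(td, "a.gff3"), file.path(td, "c.fa"))
  expect_setequal(vapply(genes, `[[`, "", "gene_id"),
                  vapply(ann$genes, `[[`, "", "gene_id"))
  ex <- read.delim(file.path(td, "e.tsv"))
  expect_true(ann$candidate_gene %in% ex$gene_id)
  expect_error(simulate_annotation_and_expression(
    spec, region = c(2.4e6, 2.6e6), n_genes = 141), "too small")
})

test_that("1:1 phenotype segregation passes the chi-square test in nearly all simulations", {
  spec <- tiny_spec(n_markers = 12, seed = 3)
  p <- simulate_parents(spec)
  ok <- vapply(1:100, function(s) {
    tets <- simulate_tetrads(p, 120, seed = 5000 + s)
    pop <- assemble_population(tets, p, seed = 6000 + s)
    tab <- table(factor(pop$samples$phenotype, c("WT", "RT")))
    !chi_square_segregation(tab[["WT"]], tab[["RT"]])$significant
  }, TRUE)
  expect_gte(mean(ok), 0.94)
})
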