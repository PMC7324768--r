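test_that("codon-level effect calls: Gln>Pro missense, silent Leu, distance rules", {
  g <- gene_model("g1", "chr1", "+", data.frame(start = 1001, end = 1009),
                  cds_seq = "ATGCAACTA")
  # A>C at the 2nd base of the CAA codon: Gln (Q) -> Pro (P)
  e <- classify_snp_effect(1005, "A", "C", list(g))
  expect_equal(e$class, "coding_nonsynonymous")
  expect_equal(e$codon_index, 2)
  expect_equal(e$aa_ref, "Q")
  expect_equal(e$aa_alt, "P")
  # A>G at the 3rd base of CTA (-> CTG): Leu -> Leu
  e2 <- classify_snp_effect(1009, "A", "G", list(g))
  expect_equal(e2$class, "coding_synonymous")
  expect_equal(c(e2$aa_ref, e2$aa_alt), c("L", "L"))
  # 5,000 bp from the nearest gene with a 1,000-bp flank: intergenic
  expect_equal(classify_snp_effect(6009, "A", "C", list(g))$class,
               "intergenic")
  # within the flank: upstream/downstream follow the strand
  expect_equal(classify_snp_effect(500, "A", "C", list(g))$class, "upstream")
  expect_equal(classify_snp_effect(1500, "A", "C", list(g))$class,
               "downstream")
  gm <- gene_model("g2", "chr1", "-", data.frame(start = 1001, end = 1009),
                   cds_seq = "ATGCAACTA")
  expect_equal(classify_snp_effect(1500, "A", "C", list(gm))$class, "upstream")
  # errors: missing CDS, ambiguous base, reference mismatch
  g_noseq <- gene_model("g3", "chr1", "+", data.frame(start = 1001, end = 1009))
  expect_error(classify_snp_effect(1005, "A", "C", list(g_noseq)), "missing")
  expect_error(classify_snp_effect(1005, "N", "C", list(g)), "ambiguous")
  expect_error(classify_snp_effect(1005, "C", "A", list(g)), "mismatch")
})

test_that("coding call beats a regulatory call from a neighbouring gene", {
  ga <- gene_model("a", "chr1", "+", data.frame(start = 1001, end = 1009),
                   cds_seq = "ATGCAACTA")
  gb <- gene_model("b", "chr1", "+", data.frame(start = 1200, end = 1208),
                   cds_seq = "ATGAAACCC")
  e <- classify_snp_effect(1203, "A", "C", list(ga, gb))  # in b CDS, a flank
  expect_equal(e$class, "coding_nonsynonymous")
  expect_equal(e$gene_id, "b")
})

test_that("effect classification is strand-symmetric under genome reversal", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- 10000
  for (s in 1:8) {
    set.seed(s)
    n_cod <- 30
    cds <- paste0("ATG", paste(sample(setdiff(
      c(outer(c("A","C","G","T"), c(outer(c("A","C","G","T"),
        c("A","C","G","T"), paste0)), paste0)),
      c("TAA","TAG","TGA")), n_cod - 1, TRUE), collapse = ""))
    start <- sample(2000:5000, 1)
    segs <- data.frame(start = start, end = start + 3 * n_cod - 1)
    strand <- sample(c("+", "-"), 1)
    g <- gene_model("g", "chr1", strand, segs, cds)
    pos <- sample(segs$start:segs$end, 1)
    base_plus <- if (strand == "+") substr(cds, pos - start + 1, pos - start + 1)
      else comp[[substr(cds, segs$end - pos + 1, segs$end - pos + 1)]]
    alt <- sample(setdiff(names(comp), base_plus), 1)
    e <- classify_snp_effect(pos, base_plus, alt, list(g))
    # mirrored genome: coordinates reflected, strand flipped, bases complemented
    g2 <- gene_model("g", "chr1", if (strand == "+") "-" else "+",
                     data.frame(start = L - segs$end + 1,
                                end = L - segs$start + 1), cds)
    e2 <- classify_snp_effect(L - pos + 1, comp[[base_plus]], comp[[alt]],
                              list(g2))
    expect_equal(e2[c("class", "codon_index", "aa_ref", "aa_alt")],
                 e[c("class", "codon_index", "aa_ref", "aa_alt")])
  }
})

test_that("every planted SNP gets exactly one class and the truth classes are recovered", {
  spec <- tiny_spec(n_markers = 30, seed = 12)
  ann <- simulate_annotation_and_expression(spec, seed = 13, n_genes = 80,
                                            n_background_genes = 20,
                                            n_background_degs = 5)
  eff <- classify_snps(ann$snps[c("chrom", "pos", "ref", "alt")], ann$genes)
  expect_equal(nrow(eff), nrow(ann$snps))
  expect_equal(eff$class, ann$snps$class)
  valid <- c("intergenic", "upstream", "downstream", "coding_synonymous",
             "coding_nonsynonymous")
  expect_true(all(eff$class %in% valid))
  expect_equal(sum(table(eff$class)), nrow(ann$snps))
})

test_that("protein length trims a terminal stop only when the sequence shows one", {
  expect_equal(protein_length(1338), 446)
  expect_equal(protein_length(3), 1)
  expect_equal(protein_length(cds_seq = "ATGAAATAA"), 2)
  expect_equal(protein_length(cds_seq = "ATGAAAAAA"), 3)
  expect_error(protein_length(1000), "divisible")
})

test_that("DEG filter is strict, sign-splitting, detection-aware and idempotent", {
  ex <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   log2fc = c(1.0, -2.3, 0.5, 4, NA),
                   detected = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  d <- deg_filter(ex)
  expect_equal(d$gene_id, "b")      # 1.0 excluded (strict), d undetected
  expect_equal(d$direction, "down")
  expect_equal(deg_filter(d[names(ex)]), d)
})

test_that("candidate ranking: planted gene first, region gate, position fallback", {
  spec <- tiny_spec(n_markers = 30, seed = 17)
  ann <- simulate_annotation_and_expression(spec, seed = 18)
  eff <- classify_snps(ann$snps[c("chrom", "pos", "ref", "alt")], ann$genes)
  rk <- prioritize_candidates(c(ann$region[["start"]], ann$region[["end"]]),
                              ann$chrom, ann$genes, eff, ann$expression)
  expect_equal(rk$gene_id[1], ann$candidate_gene)
  expect_equal(rk$rank[1], 1)
  expect_equal(sum(rk$rank == 1), 1)
  # a DEG outside the region is excluded
  expect_false(any(grepl("^B", rk$gene_id)))
  # no DEGs, no effects: ordered by position
  empty_expr <- data.frame(gene_id = character(), log2fc = numeric(),
                           detected = logical())
  rk0 <- prioritize_candidates(c(ann$region[["start"]], ann$region[["end"]]),
                               ann$chrom, ann$genes, eff[0, ], empty_expr)
  expect_equal(rk0$start, sort(rk0$start))
})

test_that("2^-ddCt relative expression", {
  expect_equal(ddct(20, 18, 22, 20), 1)
  expect_equal(ddct(21, 18, 22, 20), 0.5)
  expect_equal(ddct(18, 18, 22, 20), 4)
  expect_error(ddct(Inf, 18, 22, 20), "finite")
})
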