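#' Gene model
#'
#' A strand-aware protein-coding gene model: sorted, non-overlapping CDS
#' segments in genome coordinates plus the CDS sequence in transcript
#' orientation.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome.
#' @param strand "+" or "-".
#' @param segments data.frame with 1-based inclusive \code{start}, \code{end}.
#' @param cds_seq CDS sequence (transcript orientation) or \code{NULL}.
#' @return Object of class \code{"gene_model"}.
#' @export
gene_model <- function(gene_id, chrom, strand, segments, cds_seq = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$end < segments$start)) stop("CDS segment with end < start")
  if (nrow(segments) > 1 &&
      any(segments$start[-1] <= segments$end[-nrow(segments)]))
    stop("CDS segments overlap")
  len <- sum(segments$end - segments$start + 1)
  if (len %% 3 != 0) stop("CDS length ", len, " not divisible by 3")
  if (!is.null(cds_seq) && nchar(cds_seq) != len)
    stop("cds_seq length does not match CDS segments")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 segments = segments, cds_seq = cds_seq,
                 start = min(segments$start), end = max(segments$end)),
            class = "gene_model")
}

.NONSTOP_CODONS <- setdiff(
  c(t(outer(c("A", "C", "G", "T"),
            c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))),
            paste0))),
  c("TAA", "TAG", "TGA"))

.random_cds <- function(n_codons) {
  paste0("ATG", paste(sample(.NONSTOP_CODONS, n_codons - 1L, replace = TRUE),
                      collapse = ""))
}

#' Simulate gene annotation, planted variants, and expression
#'
#' Plants a realistic candidate-region annotation around the causal locus:
#' non-overlapping strand-labelled gene models, one candidate gene whose CDS
#' carries the causal A>C substitution as the region's only non-synonymous
#' coding SNP (a CAA glutamine codon mutated at its second base to CCA,
#' proline), a small set of regulatory-flank and intergenic SNPs, and an
#' expression table with planted differentially expressed genes
#' (|log2 fold change| > 1) that include the candidate.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @param seed Seed (defaults to the spec's).
#' @param region 1-based inclusive (start, end) interval to annotate on the
#'   causal chromosome; default a 1.42-Mb interval centred on the causal locus.
#' @param n_genes Genes planted inside the region.
#' @param n_intergenic,n_regulatory Number of planted intergenic and
#'   regulatory-flank SNPs.
#' @param n_region_degs Differentially expressed genes inside the region
#'   (including the candidate).
#' @param n_background_genes,n_background_degs Genes outside the region that
#'   appear only in the expression table, and how many of them are DEGs.
#' @param candidate_cds_bp CDS length of the candidate gene (divisible by 3).
#' @param gff,cds_fasta,expr,truth Optional output paths (GFF3, FASTA of CDS,
#'   expression TSV, truth TSV).
#' @return List with \code{genes} (list of \code{gene_model}), \code{snps}
#'   (planted SNP table with true classes), \code{expression},
#'   \code{region}, \code{chrom}, and \code{candidate_gene}.
#' @export
simulate_annotation_and_expression <- function(spec, seed = spec$seed,
    region = NULL, n_genes = 141, n_intergenic = 24, n_regulatory = 2,
    n_region_degs = 13, n_background_genes = 300, n_background_degs = 100,
    candidate_cds_bp = 1338,
    gff = NULL, cds_fasta = NULL, expr = NULL, truth = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  if (candidate_cds_bp %% 3 != 0 || candidate_cds_bp < 993)
    stop("candidate_cds_bp must be a multiple of 3 covering codon 331")
  chrom <- spec$causal_chrom
  if (is.null(region)) {
    half <- 710935
    region <- c(max(1, spec$causal_pos - half),
                min(spec$chrom_lengths[[chrom]], spec$causal_pos + half))
  }
  slot <- floor((region[2] - region[1] + 1) / n_genes)
  if (slot < 4500)
    stop("region too small for ", n_genes, " genes (slot width ", slot, " bp)")
  set.seed(seed)

  slot_starts <- region[1] + (seq_len(n_genes) - 1L) * slot
  causal_slot <- findInterval(spec$causal_pos, slot_starts)
  if (causal_slot < 1 || causal_slot > n_genes)
    stop("causal locus outside annotated region")

  genes <- vector("list", n_genes)
  ids <- sprintf("G%03d", seq_len(n_genes))
  margin <- 1200
  for (i in seq_len(n_genes)) {
    if (i == causal_slot) {
      start <- spec$causal_pos - 991
      segs <- data.frame(start = start, end = start + candidate_cds_bp - 1)
      cds <- .random_cds(candidate_cds_bp / 3)
      substr(cds, 991, 993) <- "CAA"  # Gln codon hit by the causal A>C
      genes[[i]] <- gene_model(ids[i], chrom, "+", segs, cds)
      next
    }
    n_cod <- sample(100:500, 1L)
    strand <- sample(c("+", "-"), 1L)
    two_exon <- stats::runif(1) < 0.1
    span <- n_cod * 3L + if (two_exon) 200L else 0L
    off <- sample(margin:(slot - span - margin), 1L)
    start <- slot_starts[i] + off
    segs <- if (two_exon) {
      cut <- 3L * sample.int(n_cod - 1L, 1L)
      data.frame(start = c(start, start + cut + 200L),
                 end = c(start + cut - 1L, start + n_cod * 3L + 199L))
    } else data.frame(start = start, end = start + n_cod * 3L - 1L)
    genes[[i]] <- gene_model(ids[i], chrom, strand, segs, .random_cds(n_cod))
  }
  spans <- data.frame(start = vapply(genes, `[[`, 0, "start"),
                      end = vapply(genes, `[[`, 0, "end"))

  # planted SNPs: the causal non-synonymous one, regulatory-flank ones beside
  # the candidate's neighbours, and intergenic ones at slot boundaries
  bases <- c("A", "C", "G", "T")
  rand_snp <- function(pos) {
    ref <- sample(bases, 1L)
    data.frame(chrom = chrom, pos = pos, ref = ref,
               alt = sample(setdiff(bases, ref), 1L), stringsAsFactors = FALSE)
  }
  snps <- data.frame(chrom = chrom, pos = spec$causal_pos, ref = "A", alt = "C",
                     class = "coding_nonsynonymous",
                     gene_id = ids[causal_slot], stringsAsFactors = FALSE)
  reg_targets <- setdiff(c(causal_slot - 1L, causal_slot + 1L,
                           causal_slot - 2L, causal_slot + 2L),
                         c(0L, n_genes + 1L))[seq_len(n_regulatory)]
  for (g in reg_targets) {
    before <- stats::runif(1) < 0.5
    pos <- if (before) genes[[g]]$start - sample(200:900, 1L)
           else genes[[g]]$end + sample(200:900, 1L)
    cls <- if (xor(before, genes[[g]]$strand == "-")) "upstream" else "downstream"
    snps <- rbind(snps, cbind(rand_snp(pos), class = cls, gene_id = ids[g]))
  }
  ig_slots <- setdiff(seq_len(n_genes),
                      c(causal_slot, causal_slot + 1L, reg_targets, reg_targets + 1L))
  ig_slots <- sample(ig_slots[ig_slots > 1], n_intergenic)
  for (s in ig_slots) {
    pos <- slot_starts[s] + sample(-100:100, 1L)
    snps <- rbind(snps, cbind(rand_snp(pos), class = "intergenic", gene_id = NA))
  }
  snps <- snps[order(snps$pos), ]
  rownames(snps) <- NULL

  # expression: candidate strongly up in the mutant; one regulatory-SNP gene
  # silent, one unchanged; remaining planted DEGs split across the region and
  # the genome-wide background
  lfc <- stats::runif(n_genes, -0.9, 0.9)
  detected <- rep(TRUE, n_genes)
  lfc[causal_slot] <- 2.8
  if (length(reg_targets) >= 1) { detected[reg_targets[1]] <- FALSE; lfc[reg_targets[1]] <- NA }
  if (length(reg_targets) >= 2) lfc[reg_targets[2]] <- 0.3
  pool <- setdiff(seq_len(n_genes), c(causal_slot, reg_targets))
  extra <- sample(pool, n_region_degs - 1L)
  lfc[extra] <- sample(c(-1, 1), length(extra), TRUE) * stats::runif(length(extra), 1.2, 3)
  bg_ids <- sprintf("B%03d", seq_len(n_background_genes))
  bg_lfc <- stats::runif(n_background_genes, -0.9, 0.9)
  bg_deg <- sample(n_background_genes, n_background_degs)
  bg_lfc[bg_deg] <- sample(c(-1, 1), n_background_degs, TRUE) *
    stats::runif(n_background_degs, 1.2, 4)
  expression <- data.frame(
    gene_id = c(ids, bg_ids), log2fc = c(lfc, bg_lfc),
    detected = c(detected, rep(TRUE, n_background_genes)),
    stringsAsFactors = FALSE)

  res <- list(genes = genes, snps = snps, expression = expression,
              region = c(start = region[1], end = region[2]), chrom = chrom,
              candidate_gene = ids[causal_slot])

  if (!is.null(gff)) write_gff3(genes, gff, spec$chrom_lengths)
  if (!is.null(cds_fasta)) {
    seqs <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "cds_seq"))
    names(seqs) <- ids
    Biostrings::writeXStringSet(seqs, cds_fasta)
  }
  if (!is.null(expr))
    utils::write.table(expression, expr, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    con <- file(truth, "w")
    writeLines(sprintf("# candidate_gene\t%s", res$candidate_gene), con)
    utils::write.table(snps, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  res
}
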