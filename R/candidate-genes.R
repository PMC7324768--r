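.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("ambiguous base in codon ", codon)
  aa
}

# 1-based CDS offset (transcript orientation) of a genomic position within a
# gene model's CDS segments, or NA when the position is not coding
.cds_offset <- function(gene, pos) {
  segs <- gene$segments
  hit <- which(pos >= segs$start & pos <= segs$end)
  if (length(hit) == 0) return(NA_integer_)
  plus_off <- if (hit > 1) sum(segs$end[seq_len(hit - 1)] - segs$start[seq_len(hit - 1)] + 1) else 0L
  plus_off <- plus_off + (pos - segs$start[hit] + 1)
  if (gene$strand == "+") plus_off
  else sum(segs$end - segs$start + 1) - plus_off + 1L
}

#' Classify the consequence of a SNP against gene models
#'
#' A coding SNP is translated strand-aware with the standard genetic code:
#' reference and mutated codons are compared, giving a synonymous or
#' non-synonymous call with the affected residue index (ceiling of the CDS
#' offset over 3). A SNP within \code{flank} bp of a gene but outside every
#' CDS is regulatory (upstream or downstream relative to the gene's strand);
#' anything else is intergenic. When a SNP is coding in one gene and in the
#' flank of another, the coding (more severe) call wins.
#'
#' @param pos SNP position (1-based).
#' @param ref,alt Reference and alternate bases on the plus strand.
#' @param genes List of \code{\link{gene_model}} objects.
#' @param chrom Chromosome of the SNP; gene models on other chromosomes are
#'   ignored (ignored if NULL).
#' @param flank Regulatory flank in bp.
#' @return List: class (one of intergenic, upstream, downstream,
#'   coding_synonymous, coding_nonsynonymous), gene_id, codon_index, aa_ref,
#'   aa_alt.
#' @examples
#' g <- gene_model("g1", "chr1", "+", data.frame(start = 101, end = 109),
#'                 cds_seq = "ATGCAACTA")
#' classify_snp_effect(105, "A", "C", list(g))$aa_alt
#' @export
classify_snp_effect <- function(pos, ref, alt, genes, chrom = NULL,
                                flank = 1000) {
  if (pos < 1) stop("pos must be >= 1")
  if (!ref %in% names(.COMPLEMENT) || !alt %in% names(.COMPLEMENT))
    stop("ambiguous base: ref/alt must be one of A, C, G, T")
  if (!is.null(chrom))
    genes <- Filter(function(g) g$chrom == chrom, genes)
  none <- list(class = "intergenic", gene_id = NA_character_,
               codon_index = NA_integer_, aa_ref = NA_character_,
               aa_alt = NA_character_)
  for (g in genes) {
    off <- .cds_offset(g, pos)
    if (is.na(off)) next
    if (is.null(g$cds_seq))
      stop("SNP at ", pos, " is coding in ", g$gene_id,
           " but its CDS sequence is missing")
    ref_t <- if (g$strand == "+") ref else .COMPLEMENT[[ref]]
    alt_t <- if (g$strand == "+") alt else .COMPLEMENT[[alt]]
    if (substr(g$cds_seq, off, off) != ref_t)
      stop("reference base mismatch at CDS offset ", off, " of ", g$gene_id)
    ci <- ceiling(off / 3)
    codon <- substr(g$cds_seq, 3 * ci - 2, 3 * ci)
    mut <- codon
    substr(mut, off - 3 * (ci - 1), off - 3 * (ci - 1)) <- alt_t
    aa_r <- .translate_codon(codon)
    aa_a <- .translate_codon(mut)
    return(list(
      class = if (aa_r == aa_a) "coding_synonymous" else "coding_nonsynonymous",
      gene_id = g$gene_id, codon_index = ci, aa_ref = aa_r, aa_alt = aa_a))
  }
  # regulatory: nearest gene whose flank covers the position
  best <- NULL; best_d <- Inf
  for (g in genes) {
    if (pos >= g$start && pos <= g$end) next  # intronic/UTR-less span: skip
    d <- if (pos < g$start) g$start - pos else pos - g$end
    if (d <= flank && d < best_d) { best <- g; best_d <- d }
  }
  if (is.null(best)) return(none)
  before <- pos < best$start
  cls <- if (xor(before, best$strand == "-")) "upstream" else "downstream"
  list(class = cls, gene_id = best$gene_id, codon_index = NA_integer_,
       aa_ref = NA_character_, aa_alt = NA_character_)
}

#' Classify many SNPs
#'
#' @param snps data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @inheritParams classify_snp_effect
#' @return data.frame of effects, one row per SNP.
#' @export
classify_snps <- function(snps, genes, flank = 1000) {
  eff <- lapply(seq_len(nrow(snps)), function(i)
    classify_snp_effect(snps$pos[i], snps$ref[i], snps$alt[i], genes,
                        chrom = snps$chrom[i], flank = flank))
  cbind(snps[c("chrom", "pos", "ref", "alt")],
        do.call(rbind, lapply(eff, function(e)
          data.frame(class = e$class, gene_id = e$gene_id,
                     codon_index = e$codon_index, aa_ref = e$aa_ref,
                     aa_alt = e$aa_alt, stringsAsFactors = FALSE))))
}

#' Protein length from a CDS
#'
#' Length in residues is CDS length over 3; when the sequence itself is given
#' and ends in a stop codon, the stop is trimmed from the residue count.
#'
#' @param cds_bp CDS length in bp (used when \code{cds_seq} is NULL).
#' @param cds_seq Optional CDS sequence.
#' @return Residue count.
#' @examples
#' protein_length(1338)
#' protein_length(cds_seq = "ATGAAATAA")
#' @export
protein_length <- function(cds_bp = NULL, cds_seq = NULL) {
  if (!is.null(cds_seq)) {
    cds_bp <- nchar(cds_seq)
    if (cds_bp %% 3 != 0) stop("CDS length not divisible by 3")
    last <- substr(cds_seq, cds_bp - 2, cds_bp)
    n <- cds_bp / 3
    return(if (.translate_codon(last) == "*") n - 1 else n)
  }
  if (cds_bp %% 3 != 0) stop("CDS length not divisible by 3")
  cds_bp / 3
}

#' Filter differentially expressed genes
#'
#' A gene is a DEG when it is detected and |log2 fold change| strictly exceeds
#' the threshold; the result is split by sign.
#'
#' @param expression data.frame: gene_id, log2fc, detected.
#' @param threshold log2 fold-change threshold (strict).
#' @return data.frame of DEGs with a \code{direction} ("up"/"down") column.
#' @export
deg_filter <- function(expression, threshold = 1) {
  keep <- expression$detected & !is.na(expression$log2fc) &
    abs(expression$log2fc) > threshold
  out <- expression[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Rank candidate genes in a region
#'
#' Genes overlapping the candidate region are scored by the joint evidence of
#' variant consequence and differential expression: rank 1 = DEG carrying a
#' non-synonymous coding SNP; rank 2 = DEG with a regulatory-flank SNP;
#' rank 3 = DEG without a SNP; rank 4 = SNP-bearing non-DEG; rank 5 =
#' everything else. Ties are broken by |log2 fold change| (descending), then
#' position.
#'
#' @param region Numeric (start, end) on \code{chrom}.
#' @param chrom Chromosome of the region.
#' @param genes List of \code{\link{gene_model}} objects.
#' @param effects Effect table from \code{\link{classify_snps}}.
#' @param expression Expression table (gene_id, log2fc, detected).
#' @param threshold DEG threshold passed to \code{\link{deg_filter}}.
#' @return data.frame of region genes sorted by rank: gene_id, start, end,
#'   rank, log2fc, deg, snp_class.
#' @export
prioritize_candidates <- function(region, chrom, genes, effects, expression,
                                  threshold = 1) {
  if (region[2] < region[1]) stop("invalid region")
  inreg <- Filter(function(g) g$chrom == chrom && g$end >= region[1] &&
                    g$start <= region[2], genes)
  if (length(inreg) == 0)
    return(data.frame(gene_id = character(), start = numeric(),
                      end = numeric(), rank = integer(), log2fc = numeric(),
                      deg = logical(), snp_class = character()))
  degs <- deg_filter(expression, threshold)
  lfc <- stats::setNames(expression$log2fc, expression$gene_id)
  sev <- function(gid) {
    cl <- effects$class[!is.na(effects$gene_id) & effects$gene_id == gid]
    if ("coding_nonsynonymous" %in% cl) "coding_nonsynonymous"
    else if ("coding_synonymous" %in% cl) "coding_synonymous"
    else if (any(cl %in% c("upstream", "downstream"))) "regulatory"
    else NA_character_
  }
  rows <- lapply(inreg, function(g) {
    cls <- sev(g$gene_id)
    is_deg <- g$gene_id %in% degs$gene_id
    rank <- if (is_deg && identical(cls, "coding_nonsynonymous")) 1L
      else if (is_deg && identical(cls, "regulatory")) 2L
      else if (is_deg) 3L
      else if (!is.na(cls)) 4L
      else 5L
    data.frame(gene_id = g$gene_id, start = g$start, end = g$end, rank = rank,
               log2fc = unname(lfc[g$gene_id])[1], deg = is_deg,
               snp_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key_lfc <- ifelse(is.na(out$log2fc), -Inf, abs(out$log2fc))
  out <- out[order(out$rank, -key_lfc, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in the
#'   test sample.
#' @param ct_target_control,ct_ref_control Same in the control sample.
#' @return Relative expression 2^-[(Ct_t,test - Ct_r,test) -
#'   (Ct_t,control - Ct_r,control)].
#' @examples
#' ddct(20, 18, 22, 20)  # ddCt = 0 -> 1
#' @export
ddct <- function(ct_target_test, ct_ref_test, ct_target_control,
                 ct_ref_control) {
  vals <- c(ct_target_test, ct_ref_test, ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  2^-((ct_target_test - ct_ref_test) - (ct_target_control - ct_ref_control))
}
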