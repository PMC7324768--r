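#' Genome and cross specification
#'
#' Describes the simulated haploid x haploid cross: chromosome lengths, the
#' number of parent-differentiating markers, the planted causal locus for the
#' red-coloration phenotype, and the recombination rate used by the meiosis
#' model.
#'
#' Defaults mirror a three-chromosome red-algal genome of roughly 108 Mb with
#' 20,000 fixed parental differences and a single causal locus near the distal
#' end of chromosome 1. The recombination rate default of 4.37 cM/Mb gives a
#' total map length of 472.45 cM over the default genome.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_markers Total number of biallelic markers, apportioned to
#'   chromosomes proportionally to their length. The causal locus is always
#'   included as a marker.
#' @param causal_chrom,causal_pos Chromosome and 1-based position of the
#'   planted causal locus.
#' @param recomb_rate Recombination rate in cM/Mb (Haldane model, no
#'   interference).
#' @param seed Integer seed from which all downstream randomness flows.
#' @return An object of class \code{"genome_spec"}.
#' @examples
#' spec <- genome_spec(n_markers = 500)
#' spec$causal_pos
#' @export
genome_spec <- function(chrom_lengths = c(chr1 = 45e6, chr2 = 35e6, chr3 = 28e6),
                        n_markers = 20000,
                        causal_chrom = "chr1",
                        causal_pos = 41500000,
                        recomb_rate = 4.37,
                        seed = 1L) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must be uniquely named")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1 bp")
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (!causal_chrom %in% names(chrom_lengths))
    stop("causal_chrom '", causal_chrom, "' is not a simulated chromosome")
  if (causal_pos < 1 || causal_pos > chrom_lengths[[causal_chrom]])
    stop("causal_pos lies outside chromosome ", causal_chrom)
  if (recomb_rate < 0) stop("recomb_rate must be non-negative")
  structure(list(
    chrom_lengths = chrom_lengths,
    n_markers = as.integer(n_markers),
    causal_chrom = causal_chrom,
    causal_pos = as.numeric(causal_pos),
    recomb_rate = recomb_rate,
    seed = as.integer(seed)
  ), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Haploid cross genome specification\n")
  cat("  chromosomes:", paste0(names(x$chrom_lengths), " (",
      format(x$chrom_lengths / 1e6, trim = TRUE), " Mb)", collapse = ", "), "\n")
  cat("  markers:", x$n_markers, "\n")
  cat("  causal locus:", x$causal_chrom, "at", format(x$causal_pos, big.mark = ","), "\n")
  cat("  recombination:", x$recomb_rate, "cM/Mb; seed:", x$seed, "\n")
  invisible(x)
}
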