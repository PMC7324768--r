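---
title: "Methods: simulated bulked-segregant mapping in a haploid cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated bulked-segregant mapping in a haploid cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

# Scope

`tetramap` re-implements, with a fully synthetic data generator, the
analysis chain used to map a monogenic color locus in a haploid alga:
Δ(SNP-index) QTL-seq with simulated confidence intervals, a single-marker
LOD confirmation scan, recombinant-based interval narrowing, and
candidate-gene prioritization. This vignette records the models, the
defaults and why they were chosen, the numerical conventions, and what the
simulations do and do not show about real data.

# The meiosis and population model

A heterozygous diploid phase is meiosed into **ordered tetrads**. Per
chromosome, crossover events on the four-chromatid bivalent form a Poisson
process with rate 2 per Morgan; each of two tracked chromatids participates
in any event independently with probability ½, and the remaining two
products are their parental-origin complements. Consequences:

* every marker segregates exactly 2:2 in every tetrad (asserted, not
  approximate);
* each single product accumulates switch points at rate 1 per Morgan, so the
  recombinant fraction between two markers follows Haldane's map function
  r = ½(1 − e^(−2d)) with no interference;
* chromosomes assort independently (phase is drawn per chromosome), so the
  "zero recombination gives parental products" limit holds per chromosome,
  as it must biologically.

Chiasma interference and chromatid interference are not modelled; nothing
downstream depends on either.

Each tetrad founds one chimeric blade carrying 1–4 single-genotype sectors
(a random subset of the four products). The sector-count distribution
defaults to (0.1, 0.3, 0.3, 0.3): the source experiment reports only that
sectored blades outnumber unsectored ones, so the mass is spread evenly over
2–4 sectors with a small unsectored remainder; it is configurable because
the real distribution is not published. Phenotype is deterministic from the
allele at the planted causal locus (mutant allele ⇒ red type), which is what
"single nuclear locus, 1:1 segregation" means in a haploid.

## Genome defaults

Three chromosomes of 45, 35 and 28 Mb (the first must exceed the ~43.6 Mb
coordinates the published tables use), 20,000 fixed parental differences
apportioned by length, causal locus at chr1:41.5 Mb, and 4.37 cM/Mb — chosen
so the total map length is 472.45 cM over the simulated 108-Mb genome,
matching the published genetic map total. The same factor converts physical
to genetic distance wherever explicit cM positions are absent (it only
affects the <10 cM peak-merge rule).

## Sequencing model

Pooled sequencing is modelled at the allele-frequency level: per marker and
pool, depth ~ Poisson(mean 100) and mutant-allele reads ~ Binomial(depth,
bulk allele frequency). Read-level artefacts (sequencing error, mapping
bias, InDels) are not simulated; the filtering stage treats records
generically, so real VCFs with such artefacts pass through the same
interfaces. The 100× default is a desk-scale stand-in for the far deeper
coverage of the original pools; the confidence-interval machinery is keyed
by observed depth, so nothing assumes this value.

# The Δ(SNP-index) scan

The SNP-index numerator counts reads carrying the **mutant-parent
(alternate) allele**; the published description of which parent was counted
is ambiguous, and this orientation is the one under which the causal locus
drives Δ = index(RT) − index(WT) to +1 (the magnitude of Δ is unaffected).
Significance is accordingly one-sided against the upper bound; the lower
band is retained for plotting.

Null confidence intervals are empirical quantiles of Δ simulated under no
QTL: bulk allele count ~ Binomial(n, ½), then reads ~ Binomial(depth,
count/n), 10,000 replicates by default, computed once per observed
(depth_RT, depth_WT) pair and shared within a scan. Windows are 1 Mb sliding
by 100 kb, anchored at position 1 (the published region endpoints of the
form x00,001–y00,000 confirm that grid); a window's statistic and its bounds
are arithmetic means over member SNPs, windows with fewer than 3 SNPs are
reported missing, and overlapping or abutting significant windows merge with
no gap tolerance. Coordinates are 1-based inclusive everywhere in memory and
TSV; BED output converts to 0-based half-open at the boundary.

Two caveats the simulations make visible. First, bulk composition drifts at
genome scale: a 24-sector bulk's allele frequency wanders far from ½ over
tens of cM, so single scans produce occasional multi-window false regions —
the published experiment shows the same behaviour (three of four regions in
its smaller bulk pair lie away from the locus) and the remedy is the same:
intersect independent bulk pairs. A per-run bound on the fraction of
significant null windows is therefore meaningless; only its average over
many runs (~3% observed, nominal 2.5%) is stable. Second, with ~4.4 cM/Mb
and bulks of 24–56, the region around a true locus that exceeds the bound
is broad (tens of Mb); the scan localizes, the later stages narrow.

# Variant filtering

Defaults follow the published pipeline: per-pool depth in [4, 1000]
(enforced on both progeny bulks, since the source does not say which pool
its bound applied to), mapping quality ≥ 20, and adjacent-site distance
≥ 5 bp. The adjacency rule removes **both** members of any closer pair,
assessed on the full input set — symmetric, order-independent, and
idempotent. Removal counts partition removed records by first failing rule
(depth, then MQ, then adjacency). A parental difference requires the haploid
mutant parent's pool to be ≥ 90% alternate reads (1.0 would be brittle to
any contamination or error; configurable) with nonzero coverage in both
bulks. Multiallelic records are rejected at parse time.

# LOD confirmation and narrowing

The confirmation scan is a deliberate re-implementation, not a wrapper
around interval-mapping software: for a fully penetrant binary trait in a
haploid population, single-marker linkage is a binomial likelihood, and
LOD = log₁₀[θ̂ʳ(1−θ̂)ⁿ⁻ʳ/0.5ⁿ] with θ̂ = r/n (0⁰ ≡ 1; missing genotypes drop
out of both r and n). The genome-wide threshold is the 95th percentile of
the maximum LOD over 1,000 phenotype permutations; contiguous
above-threshold runs form QTLs, peaks closer than 10 cM merge keeping the
higher, and support intervals are contiguous markers within 1.5 LOD of the
peak. Markers are pre-screened (missing ≤ 0.2, MAF ≥ 0.05) and clustered
into bins by exact equality of genotype vectors, missing treated as its own
symbol, the leftmost member representing the bin. Exact-equality binning
presumes essentially complete calls — independent random missingness makes
every column unique — so the pipeline's mapping panel is simulated without
missing calls and the screening filters are exercised separately.

Recombinant narrowing assumes the locus lies in the cosegregating core:
a sample is recombinant at a marker when its allele contradicts its
phenotype, each boundary moves inward to the innermost marker with at least
one recombinant, boundary markers are closed endpoints (the published
narrowed interval starts *at* its recombinant marker), and sides without
recombinant markers keep the prior boundary. The published interval's
printed length (1.42 Mb) corresponds to end − start; the package's inclusive
convention adds 1 bp — both agree at the printed precision, and the
inclusive convention is used consistently because it reproduces the
region-table totals exactly.

# Candidate genes

SNP consequences are classified against strand-aware CDS segments using the
standard genetic code (the locus is nuclear): reference and mutated codons
are translated, residue index = ⌈CDS offset / 3⌉; within 1,000 bp of a gene
but outside its CDS is upstream/downstream relative to strand (a common
annotation-tool convention; the source says only "up/down regulatory
region"); a SNP coding in one gene and flanking another takes the more
severe coding call. DEGs require detection and |log₂FC| strictly > 1;
undetected genes are never DEGs. Ranking: non-synonymous DEG, regulatory
DEG, DEG, SNP-bearing non-DEG, rest; ties by |log₂FC| then position.
`protein_length()` divides by 3 and trims one terminal stop only when an
actual sequence ends in one — the published 1,338-bp CDS ↦ 446 residues is
the length-only call, leaving the stop-inclusion convention to the data.

The generator plants exactly one non-synonymous SNP in the candidate region:
a CAA glutamine codon at residue 331 of a 1,338-bp single-exon CDS, mutated
A→C at its second base to CCA (proline), with two regulatory-flank SNPs on
neighbouring genes (one silent, one expression-unchanged — mirroring how
real neighbours were excluded), 24 intergenic SNPs, and 13 region DEGs among
141 region genes plus a 300-gene expression background.

# Problem sizes and reproducibility

Every simulation flows from one integer seed; pipeline stages derive fixed
offsets from it, runs are byte-reproducible, and the JSON run log records
seeds, thresholds and per-stage counts. The test suite checks stochastic
properties at sizes chosen to make Monte Carlo error negligible relative to
the asserted margins: 10,000 tetrads for the Haldane check (3 SE), 10,000
fresh draws for CI coverage (±1%), 50 simulated crosses each for
planted-locus recovery and end-to-end candidate recovery (≥ 90%), and 12
null scans for the false-window average. The acceptance script uses 25-run
recovery batches. A deliberate limitation throughout: synthetic data cannot
validate behaviour under alignment artefacts, reference bias, segmental
duplication, or distorted segregation — passing tests demonstrate the
statistics and bookkeeping, not robustness to upstream calling errors.
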