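#' Simulate the parental marker table
#'
#' Generates the fixed biallelic differences between the two haploid parents:
#' the wild-type maternal strain carries the reference allele at every site and
#' the red-mutant paternal strain the alternate allele. Marker positions are
#' drawn uniformly per chromosome (count proportional to chromosome length) and
#' the causal locus is always included as a marker with an A>C substitution.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @return A data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{is_causal}, sorted by (chrom, pos), with the spec
#'   attached as attribute \code{"spec"}.
#' @examples
#' p <- simulate_parents(genome_spec(n_markers = 100))
#' nrow(p)
#' @export
simulate_parents <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  if (spec$n_markers < 1) stop("spec requests zero markers")
  set.seed(spec$seed)
  lens <- spec$chrom_lengths
  n_per <- round(spec$n_markers * lens / sum(lens))
  n_per[n_per < 1] <- 1
  bases <- c("A", "C", "G", "T")
  out <- lapply(names(lens), function(ch) {
    n <- n_per[[ch]]
    pos <- sort(sample.int(lens[[ch]], n))
    if (ch == spec$causal_chrom && !spec$causal_pos %in% pos)
      pos <- sort(c(pos, spec$causal_pos))
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    df <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                     is_causal = FALSE, stringsAsFactors = FALSE)
    if (ch == spec$causal_chrom) {
      i <- match(spec$causal_pos, df$pos)
      df$is_causal[i] <- TRUE
      df$ref[i] <- "A"
      df$alt[i] <- "C"
    }
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

# Haldane meiosis for one chromosome: bivalent crossover events occur as a
# Poisson process with rate 2 per Morgan; each of the two tracked chromatids
# participates in an event independently with probability 1/2, so each product
# accumulates switch points at rate 1/Morgan and the recombinant fraction
# between two markers follows Haldane's map function. Products 3 and 4 are the
# parental-origin complements of products 1 and 2, which enforces exact 2:2
# segregation at every marker.
.meiose_chrom <- function(mpos, chrom_len, rate_cm_per_mb) {
  d_morgan <- rate_cm_per_mb * chrom_len / 1e6 / 100
  n_ev <- stats::rpois(1L, 2 * d_morgan)
  ev <- sort(stats::runif(n_ev, 0, chrom_len))
  in1 <- stats::runif(n_ev) < 0.5
  in2 <- stats::runif(n_ev) < 0.5
  phase <- sample(0:1, 1L)
  par1 <- findInterval(mpos, ev[in1]) %% 2L
  par2 <- findInterval(mpos, ev[in2]) %% 2L
  g1 <- (phase + par1) %% 2L
  g2 <- (phase + par2) %% 2L
  list(geno = rbind(g1, g2, 1L - g1, 1L - g2),
       breakpoints = list(product1 = ev[in1], product2 = ev[in2]))
}

#' Simulate one ordered tetrad
#'
#' Performs one meiosis of the heterozygous diploid phase and returns the four
#' ordered haploid products. Crossovers follow a Poisson (Haldane, no
#' interference) model; products 1-2 and 3-4 are the two sister pairs. At every
#' marker exactly two products carry the maternal (reference) allele and two
#' the paternal (alternate) allele.
#'
#' @param parents Marker table from \code{\link{simulate_parents}}.
#' @param recomb_rate Recombination rate in cM/Mb; defaults to the rate in the
#'   spec attached to \code{parents}.
#' @param seed Optional seed; when \code{NULL} the current RNG stream is used.
#' @return A list of class \code{"tetrad"} with \code{genotypes} (4 x markers
#'   integer matrix, 0 = maternal/reference, 1 = paternal/alternate) and
#'   \code{breakpoints} (per chromosome, per tracked product).
#' @export
simulate_tetrad <- function(parents, recomb_rate = NULL, seed = NULL) {
  spec <- attr(parents, "spec")
  if (is.null(recomb_rate)) recomb_rate <- spec$recomb_rate
  if (recomb_rate < 0) stop("recomb_rate must be non-negative")
  if (nrow(parents) < 1) stop("parents table has no markers")
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(parents$chrom)
  geno <- matrix(0L, 4L, nrow(parents))
  bps <- vector("list", length(chroms))
  names(bps) <- chroms
  for (ch in chroms) {
    idx <- which(parents$chrom == ch)
    res <- .meiose_chrom(parents$pos[idx], spec$chrom_lengths[[ch]], recomb_rate)
    geno[, idx] <- res$geno
    bps[[ch]] <- res$breakpoints
  }
  structure(list(genotypes = geno, breakpoints = bps), class = "tetrad")
}

#' Simulate many ordered tetrads
#'
#' @inheritParams simulate_tetrad
#' @param n Number of meioses.
#' @param seed Seed for the whole batch.
#' @return A list of \code{"tetrad"} objects.
#' @export
simulate_tetrads <- function(parents, n, recomb_rate = NULL, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) simulate_tetrad(parents, recomb_rate))
}

#' Assemble a chimeric-blade population of single-genotype sectors
#'
#' Each tetrad develops into one blade carrying 1-4 single-genotype sectors
#' (a subset of the tetrad's four ordered products). The phenotype of a sector
#' is determined by its allele at the planted causal locus: the paternal
#' (alternate) allele gives the red-type (RT) phenotype, the maternal allele
#' the wild type (WT).
#'
#' @param tetrads List of tetrads from \code{\link{simulate_tetrads}}.
#' @param parents Marker table the tetrads were simulated from.
#' @param sector_dist Probabilities of a blade carrying 1, 2, 3 or 4 sectors;
#'   must sum to 1.
#' @param seed Seed.
#' @return A list of class \code{"sector_population"} with \code{samples}
#'   (data.frame: sample_id, blade_id, sectors_in_blade, phenotype) and
#'   \code{genotypes} (samples x markers integer matrix).
#' @export
assemble_population <- function(tetrads, parents,
                                sector_dist = c(0.1, 0.3, 0.3, 0.3),
                                seed = 1L) {
  if (length(tetrads) == 0) stop("empty tetrad list")
  if (length(sector_dist) != 4 || abs(sum(sector_dist) - 1) > 1e-8)
    stop("sector_dist must be 4 probabilities summing to 1")
  causal <- which(parents$is_causal)
  if (length(causal) != 1) stop("parents table must contain one causal marker")
  set.seed(seed)
  n_blades <- length(tetrads)
  ks <- sample(1:4, n_blades, replace = TRUE, prob = sector_dist)
  rows <- list(); meta <- list()
  sid <- 0L
  for (b in seq_len(n_blades)) {
    prods <- sort(sample.int(4L, ks[b]))
    for (p in prods) {
      sid <- sid + 1L
      g <- tetrads[[b]]$genotypes[p, ]
      rows[[sid]] <- g
      meta[[sid]] <- data.frame(
        sample_id = sprintf("F1-%04d", sid), blade_id = sprintf("B%04d", b),
        sectors_in_blade = ks[b],
        phenotype = if (g[causal] == 1L) "RT" else "WT",
        stringsAsFactors = FALSE)
    }
  }
  geno <- do.call(rbind, rows)
  samples <- do.call(rbind, meta)
  rownames(geno) <- samples$sample_id
  structure(list(samples = samples, genotypes = geno, parents = parents),
            class = "sector_population")
}

#' @export
print.sector_population <- function(x, ...) {
  tab <- table(x$samples$phenotype)
  cat("Sector population:", nrow(x$samples), "sectors on",
      length(unique(x$samples$blade_id)), "blades (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Pool sectors into phenotype bulks and sample sequencing depths
#'
#' Draws two phenotype bulks (red-type and wild-type) of the requested sizes
#' from the population and simulates pooled resequencing: per marker and pool,
#' total depth is Poisson with the given mean and the number of reads carrying
#' the paternal (alternate) allele is binomial in the bulk's true allele
#' frequency. The paternal parent is included as its own pool (allele
#' frequency 1).
#'
#' @param pop A \code{sector_population}.
#' @param n_rt,n_wt Number of sectors pooled per bulk.
#' @param mean_depth Mean sequencing depth per pool (Poisson).
#' @param seed Seed.
#' @param pool_names Names for the parent, red-type and wild-type pools.
#' @param vcf Optional path: write the pooled counts as a VCF 4.2 file with
#'   per-pool AD and DP fields.
#' @param truth Optional path: write a TSV recording the causal locus and every
#'   pooled sample's phenotype and causal-locus allele.
#' @return A data.frame of class \code{"bulk_counts"}: marker columns plus
#'   \code{<pool>.alt} / \code{<pool>.dp} count columns; bulk sizes and member
#'   ids attached as attributes.
#' @export
build_bulks <- function(pop, n_rt, n_wt, mean_depth = 100, seed = 1L,
                        pool_names = c(parent = "P1", rt = "RT", wt = "WT"),
                        vcf = NULL, truth = NULL) {
  stopifnot(inherits(pop, "sector_population"))
  if (mean_depth <= 0) stop("mean_depth must be positive")
  ph <- pop$samples$phenotype
  if (sum(ph == "RT") < n_rt || sum(ph == "WT") < n_wt)
    stop("not enough sectors of the requested phenotypes (have ",
         sum(ph == "RT"), " RT, ", sum(ph == "WT"), " WT)")
  set.seed(seed)
  rt_ids <- sample(which(ph == "RT"), n_rt)
  wt_ids <- sample(which(ph == "WT"), n_wt)
  m <- nrow(pop$parents)
  freq_rt <- colMeans(pop$genotypes[rt_ids, , drop = FALSE])
  freq_wt <- colMeans(pop$genotypes[wt_ids, , drop = FALSE])

  draw_pool <- function(freq) {
    dp <- stats::rpois(m, mean_depth)
    alt <- stats::rbinom(m, dp, freq)
    list(alt = alt, dp = dp)
  }
  p1 <- draw_pool(rep(1, m)); rt <- draw_pool(freq_rt); wt <- draw_pool(freq_wt)

  out <- pop$parents[c("chrom", "pos", "ref", "alt")]
  names(out)[4] <- "alt_allele"
  out$mq <- 60
  out[[paste0(pool_names[["parent"]], ".alt")]] <- p1$alt
  out[[paste0(pool_names[["parent"]], ".dp")]] <- p1$dp
  out[[paste0(pool_names[["rt"]], ".alt")]] <- rt$alt
  out[[paste0(pool_names[["rt"]], ".dp")]] <- rt$dp
  out[[paste0(pool_names[["wt"]], ".alt")]] <- wt$alt
  out[[paste0(pool_names[["wt"]], ".dp")]] <- wt$dp
  names(out)[names(out) == "alt_allele"] <- "alt"
  attr(out, "bulk_sizes") <- c(rt = n_rt, wt = n_wt)
  attr(out, "members") <- list(rt = pop$samples$sample_id[rt_ids],
                               wt = pop$samples$sample_id[wt_ids])
  attr(out, "spec") <- attr(pop$parents, "spec")
  class(out) <- c("bulk_counts", "data.frame")

  if (!is.null(vcf))
    write_pool_vcf(out, vcf, chrom_lengths = attr(pop$parents, "spec")$chrom_lengths)
  if (!is.null(truth)) {
    spec <- attr(pop$parents, "spec")
    causal <- which(pop$parents$is_causal)
    tr <- data.frame(
      sample_id = pop$samples$sample_id,
      phenotype = pop$samples$phenotype,
      causal_allele = ifelse(pop$genotypes[, causal] == 1L, "HT", "RZ"),
      bulk = ifelse(pop$samples$sample_id %in% attr(out, "members")$rt, "RT",
             ifelse(pop$samples$sample_id %in% attr(out, "members")$wt, "WT", "none")),
      stringsAsFactors = FALSE)
    con <- file(truth, "w")
    writeLines(sprintf("# causal_locus\t%s\t%d", spec$causal_chrom,
                       as.integer(spec$causal_pos)), con)
    utils::write.table(tr, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  out
}
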