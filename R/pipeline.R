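#' Pipeline configuration
#'
#' Collects every threshold, size and seed of the simulate - filter - QTL-seq
#' - fine-map - candidate stages into one validated object. Defaults are the
#' study conditions of the analysis the package models: a three-chromosome
#' genome with 20,000 fixed parental differences, two bulk pairs of 24 and 56
#' sectors at 100x mean depth, 1-Mb/100-kb sliding windows with 10,000-replicate
#' simulated confidence intervals, an 84-sector mapping panel with 1,000
#' permutations, a 320-sample recombinant-screening panel genotyped at 4
#' markers, a 1,000-bp regulatory flank and a |log2FC| > 1 DEG threshold.
#'
#' @param outdir Output directory.
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides for any default listed by \code{pipeline_config()}.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(outdir = tempfile("tetramap_run_"), seed = 1L,
                            ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    chrom_lengths = c(chr1 = 45e6, chr2 = 35e6, chr3 = 28e6),
    n_markers = 20000, causal_chrom = "chr1", causal_pos = 41500000,
    recomb_rate = 4.37,
    n_blades = 120, sector_dist = c(0.1, 0.3, 0.3, 0.3),
    bulk_pairs = list(list(name = "RT24-WT24", n_rt = 24, n_wt = 24),
                      list(name = "RT56-WT56", n_rt = 56, n_wt = 56)),
    mean_depth = 100,
    min_depth = 4, max_depth = 1000, min_mq = 20, min_gap = 5,
    min_parent_alt_frac = 0.9,
    window = 1e6, step = 1e5, ci_reps = 10000, levels = c(95, 99),
    min_snps = 3,
    n_map_samples = 84, n_perm = 1000, lod_alpha = 0.05, merge_cm = 10,
    lod_drop = 1.5, map_missing_rate = 0,
    n_kasp_samples = 320, n_kasp_markers = 4,
    flank = 1000, deg_threshold = 1,
    plots = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$max_depth < cfg$min_depth)
    stop("config invalid: max_depth < min_depth")
  if (cfg$window %% cfg$step != 0)
    stop("config invalid: window must be a multiple of step")
  if (cfg$mean_depth <= 0) stop("config invalid: mean_depth must be positive")
  if (abs(sum(cfg$sector_dist) - 1) > 1e-8)
    stop("config invalid: sector_dist must sum to 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of config fields.
#' @param ... Overrides applied after the file.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$chrom_lengths)) vals$chrom_lengths <- unlist(vals$chrom_lengths)
  if (!is.null(vals$sector_dist)) vals$sector_dist <- unlist(vals$sector_dist)
  if (!is.null(vals$levels)) vals$levels <- unlist(vals$levels)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(pipeline_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full simulated mapping pipeline
#'
#' Simulates the cross and its sequencing, filters pooled variants, runs the
#' delta(SNP-index) scan for every bulk pair, intersects the called regions,
#' checks 1:1 segregation, performs the binned single-marker LOD scan on a
#' mapping panel, narrows the interval with a recombinant-screening panel, and
#' ranks candidate genes in the narrowed region. All outputs (VCF, GFF3,
#' FASTA, TSV, BED, JSON run log) are written under \code{config$outdir}.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a report list: regions per pair, intersected region,
#'   segregation test, LOD scan, narrowing result, ranked candidates, truth,
#'   and per-stage counts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  log <- list(seed = config$seed, stages = list())

  spec <- genome_spec(config$chrom_lengths, config$n_markers,
                      config$causal_chrom, config$causal_pos,
                      config$recomb_rate, seed = config$seed)
  thr <- filter_thresholds(config$min_depth, config$max_depth, config$min_mq,
                           config$min_gap, config$min_parent_alt_frac)

  sim <- .stage("simulate", {
    parents <- simulate_parents(spec)
    tetrads <- simulate_tetrads(parents, config$n_blades, seed = config$seed + 1L)
    pop <- assemble_population(tetrads, parents, config$sector_dist,
                               seed = config$seed + 2L)
    ann <- simulate_annotation_and_expression(
      spec, seed = config$seed + 3L,
      gff = out("annotation.gff3"), cds_fasta = out("cds.fa"),
      expr = out("expression.tsv"), truth = out("truth_snps.tsv"))
    vcfs <- character()
    for (k in seq_along(config$bulk_pairs)) {
      bp <- config$bulk_pairs[[k]]
      vcfs[bp$name] <- out(paste0("bulks_", bp$name, ".vcf"))
      build_bulks(pop, bp$n_rt, bp$n_wt, config$mean_depth,
                  seed = config$seed + 10L + k,
                  vcf = vcfs[bp$name],
                  truth = out(paste0("truth_", bp$name, ".tsv")))
    }
    list(parents = parents, pop = pop, ann = ann, vcfs = vcfs)
  })
  log$stages$simulate <- list(markers = nrow(sim$parents),
                              sectors = nrow(sim$pop$samples))

  scans <- list()
  for (k in seq_along(config$bulk_pairs)) {
    bp <- config$bulk_pairs[[k]]
    flt <- .stage("filter", {
      recs <- read_pool_vcf(sim$vcfs[[bp$name]])
      fv <- filter_variants(recs, thr, pools = c("RT", "WT"))
      kept <- extract_parental_differences(fv$kept, "P1", c("RT", "WT"), thr)
      log$stages[[paste0("filter_", bp$name)]] <- list(
        input = nrow(recs), removed = as.list(fv$removed),
        parental_differences = nrow(kept))
      kept
    })
    scans[[bp$name]] <- .stage("qtlseq", {
      sc <- qtlseq_scan(flt, config$chrom_lengths, "RT", "WT",
                        n_rt = bp$n_rt, n_wt = bp$n_wt,
                        window = config$window, step = config$step,
                        reps = config$ci_reps, levels = config$levels,
                        min_snps = config$min_snps,
                        seed = config$seed + 20L + k)
      .write_tsv(sc$index, out(paste0("snp_index_", bp$name, ".tsv")))
      .write_tsv(sc$windows, out(paste0("windows_", bp$name, ".tsv")))
      for (lv in names(sc$regions)) {
        .write_tsv(sc$regions[[lv]],
                   out(paste0("regions", lv, "_", bp$name, ".tsv")))
        write_regions_bed(sc$regions[[lv]],
                          out(paste0("regions", lv, "_", bp$name, ".bed")))
      }
      if (isTRUE(config$plots)) {
        grDevices::png(out(paste0("scan_", bp$name, ".png")), 900, 700)
        plot(sc)
        grDevices::dev.off()
      }
      sc
    })
  }

  overlap <- .stage("intersect", {
    regs <- lapply(scans, function(s) s$regions[["95"]])
    ov <- Reduce(intersect_pool_pairs, regs)
    .write_tsv(ov, out("regions_overlap.tsv"))
    ov
  })
  log$stages$intersect <- list(n_regions = nrow(overlap))

  fm <- .stage("finemap", {
    ph <- table(sim$pop$samples$phenotype)
    seg <- chi_square_segregation(ph[["WT"]], ph[["RT"]])
    set.seed(config$seed + 30L)
    map_ids <- sample(nrow(sim$pop$samples), config$n_map_samples)
    G <- sim$pop$genotypes[map_ids, , drop = FALSE]
    G[matrix(stats::runif(length(G)) < config$map_missing_rate,
             nrow(G), ncol(G))] <- NA
    mk <- data.frame(id = sprintf("M%05d", seq_len(nrow(sim$parents))),
                     chrom = sim$parents$chrom, pos = sim$parents$pos,
                     stringsAsFactors = FALSE)
    bins <- screen_and_bin_markers(G, mk)
    lsc <- lod_scan(bins$geno, sim$pop$samples$phenotype[map_ids],
                    bins$markers, n_perm = config$n_perm,
                    alpha = config$lod_alpha, merge_cm = config$merge_cm,
                    lod_drop = config$lod_drop,
                    cm_per_mb = config$recomb_rate,
                    seed = config$seed + 31L)
    .write_tsv(lsc$table, out("lod_scan.tsv"))

    # recombinant screening on a fresh panel genotyped at a few markers
    prior <- if (nrow(overlap) > 0) {
      i <- which.max(region_length(overlap))
      c(overlap$start[i], overlap$end[i])
    } else c(sim$ann$region[["start"]], sim$ann$region[["end"]])
    prior_chrom <- if (nrow(overlap) > 0) overlap$chrom[which.max(region_length(overlap))]
                   else sim$ann$chrom
    in_reg <- which(sim$parents$chrom == prior_chrom &
                    sim$parents$pos >= prior[1] & sim$parents$pos <= prior[2])
    targets <- prior[1] + (seq_len(config$n_kasp_markers - 1) - 0.5) /
      (config$n_kasp_markers - 1) * (prior[2] - prior[1])
    kasp_idx <- unique(c(in_reg[vapply(targets, function(t)
      which.min(abs(sim$parents$pos[in_reg] - t)), 0L)],
      which(sim$parents$is_causal)))
    kasp_parents <- sim$parents[sort(kasp_idx), , drop = FALSE]
    attr(kasp_parents, "spec") <- spec
    n_t <- ceiling(config$n_kasp_samples / 2.8) + 20L
    ktet <- simulate_tetrads(kasp_parents, n_t, seed = config$seed + 32L)
    kpop <- assemble_population(ktet, kasp_parents, config$sector_dist,
                                seed = config$seed + 33L)
    ksel <- seq_len(min(config$n_kasp_samples, nrow(kpop$samples)))
    nb <- narrow_by_recombinants(
      data.frame(id = sprintf("SNP%d", seq_len(nrow(kasp_parents))),
                 pos = kasp_parents$pos),
      kpop$genotypes[ksel, , drop = FALSE],
      kpop$samples$phenotype[ksel], prior)
    .write_tsv(data.frame(chrom = prior_chrom, start = nb$region[["start"]],
                          end = nb$region[["end"]]),
               out("region_narrowed.tsv"))
    list(segregation = seg, bins = bins, lod = lsc, narrowing = nb,
         prior = prior, chrom = prior_chrom)
  })
  log$stages$finemap <- list(
    chisq = fm$segregation$statistic, bins = length(fm$bins$representatives),
    lod_threshold = fm$lod$threshold,
    narrowed = unname(fm$narrowing$region))

  cand <- .stage("candidates", {
    genes <- read_gene_models(out("annotation.gff3"), out("cds.fa"))
    expression <- utils::read.delim(out("expression.tsv"),
                                    stringsAsFactors = FALSE)
    snps <- sim$ann$snps
    reg <- fm$narrowing$region
    snps <- snps[snps$chrom == fm$chrom & snps$pos >= reg[["start"]] &
                 snps$pos <= reg[["end"]], , drop = FALSE]
    eff <- classify_snps(snps[c("chrom", "pos", "ref", "alt")], genes,
                         flank = config$flank)
    .write_tsv(eff, out("snp_effects.tsv"))
    ranked <- prioritize_candidates(c(reg[["start"]], reg[["end"]]), fm$chrom,
                                    genes, eff, expression,
                                    threshold = config$deg_threshold)
    .write_tsv(ranked, out("candidates.tsv"))
    list(effects = eff, ranked = ranked)
  })
  log$stages$candidates <- list(snps_classified = nrow(cand$effects),
                                genes_ranked = nrow(cand$ranked))
  log$config <- unclass(config)
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(scans = scans, overlap = overlap, finemap = fm,
                 candidates = cand, truth = list(
                   causal_chrom = spec$causal_chrom,
                   causal_pos = spec$causal_pos,
                   candidate_gene = sim$ann$candidate_gene),
                 log = log, outdir = config$outdir))
}
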