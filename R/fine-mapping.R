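#' Chi-square test for 1:1 phenotype segregation
#'
#' Goodness-of-fit test of the observed wild-type : red-type sector counts
#' against the 1:1 Mendelian expectation for a single nuclear locus in a
#' haploid cross. No continuity correction; significance is judged against
#' the df = 1 critical value 3.84 at alpha = 0.05.
#'
#' @param count_wt,count_rt Observed sector counts.
#' @param alpha Significance level.
#' @return List: statistic, df, critical, p_value, significant.
#' @examples
#' chi_square_segregation(5830, 5682)
#' @export
chi_square_segregation <- function(count_wt, count_rt, alpha = 0.05) {
  if (count_wt < 0 || count_rt < 0) stop("counts must be non-negative")
  if (count_wt + count_rt < 1) stop("both counts are zero")
  ht <- stats::chisq.test(c(count_wt, count_rt), p = c(0.5, 0.5),
                          correct = FALSE)
  crit <- stats::qchisq(1 - alpha, df = 1)
  list(statistic = unname(ht$statistic), df = 1, critical = crit,
       p_value = unname(ht$p.value),
       significant = unname(ht$statistic) > crit)
}

#' Screen markers and cluster them into recombination bins
#'
#' Removes markers with too many missing genotypes or too low a minor-allele
#' frequency, then groups the survivors by exact equality of their genotype
#' vectors (missing treated as its own symbol); each group is one
#' recombination bin represented by its leftmost marker.
#'
#' @param geno Samples x markers matrix, entries 0 (maternal), 1 (paternal) or
#'   NA.
#' @param markers data.frame with \code{id}, \code{chrom}, \code{pos}, one row
#'   per column of \code{geno}, sorted by (chrom, pos).
#' @param max_missing Maximum missing fraction per marker.
#' @param min_maf Minimum minor-allele frequency among non-missing calls.
#' @return List: \code{representatives} (marker ids), \code{bins} (named list
#'   of member ids), \code{geno} and \code{markers} restricted to
#'   representatives, \code{n_filtered}.
#' @export
screen_and_bin_markers <- function(geno, markers, max_missing = 0.2,
                                   min_maf = 0.05) {
  stopifnot(ncol(geno) == nrow(markers))
  miss <- colMeans(is.na(geno))
  p <- colMeans(geno, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- which(miss <= max_missing & !is.na(maf) & maf >= min_maf)
  if (length(keep) == 0) stop("all markers removed by screening filters")
  sig <- apply(geno[, keep, drop = FALSE], 2,
               function(g) paste(ifelse(is.na(g), "m", g), collapse = ""))
  first <- !duplicated(sig)
  rep_idx <- keep[first]
  bins <- split(markers$id[keep], match(sig, sig[first]))
  names(bins) <- markers$id[rep_idx]
  list(representatives = markers$id[rep_idx], bins = bins,
       geno = geno[, rep_idx, drop = FALSE],
       markers = markers[rep_idx, , drop = FALSE],
       n_filtered = nrow(markers) - length(keep))
}

.lod_from_r <- function(r, n) {
  theta <- r / n
  ll <- ifelse(r > 0, r * log10(theta), 0) +
    ifelse(n - r > 0, (n - r) * log10(1 - theta), 0)
  ll - n * log10(0.5)
}

#' Single-marker LOD scan for a binary trait in a haploid population
#'
#' For each marker, counts recombinants r (samples whose allele differs from
#' the phenotype-implied allele: red-type implies the paternal allele) among
#' the n informative samples and scores
#' LOD = log10[ theta^r (1-theta)^(n-r) / 0.5^n ] with theta = r/n. The
#' genome-wide significance threshold is the (1-alpha) quantile of the maximum
#' LOD over phenotype permutations. Contiguous runs of significant markers
#' form QTLs; QTLs whose peaks are closer than \code{merge_cm} are merged
#' keeping the higher peak, and each peak's support interval is the contiguous
#' run of markers within 1.5 LOD of the peak.
#'
#' @param geno Samples x markers 0/1/NA matrix.
#' @param phenotype Character vector ("RT"/"WT") per sample.
#' @param markers data.frame \code{id}, \code{chrom}, \code{pos}; optional
#'   \code{cm} genetic positions.
#' @param n_perm Phenotype permutations for the threshold.
#' @param alpha Genome-wide significance level.
#' @param merge_cm Peaks closer than this (cM) are merged.
#' @param lod_drop Support-interval drop from the peak.
#' @param cm_per_mb Physical-to-genetic conversion used when \code{markers$cm}
#'   is absent.
#' @param seed Seed for the permutations.
#' @return Object of class \code{"lod_scan"}: per-marker table, threshold, and
#'   peak table with 1.5-LOD support intervals.
#' @export
lod_scan <- function(geno, phenotype, markers, n_perm = 1000, alpha = 0.05,
                     merge_cm = 10, lod_drop = 1.5, cm_per_mb = 4.37,
                     seed = 1L) {
  if (length(unique(phenotype)) < 2)
    stop("need both phenotype classes present")
  if (nrow(geno) < 2) stop("need at least two samples")
  if (any(colSums(!is.na(geno)) == 0)) stop("marker with all genotypes missing")
  ph <- as.integer(phenotype == "RT")
  M <- !is.na(geno)
  G0 <- geno; G0[!M] <- 0L
  n_inf <- colSums(M)
  # r(p) = sum_i informative |g_i - p_i| = colSums(G0) + t(M) p - 2 t(G0) p
  r_of <- function(P) {
    colSums(G0) + crossprod(M, P) - 2 * crossprod(G0, P)
  }
  r_obs <- drop(r_of(ph))
  lod <- .lod_from_r(r_obs, n_inf)
  set.seed(seed)
  P <- replicate(n_perm, sample(ph))
  Rp <- r_of(P)
  max_lod <- apply(.lod_from_r(Rp, n_inf), 2, max)
  threshold <- unname(stats::quantile(max_lod, 1 - alpha))

  cm <- if (!is.null(markers$cm)) markers$cm else markers$pos / 1e6 * cm_per_mb
  tab <- data.frame(id = markers$id, chrom = markers$chrom, pos = markers$pos,
                    cm = cm, r = r_obs, n = n_inf, lod = lod,
                    stringsAsFactors = FALSE)

  peaks <- list()
  for (ch in unique(tab$chrom)) {
    t_ch <- tab[tab$chrom == ch, , drop = FALSE]
    sig <- t_ch$lod > threshold
    if (!any(sig)) next
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in which(runs$values)) {
      block <- starts[k]:ends[k]
      pk <- block[which.max(t_ch$lod[block])]
      # support: contiguous markers within lod_drop of the peak
      lo <- pk; while (lo > 1 && t_ch$lod[lo - 1] >= t_ch$lod[pk] - lod_drop) lo <- lo - 1
      hi <- pk; while (hi < nrow(t_ch) && t_ch$lod[hi + 1] >= t_ch$lod[pk] - lod_drop) hi <- hi + 1
      peaks[[length(peaks) + 1]] <- data.frame(
        id = t_ch$id[pk], chrom = ch, pos = t_ch$pos[pk], cm = t_ch$cm[pk],
        lod = t_ch$lod[pk],
        support_start = t_ch$pos[lo], support_end = t_ch$pos[hi],
        support_start_cm = t_ch$cm[lo], support_end_cm = t_ch$cm[hi],
        stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(id = character(), chrom = character(), pos = numeric(),
               cm = numeric(), lod = numeric(), support_start = numeric(),
               support_end = numeric(), support_start_cm = numeric(),
               support_end_cm = numeric())
  # merge peaks < merge_cm apart on the same chromosome, keeping the higher
  if (nrow(peaks) > 1) {
    peaks <- peaks[order(peaks$chrom, peaks$cm), , drop = FALSE]
    repeat {
      merged <- FALSE
      i <- 1
      while (i < nrow(peaks)) {
        if (peaks$chrom[i] == peaks$chrom[i + 1] &&
            abs(peaks$cm[i + 1] - peaks$cm[i]) < merge_cm) {
          keep <- if (peaks$lod[i] >= peaks$lod[i + 1]) i else i + 1
          drop_ <- setdiff(c(i, i + 1), keep)
          peaks$support_start[keep] <- min(peaks$support_start[c(i, i + 1)])
          peaks$support_end[keep] <- max(peaks$support_end[c(i, i + 1)])
          peaks$support_start_cm[keep] <- min(peaks$support_start_cm[c(i, i + 1)])
          peaks$support_end_cm[keep] <- max(peaks$support_end_cm[c(i, i + 1)])
          peaks <- peaks[-drop_, , drop = FALSE]
          merged <- TRUE
        } else i <- i + 1
      }
      if (!merged) break
    }
    rownames(peaks) <- NULL
  }
  structure(list(table = tab, threshold = threshold, peaks = peaks,
                 params = list(n_perm = n_perm, alpha = alpha,
                               merge_cm = merge_cm, lod_drop = lod_drop,
                               cm_per_mb = cm_per_mb, seed = seed)),
            class = "lod_scan")
}

#' @export
print.lod_scan <- function(x, ...) {
  cat("Single-marker LOD scan:", nrow(x$table), "markers;",
      "threshold (", 100 * (1 - x$params$alpha), "%): ",
      round(x$threshold, 2), "\n", sep = "")
  if (nrow(x$peaks) == 0) cat("no significant QTL\n")
  else print(x$peaks[c("id", "chrom", "pos", "cm", "lod",
                       "support_start", "support_end")])
  invisible(x)
}

#' @export
summary.lod_scan <- function(object, ...) {
  cat("markers:", nrow(object$table), " max LOD:",
      round(max(object$table$lod), 2), " threshold:",
      round(object$threshold, 2), "\n")
  invisible(object)
}

#' @export
plot.lod_scan <- function(x, ...) {
  chroms <- unique(x$table$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    d <- x$table[x$table$chrom == ch, ]
    plot(d$pos / 1e6, d$lod, type = "l", xlab = "position (Mb)", ylab = "LOD",
         main = ch, ...)
    graphics::abline(h = x$threshold, col = "red", lty = 2)
  }
  invisible(x)
}

#' Narrow a candidate region using recombinant genotypes
#'
#' A sample is recombinant at a marker when its allele differs from the allele
#' implied by its phenotype (red-type implies the paternal allele, wild type
#' the maternal one). The causal locus must lie within the cosegregating core
#' (markers with zero recombinants); each boundary moves inward to the
#' position of the innermost marker carrying at least one recombinant on that
#' side, and keeps the prior boundary where no such marker exists. Boundary
#' markers are closed (included) endpoints.
#'
#' @param markers data.frame \code{id}, \code{pos} sorted by position, all
#'   markers inside or flanking the prior region.
#' @param geno Samples x markers 0/1/NA matrix.
#' @param phenotype "RT"/"WT" per sample; must be non-missing for genotyped
#'   samples.
#' @param prior Numeric (start, end) of the prior candidate region.
#' @return List: \code{region} (start, end), \code{recombinants} (named list
#'   of sample ids per marker), \code{cosegregating} (ids of zero-recombinant
#'   markers inside the narrowed region), \code{counts} per-marker table.
#' @export
narrow_by_recombinants <- function(markers, geno, phenotype, prior) {
  if (is.unsorted(markers$pos, strictly = TRUE))
    stop("markers must be strictly ordered by position")
  if (anyNA(phenotype[rowSums(!is.na(geno)) > 0]))
    stop("phenotype missing for a genotyped sample")
  expected <- as.integer(phenotype == "RT")
  rec <- lapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    which(!is.na(g) & g != expected)
  })
  n_rec <- lengths(rec)
  counts <- data.frame(id = markers$id, pos = markers$pos,
                       n_recombinants = n_rec, stringsAsFactors = FALSE)
  zero <- which(n_rec == 0)
  prior <- c(prior[[1]], prior[[2]])
  start <- prior[1]; end <- prior[2]
  if (length(zero) > 0) {
    core_l <- min(markers$pos[zero]); core_r <- max(markers$pos[zero])
    left <- which(n_rec > 0 & markers$pos < core_l)
    right <- which(n_rec > 0 & markers$pos > core_r)
    if (length(left) > 0) start <- max(prior[1], max(markers$pos[left]))
    if (length(right) > 0) end <- min(prior[2], min(markers$pos[right]))
  }
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  recomb <- lapply(rec, function(i) ids[i])
  names(recomb) <- markers$id
  coseg <- markers$id[n_rec == 0 & markers$pos >= start & markers$pos <= end]
  list(region = c(start = start, end = end),
       recombinants = recomb[n_rec > 0], cosegregating = coseg,
       counts = counts)
}

#' Average genetic-map spacing
#'
#' Total map length divided by the number of bin markers (the reporting
#' convention that prints 1.94 cM for 472.45 cM over 243 bins).
#'
#' @param total_cm Total map length in cM.
#' @param n_bins Number of bin markers.
#' @return Average spacing in cM.
#' @export
average_bin_spacing <- function(total_cm, n_bins) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  total_cm / n_bins
}
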