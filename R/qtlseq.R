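#' SNP-index and delta(SNP-index)
#'
#' The SNP-index of a pool at a site is the fraction of reads supporting the
#' mutant-parent (alternate) allele; delta(SNP-index) is the red-type bulk's
#' index minus the wild-type bulk's. With this orientation a causal locus
#' drives the red-type bulk's index towards 1 and the wild-type bulk's towards
#' 0, so delta approaches +1.
#'
#' @param alt_reads,total_reads Read counts (vectorised).
#' @param index_rt,index_wt Pool indices in [0, 1].
#' @return Numeric vector.
#' @examples
#' snp_index(3, 12)
#' delta_index(0.3, 0.7)
#' @export
snp_index <- function(alt_reads, total_reads) {
  if (any(total_reads < 1)) stop("total_reads must be >= 1 (filter first)")
  if (any(alt_reads < 0 | alt_reads > total_reads))
    stop("alt_reads outside [0, total_reads]")
  alt_reads / total_reads
}

#' @rdname snp_index
#' @export
delta_index <- function(index_rt, index_wt) {
  if (any(index_rt < 0 | index_rt > 1 | index_wt < 0 | index_wt > 1))
    stop("indices must lie in [0, 1]")
  index_rt - index_wt
}

#' Per-site SNP-index table for a bulk pair
#'
#' @param records Filtered record table.
#' @param rt_pool,wt_pool Pool names of the red-type and wild-type bulks.
#' @return data.frame: chrom, pos, depth_rt, depth_wt, index_rt, index_wt,
#'   delta.
#' @export
snp_index_table <- function(records, rt_pool = "RT", wt_pool = "WT") {
  d_rt <- records[[paste0(rt_pool, ".dp")]]
  d_wt <- records[[paste0(wt_pool, ".dp")]]
  i_rt <- snp_index(records[[paste0(rt_pool, ".alt")]], d_rt)
  i_wt <- snp_index(records[[paste0(wt_pool, ".alt")]], d_wt)
  data.frame(chrom = records$chrom, pos = records$pos,
             depth_rt = d_rt, depth_wt = d_wt,
             index_rt = i_rt, index_wt = i_wt,
             delta = delta_index(i_rt, i_wt), stringsAsFactors = FALSE)
}

#' Simulated null confidence intervals for delta(SNP-index)
#'
#' Monte Carlo null distribution under no QTL: per replicate and bulk, the
#' bulk's allele count is Binomial(n, 1/2), its allele frequency the count
#' over n, and the observed index Binomial(depth, frequency) over depth; delta
#' is the difference of the two indices. Bounds are symmetric two-sided
#' empirical quantiles. Vectorised over depth pairs; draws are shared across
#' depths within a call so each unique (depth_rt, depth_wt) pair is simulated
#' once.
#'
#' @param n_rt,n_wt Bulk sizes (sectors pooled).
#' @param depth_rt,depth_wt Read depths (vectors of equal length, or scalars).
#' @param reps Replicates (>= 100).
#' @param levels Confidence levels in percent.
#' @param seed Seed.
#' @return data.frame aligned with the depth vectors: depth_rt, depth_wt and
#'   \code{lower<level>} / \code{upper<level>} columns.
#' @examples
#' simulate_null_ci(24, 24, 100, 100, reps = 1000)
#' @export
simulate_null_ci <- function(n_rt, n_wt, depth_rt, depth_wt, reps = 10000,
                             levels = c(95, 99), seed = 1L) {
  if (n_rt < 1 || n_wt < 1) stop("bulk sizes must be >= 1")
  if (any(depth_rt < 1) || any(depth_wt < 1)) stop("depths must be >= 1")
  if (reps < 100) stop("need at least 100 replicates")
  k <- max(length(depth_rt), length(depth_wt))
  depth_rt <- rep_len(depth_rt, k)
  depth_wt <- rep_len(depth_wt, k)
  set.seed(seed)
  p_rt <- stats::rbinom(reps, n_rt, 0.5) / n_rt
  p_wt <- stats::rbinom(reps, n_wt, 0.5) / n_wt
  ud_rt <- sort(unique(depth_rt))
  ud_wt <- sort(unique(depth_wt))
  draw_idx <- function(depths, p) {
    m <- matrix(stats::rbinom(reps * length(depths),
                              rep(depths, each = reps), rep(p, length(depths))),
                nrow = reps)
    sweep(m, 2, depths, "/")
  }
  irt <- draw_idx(ud_rt, p_rt)
  iwt <- draw_idx(ud_wt, p_wt)
  probs <- sort(c((1 - levels / 100) / 2, 1 - (1 - levels / 100) / 2))
  ir <- match(depth_rt, ud_rt)
  iw <- match(depth_wt, ud_wt)
  key <- (ir - 1L) * length(ud_wt) + iw
  uk <- which(!duplicated(key))
  # type-7 sample quantiles via partial sort (the hot loop of the scan)
  h <- (reps - 1) * probs + 1
  lo_i <- floor(h); hi_i <- ceiling(h)
  part <- unique(c(lo_i, hi_i))
  qmat <- matrix(NA_real_, length(uk), length(probs))
  for (u in seq_along(uk)) {
    k <- uk[u]
    d <- sort(irt[, ir[k]] - iwt[, iw[k]], partial = part)
    qmat[u, ] <- d[lo_i] + (h - lo_i) * (d[hi_i] - d[lo_i])
  }
  row_of <- match(key, key[uk])
  out <- data.frame(depth_rt = depth_rt, depth_wt = depth_wt)
  for (lv in sort(levels)) {
    lo <- match((1 - lv / 100) / 2, probs)
    hi <- match(1 - (1 - lv / 100) / 2, probs)
    out[[paste0("lower", lv)]] <- qmat[row_of, lo]
    out[[paste0("upper", lv)]] <- qmat[row_of, hi]
  }
  rownames(out) <- NULL
  out
}

#' Sliding-window means of delta(SNP-index)
#'
#' Windows are anchored at positions 1, step+1, 2*step+1, ... on every
#' chromosome; a site at position p belongs to every window whose inclusive
#' span [start, start+window-1] (truncated at the chromosome end) contains p.
#' The window statistic is the arithmetic mean of its member sites' delta
#' values; any per-site confidence-bound columns present are averaged the same
#' way. Windows with fewer than \code{min_snps} sites are reported with NA
#' means.
#'
#' @param idx Per-site table from \code{\link{snp_index_table}}, optionally
#'   with \code{lower*}/\code{upper*} columns merged in.
#' @param chrom_lengths Named chromosome lengths.
#' @param window,step Window and increment size in bp; window must be a
#'   multiple of step.
#' @param min_snps Minimum member sites for a window to be reported non-missing.
#' @return data.frame: chrom, start, end, n_snps, delta and averaged bound
#'   columns.
#' @export
sliding_window_means <- function(idx, chrom_lengths, window = 1e6, step = 1e5,
                                 min_snps = 3) {
  if (window < step) stop("window must be at least the step size")
  if (window %% step != 0) stop("window must be a multiple of step")
  if (length(chrom_lengths) == 0) stop("empty chromosome set")
  stat_cols <- intersect(c("delta", grep("^(lower|upper)", names(idx), value = TRUE)),
                         names(idx))
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + window - 1, len)
    sub <- idx[idx$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    i1 <- findInterval(starts - 1, sub$pos)
    i2 <- findInterval(ends, sub$pos)
    n <- i2 - i1
    w <- data.frame(chrom = ch, start = starts, end = ends, n_snps = n,
                    stringsAsFactors = FALSE)
    for (cl in stat_cols) {
      cs <- c(0, cumsum(sub[[cl]]))
      m <- (cs[i2 + 1] - cs[i1 + 1]) / n
      m[n < min_snps] <- NA_real_
      w[[cl]] <- m
    }
    out[[ch]] <- w
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call candidate regions from significant windows
#'
#' A window is significant when its mean delta exceeds its mean upper
#' confidence bound at the requested level (one-sided in the direction of the
#' red-type bulk). Overlapping or abutting significant windows are merged into
#' maximal regions spanning from the first window's start to the last
#' window's end.
#'
#' @param windows Window table from \code{\link{sliding_window_means}}.
#' @param level 95 or 99.
#' @return data.frame of class intervals: chrom, start, end, level (possibly
#'   zero rows).
#' @export
call_regions <- function(windows, level = 95) {
  ucol <- paste0("upper", level)
  if (!ucol %in% names(windows))
    stop("no ", ucol, " column: confidence level ", level, " not available")
  sig <- !is.na(windows$delta) & !is.na(windows[[ucol]]) &
    windows$delta > windows[[ucol]]
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch & sig, , drop = FALSE]
    if (nrow(w) == 0) next
    w <- w[order(w$start), , drop = FALSE]
    new_block <- c(TRUE, w$start[-1] > cummax(w$end[-nrow(w)]) + 1)
    block <- cumsum(new_block)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = tapply(w$start, block, min),
      end = tapply(w$end, block, max),
      level = level, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), level = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intersect candidate regions from two pool pairs
#'
#' Standard 1-based inclusive interval intersection of two internally
#' disjoint, sorted region sets.
#'
#' @param regions_a,regions_b Region data.frames (chrom, start, end).
#' @return data.frame of overlap intervals (possibly zero rows).
#' @export
intersect_pool_pairs <- function(regions_a, regions_b) {
  out <- list()
  for (ch in intersect(unique(regions_a$chrom), unique(regions_b$chrom))) {
    a <- regions_a[regions_a$chrom == ch, , drop = FALSE]
    b <- regions_b[regions_b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      s <- pmax(a$start[i], b$start)
      e <- pmin(a$end[i], b$end)
      hit <- s <= e
      if (any(hit))
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = s[hit],
                                             end = e[hit],
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full delta(SNP-index) genome scan for one bulk pair
#'
#' Computes per-site indices, attaches simulated null confidence bounds keyed
#' by each site's observed depth pair, averages everything over sliding
#' windows, and calls candidate regions at each confidence level.
#'
#' @param records Filtered parental-difference records.
#' @param chrom_lengths Named chromosome lengths.
#' @param rt_pool,wt_pool Bulk pool names.
#' @param n_rt,n_wt Bulk sizes.
#' @param window,step Sliding-window geometry in bp.
#' @param reps Null-simulation replicates.
#' @param levels Confidence levels in percent.
#' @param min_snps Minimum sites per window.
#' @param seed Seed for the null simulation.
#' @return Object of class \code{"qtlseq_scan"}: list with \code{index},
#'   \code{windows}, \code{regions} (one data.frame per level) and
#'   \code{params}.
#' @export
qtlseq_scan <- function(records, chrom_lengths, rt_pool = "RT", wt_pool = "WT",
                        n_rt, n_wt, window = 1e6, step = 1e5, reps = 10000,
                        levels = c(95, 99), min_snps = 3, seed = 1L) {
  idx <- snp_index_table(records, rt_pool, wt_pool)
  ci <- simulate_null_ci(n_rt, n_wt, idx$depth_rt, idx$depth_wt,
                         reps = reps, levels = levels, seed = seed)
  idx <- cbind(idx, ci[, -(1:2), drop = FALSE])
  windows <- sliding_window_means(idx, chrom_lengths, window, step, min_snps)
  regions <- lapply(levels, function(lv) call_regions(windows, lv))
  names(regions) <- as.character(levels)
  structure(list(index = idx, windows = windows, regions = regions,
                 params = list(rt_pool = rt_pool, wt_pool = wt_pool,
                               n_rt = n_rt, n_wt = n_wt, window = window,
                               step = step, reps = reps, levels = levels,
                               min_snps = min_snps, seed = seed)),
            class = "qtlseq_scan")
}

#' @export
print.qtlseq_scan <- function(x, ...) {
  cat("delta(SNP-index) scan:", nrow(x$index), "sites,",
      sum(!is.na(x$windows$delta)), "informative windows\n")
  for (lv in names(x$regions)) {
    r <- x$regions[[lv]]
    cat("  ", lv, "% regions: ", nrow(r), sep = "")
    if (nrow(r) > 0)
      cat(" (", paste(sprintf("%s:%s-%s", r$chrom,
                              format(r$start, big.mark = ",", scientific = FALSE),
                              format(r$end, big.mark = ",", scientific = FALSE)),
                      collapse = "; "), ")", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.qtlseq_scan <- function(object, ...) {
  r <- do.call(rbind, object$regions)
  if (nrow(r) > 0) r$length_bp <- region_length(r)
  structure(list(n_sites = nrow(object$index),
                 windows = object$windows, regions = r,
                 params = object$params), class = "summary.qtlseq_scan")
}

#' @export
print.summary.qtlseq_scan <- function(x, ...) {
  cat("delta(SNP-index) scan over", x$n_sites, "sites\n")
  cat("bulk sizes:", x$params$n_rt, "/", x$params$n_wt,
      "; window", x$params$window / 1e6, "Mb, step", x$params$step / 1e3, "kb\n")
  if (nrow(x$regions) == 0) cat("no candidate regions\n") else print(x$regions)
  invisible(x)
}

#' Plot a delta(SNP-index) scan
#'
#' One panel per chromosome: window mean delta with the simulated two-sided
#' confidence bands.
#'
#' @param x A \code{qtlseq_scan}.
#' @param levels Levels to draw bands for.
#' @param ... Passed to \code{plot}.
#' @export
plot.qtlseq_scan <- function(x, levels = x$params$levels, ...) {
  w <- x$windows
  chroms <- unique(w$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  cols <- c("blue", "red")
  for (ch in chroms) {
    d <- w[w$chrom == ch, ]
    mid <- (d$start + d$end) / 2 / 1e6
    plot(mid, d$delta, type = "l", ylim = c(-1, 1), xlab = "position (Mb)",
         ylab = expression(Delta * " SNP-index"), main = ch, ...)
    graphics::abline(h = 0, col = "grey")
    for (k in seq_along(levels)) {
      lv <- levels[k]
      graphics::lines(mid, d[[paste0("upper", lv)]], col = cols[k], lty = 2)
      graphics::lines(mid, d[[paste0("lower", lv)]], col = cols[k], lty = 2)
    }
  }
  invisible(x)
}
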