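#' Variant filter thresholds
#'
#' Quality thresholds applied to pooled variant records before the
#' delta(SNP-index) analysis: per-pool depth bounds, minimum mapping quality,
#' minimum distance between adjacent sites, and the minimum alternate-allele
#' fraction at which the haploid mutant parent is considered fixed for the
#' alternate allele.
#'
#' @param min_depth,max_depth Inclusive per-pool depth bounds.
#' @param min_mq Minimum mapping quality.
#' @param min_gap Minimum distance (bp) to the nearest other site; both
#'   members of any closer pair are removed.
#' @param min_parent_alt_frac Minimum alternate fraction in the mutant-parent
#'   pool for a site to count as a fixed parental difference.
#' @return Object of class \code{"filter_thresholds"}.
#' @export
filter_thresholds <- function(min_depth = 4, max_depth = 1000, min_mq = 20,
                              min_gap = 5, min_parent_alt_frac = 0.9) {
  if (min_depth > max_depth) stop("min_depth exceeds max_depth")
  if (any(c(min_depth, max_depth, min_mq, min_gap, min_parent_alt_frac) < 0))
    stop("thresholds must be non-negative")
  structure(list(min_depth = min_depth, max_depth = max_depth, min_mq = min_mq,
                 min_gap = min_gap, min_parent_alt_frac = min_parent_alt_frac),
            class = "filter_thresholds")
}

.check_sorted <- function(records) {
  ord <- order(records$chrom, records$pos)
  if (!identical(ord, seq_len(nrow(records))))
    stop("records must be sorted by (chrom, pos)")
  if (anyDuplicated(records[c("chrom", "pos")]))
    stop("duplicate positions in input")
}

#' Apply quality filters to pooled variant records
#'
#' Removes records failing per-pool depth bounds, mapping quality, or the
#' adjacent-site distance rule (both members of any pair of sites closer than
#' \code{min_gap} bp are removed; adjacency is assessed on the full input set).
#' Removal counts partition the removed records by the first failing rule, in
#' the order depth, mapping quality, adjacency.
#'
#' @param records Sorted record table (one row per site).
#' @param thresholds A \code{\link{filter_thresholds}}.
#' @param pools Pools whose depths are checked; default all pools present.
#' @return List with \code{kept} (records, input order preserved) and
#'   \code{removed} (named counts: depth, mq, adjacency).
#' @export
filter_variants <- function(records, thresholds = filter_thresholds(),
                            pools = NULL) {
  .check_sorted(records)
  if (is.null(pools)) pools <- pool_names(records)
  dp <- as.matrix(records[paste0(pools, ".dp")])
  fail_depth <- apply(dp < thresholds$min_depth | dp > thresholds$max_depth,
                      1, any)
  fail_mq <- is.na(records$mq) | records$mq < thresholds$min_mq

  too_close <- rep(FALSE, nrow(records))
  for (ch in unique(records$chrom)) {
    i <- which(records$chrom == ch)
    if (length(i) < 2) next
    gaps <- diff(records$pos[i])
    close_pair <- gaps < thresholds$min_gap
    too_close[i[c(close_pair, FALSE)]] <- TRUE
    too_close[i[c(FALSE, close_pair)]] <- TRUE
  }

  first_fail <- rep(NA_character_, nrow(records))
  first_fail[too_close] <- "adjacency"
  first_fail[fail_mq] <- "mq"
  first_fail[fail_depth] <- "depth"
  keep <- is.na(first_fail)
  removed <- c(depth = sum(first_fail == "depth", na.rm = TRUE),
               mq = sum(first_fail == "mq", na.rm = TRUE),
               adjacency = sum(first_fail == "adjacency", na.rm = TRUE))
  list(kept = records[keep, , drop = FALSE], removed = removed)
}

#' Extract fixed parental differences
#'
#' Keeps sites where the haploid mutant-parent pool is effectively fixed for
#' the alternate allele (alternate fraction at or above the threshold) and
#' both progeny bulks have nonzero coverage.
#'
#' @param records Record table.
#' @param parent_pool Name of the mutant-parent pool.
#' @param bulk_pools Names of the two progeny bulk pools.
#' @param thresholds A \code{\link{filter_thresholds}}.
#' @return The subset of \code{records} that are fixed parental differences.
#' @export
extract_parental_differences <- function(records, parent_pool = "P1",
                                         bulk_pools = c("RT", "WT"),
                                         thresholds = filter_thresholds()) {
  pa <- paste0(parent_pool, c(".alt", ".dp"))
  if (!all(pa %in% names(records)))
    stop("missing parent pool '", parent_pool, "' in records")
  alt <- records[[pa[1]]]
  dp <- records[[pa[2]]]
  frac <- ifelse(dp > 0, alt / dp, 0)
  covered <- Reduce(`&`, lapply(bulk_pools, function(p) {
    col <- paste0(p, ".dp")
    if (!col %in% names(records)) stop("missing bulk pool '", p, "'")
    records[[col]] > 0
  }))
  records[frac >= thresholds$min_parent_alt_frac & dp > 0 & covered, ,
          drop = FALSE]
}
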