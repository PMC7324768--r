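# Shared fixtures, all built in code.

# A small genome for fast simulations.
tiny_spec <- function(n_markers = 200, seed = 1L, ...) {
  genome_spec(chrom_lengths = c(chr1 = 5e6, chr2 = 4e6),
              n_markers = n_markers, causal_chrom = "chr1",
              causal_pos = 2.5e6, recomb_rate = 4.37, seed = seed, ...)
}

# A hand-built parental marker table with exact positions (one chromosome).
manual_parents <- function(positions, chrom_len, recomb_rate = 4.37,
                           causal = positions[1]) {
  spec <- genome_spec(chrom_lengths = c(chr1 = chrom_len),
                      n_markers = length(positions), causal_chrom = "chr1",
                      causal_pos = causal, recomb_rate = recomb_rate)
  p <- data.frame(chrom = "chr1", pos = sort(positions), ref = "A", alt = "C",
                  is_causal = sort(positions) == causal,
                  stringsAsFactors = FALSE)
  attr(p, "spec") <- spec
  p
}

# Variant records for filter tests: per-pool alt/dp count columns.
make_records <- function(pos, dp_rt = 50, dp_wt = 50, alt_rt = 25,
                         alt_wt = 25, mq = 60, chrom = "chr1",
                         dp_p1 = 50, alt_p1 = 50) {
  n <- length(pos)
  r <- function(x) rep_len(x, n)
  data.frame(chrom = r(chrom), pos = pos, ref = r("A"), alt = r("C"),
             mq = r(mq),
             P1.alt = r(alt_p1), P1.dp = r(dp_p1),
             RT.alt = r(alt_rt), RT.dp = r(dp_rt),
             WT.alt = r(alt_wt), WT.dp = r(dp_wt),
             stringsAsFactors = FALSE)
}

# Brute-force O(n^2) oracle for the adjacent-site rule.
adjacency_oracle <- function(records, min_gap = 5) {
  n <- nrow(records)
  fail <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && records$chrom[i] == records$chrom[j] &&
        abs(records$pos[i] - records$pos[j]) < min_gap)
      fail[i] <- TRUE
  }
  fail
}
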