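# Shared fixtures, built once per test run. Small on purpose: deep checks at
# study scale live in the acceptance tests.

fx_locus <- make_true_locus(10000, 0.42, 7)
fx_wgs <- simulate_wgs_pairs(c(locus = fx_locus),
                             read_sim_params(depth = 50, error_rate = 0, seed = 3))
fx_joined <- join_pairs(fx_wgs)

# brute-force oracle: scan every mate, both orientations, all offsets
brute_find <- function(query, pairs) {
  qlen <- nchar(query)
  pats <- c(F = query, R = revcomp(query))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    for (m in 1:2) {
      s <- pairs[[paste0("mate", m)]][i]
      if (nchar(s) < qlen) next
      for (orient in names(pats)) {
        for (k in seq_len(nchar(s) - qlen + 1L)) {
          if (substr(s, k, k + qlen - 1L) == pats[[orient]]) {
            out[[length(out) + 1L]] <- data.frame(
              id = pairs$id[i], mate = m, offset = k - 1L,
              orientation = orient, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(), mate = integer(), offset = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, out))
  out[order(out$id, out$mate, out$offset, out$orientation), , drop = FALSE]
}

# random DNA of given length
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# bare coverage track for island/domain unit tests
make_track <- function(values, bin_size = 200L, total_mapped = sum(values),
                       kind = "raw", contig = "locus",
                       contig_length = length(values) * bin_size) {
  structure(list(contig = contig, bin_size = as.integer(bin_size),
                 contig_length = contig_length, values = values, kind = kind,
                 total_mapped = total_mapped),
            class = "cw_track")
}

# bare alignments table (for count_bins-style unit tests)
make_aln <- function(start, contig = "locus", len = 75L) {
  n <- length(start)
  structure(data.frame(id = sprintf("r%d", seq_len(n)), mate = rep(1L, n),
                       contig = rep(contig, n), start = start,
                       end = start + len - 1L, strand = rep("+", n),
                       n_mismatch = rep(0L, n), stringsAsFactors = FALSE),
            n_reads = n, class = c("cw_alignments", "data.frame"))
}
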