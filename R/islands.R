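## Broad-domain island calling: 200-bp windows flagged against a genome-wide
## Poisson background, merged across gaps up to 1000 bp, scored against the
## input-scaled expectation, and filtered at Benjamini-Hochberg FDR <= 0.01.
## A self-contained, deterministic variant of window/gap island calling; not
## claimed byte-identical to external island callers.

#' Island-calling parameters
#'
#' @param window_bp scanning window size (bp).
#' @param gap_bp maximum ineligible bp bridged between eligible windows; must
#'   be a multiple of `window_bp`.
#' @param window_p Poisson upper-tail probability below which a window is
#'   eligible.
#' @param fdr_threshold report islands with q-value at or below this.
#' @param input_pseudocount floor on the input count used for the island
#'   expectation.
#' @return a `cw_islandparams` list.
#' @export
island_params <- function(window_bp = 200L, gap_bp = 1000L, window_p = 0.20,
                          fdr_threshold = 0.01, input_pseudocount = 1) {
  stopifnot(window_bp >= 1, gap_bp %% window_bp == 0,
            fdr_threshold > 0, fdr_threshold < 1,
            window_p > 0, window_p < 1, input_pseudocount > 0)
  structure(list(window_bp = as.integer(window_bp), gap_bp = as.integer(gap_bp),
                 window_p = window_p, fdr_threshold = fdr_threshold,
                 input_pseudocount = input_pseudocount),
            class = "cw_islandparams")
}

#' Upper-tail Poisson probability P(X >= k)
#'
#' @param k observed count (vectorised, k >= 0).
#' @param lam Poisson mean (> 0).
#' @return P(X >= k); 1 when k = 0.
#' @export
poisson_sf <- function(k, lam) {
  if (any(lam <= 0)) stop("lam must be > 0")
  if (any(k < 0)) stop("k must be >= 0")
  ppois(k - 1, lam, lower.tail = FALSE)
}

#' Flag windows eligible for island membership
#'
#' Background rate `lambda_w = total_reads * window_bp / effective_len`;
#' windows with `poisson_sf(count, lambda_w) < window_p` are eligible.
#'
#' @param track a raw `cw_track` binned at `window_bp`.
#' @param effective_len effective (non-N) genome length.
#' @param params an [island_params()].
#' @return data.frame of eligible windows: window (index), start, end, count.
#' @export
eligible_windows <- function(track, effective_len, params = island_params()) {
  stopifnot(inherits(track, "cw_track"), track$kind == "raw")
  if (track$bin_size != params$window_bp)
    stop("track must be binned at window_bp")
  if (effective_len <= 0) stop("effective_len must be > 0")
  total <- track$total_mapped
  if (total < 1 || sum(track$values) == 0) {
    return(data.frame(window = integer(), start = integer(), end = integer(),
                      count = integer()))
  }
  lam_w <- total * params$window_bp / effective_len
  keep <- which(poisson_sf(track$values, lam_w) < params$window_p)
  data.frame(window = keep,
             start = (keep - 1L) * params$window_bp + 1L,
             end = pmin(keep * params$window_bp, track$contig_length),
             count = track$values[keep])
}

#' Merge eligible windows into candidate islands
#'
#' Consecutive eligible windows whose start-to-start separation is at most
#' `gap_bp + window_bp` are merged, i.e. up to `gap_bp` of ineligible
#' sequence may be bridged.
#'
#' @param windows data.frame from [eligible_windows()] (sorted).
#' @param params an [island_params()].
#' @return data.frame of candidate islands: start, end, n_windows.
#' @export
merge_windows <- function(windows, params = island_params()) {
  if (nrow(windows) == 0)
    return(data.frame(start = integer(), end = integer(), n_windows = integer()))
  sep <- diff(windows$start)
  grp <- cumsum(c(1L, as.integer(sep > params$gap_bp + params$window_bp)))
  out <- lapply(split(seq_len(nrow(windows)), grp), function(i) {
    data.frame(start = windows$start[i[1]], end = windows$end[i[length(i)]],
               n_windows = length(i))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## Reads (window counts) of a raw track falling inside [start, end].
track_reads_in <- function(track, start, end) {
  w0 <- (start - 1L) %/% track$bin_size + 1L
  w1 <- (end - 1L) %/% track$bin_size + 1L
  sum(track$values[w0:min(w1, length(track$values))])
}

#' Score one island against the input-scaled expectation
#'
#' `expected = max(input reads in island, pseudocount, island length *
#' genome-wide input rate) * chip_total / input_total`;
#' `p = poisson_sf(chip reads in island, expected)`. The genome-wide floor
#' keeps a locally under-sampled input from inflating significance: the
#' local input count is a noisy Poisson draw, and treating a low draw as the
#' known mean would double-count chance fluctuation.
#'
#' @param island one-row island (list/data.frame with start, end).
#' @param chip_track,input_track raw `cw_track`s with shared binning.
#' @param params an [island_params()].
#' @param effective_len effective (non-N) genome length used for the
#'   genome-wide input rate; defaults to the track's contig length.
#' @return list with `chip_count`, `expected`, `p_value`.
#' @export
island_significance <- function(island, chip_track, input_track,
                                params = island_params(),
                                effective_len = input_track$contig_length) {
  if (chip_track$bin_size != input_track$bin_size)
    stop("tracks differ in binning")
  if (input_track$total_mapped < 1) stop("input library is empty")
  chip_n <- track_reads_in(chip_track, island$start, island$end)
  input_n <- track_reads_in(input_track, island$start, island$end)
  scale <- chip_track$total_mapped / input_track$total_mapped
  island_len <- island$end - island$start + 1
  floor_n <- input_track$total_mapped * island_len / effective_len
  expected <- max(input_n, params$input_pseudocount, floor_n) * scale
  list(chip_count = chip_n, expected = expected,
       p_value = poisson_sf(chip_n, expected))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param m number of tests corrected for; defaults to `length(p_values)`.
#'   Island calling passes the number of windows scanned, since islands are
#'   selected from a genome-wide window scan and correcting only over the
#'   surviving islands would understate the multiplicity.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH", n = max(m, length(p_values)))
}

#' Call enrichment islands on one contig
#'
#' Composition: window counts -> eligible windows -> gap merge -> island
#' significance against the input-scaled expectation -> BH FDR -> threshold.
#' With `input_aln = NULL` (ChIP-only mode) islands are scored against the
#' genome-wide background rate over their own length.
#'
#' @param chip_aln,input_aln `cw_alignments` (input may be `NULL`).
#' @param contig contig id.
#' @param contig_length its length.
#' @param effective_len effective (non-N) genome length; defaults to
#'   `contig_length`.
#' @param params an [island_params()].
#' @return `cw_islands` data.frame (start, end, n_windows, chip_count,
#'   expected, p_value, q_value) with q at or below `fdr_threshold`;
#'   attribute `"candidates"` holds all scored candidates.
#' @export
call_islands <- function(chip_aln, input_aln, contig, contig_length,
                         effective_len = contig_length,
                         params = island_params()) {
  if (nrow(chip_aln) == 0) stop("ChIP library is empty")
  chip_track <- count_bins(chip_aln, contig, contig_length, params$window_bp)
  elig <- eligible_windows(chip_track, effective_len, params)
  cand <- merge_windows(elig, params)
  # Islands are assembled from windows *selected* for high counts, so under
  # the null their summed ChIP count exceeds lambda_w per window. The floor
  # on the expectation therefore uses the eligibility-conditioned Poisson
  # means: E[X | X >= c] for selected windows, E[X | X < c] for the bridged
  # ones, with c the eligibility count threshold.
  lam_w <- chip_track$total_mapped * params$window_bp / effective_len
  c_min <- stats::qpois(1 - params$window_p, lam_w)
  while (poisson_sf(c_min, lam_w) >= params$window_p) c_min <- c_min + 1L
  mu_sel <- lam_w * poisson_sf(c_min - 1L, lam_w) / poisson_sf(c_min, lam_w)
  mu_rest <- lam_w * (1 - poisson_sf(c_min - 1L, lam_w)) /
    (1 - poisson_sf(c_min, lam_w))
  selection_floor <- function(i) {
    n_span <- (cand$end[i] - cand$start[i] + 1) / params$window_bp
    cand$n_windows[i] * mu_sel + (n_span - cand$n_windows[i]) * mu_rest
  }
  if (nrow(cand)) {
    if (!is.null(input_aln)) {
      input_track <- count_bins(input_aln, contig, contig_length, params$window_bp)
      sc <- lapply(seq_len(nrow(cand)), function(i) {
        s <- island_significance(cand[i, ], chip_track, input_track, params,
                                 effective_len = effective_len)
        s$expected <- max(s$expected, selection_floor(i))
        s$p_value <- poisson_sf(s$chip_count, s$expected)
        s
      })
    } else {
      lam0 <- chip_track$total_mapped / effective_len
      sc <- lapply(seq_len(nrow(cand)), function(i) {
        chip_n <- track_reads_in(chip_track, cand$start[i], cand$end[i])
        expected <- max(lam0 * (cand$end[i] - cand$start[i] + 1L),
                        selection_floor(i))
        list(chip_count = chip_n, expected = expected,
             p_value = poisson_sf(chip_n, expected))
      })
    }
    cand$chip_count <- vapply(sc, `[[`, numeric(1), "chip_count")
    cand$expected <- vapply(sc, `[[`, numeric(1), "expected")
    cand$p_value <- vapply(sc, `[[`, numeric(1), "p_value")
    # islands arise from a genome-wide window scan: correct over the
    # windows scanned, not just the islands that survived eligibility
    cand$q_value <- bh_fdr(cand$p_value, m = length(chip_track$values))
  } else {
    cand$chip_count <- numeric(0); cand$expected <- numeric(0)
    cand$p_value <- numeric(0); cand$q_value <- numeric(0)
  }
  out <- cand[cand$q_value <= params$fdr_threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, candidates = cand, contig = contig,
            class = c("cw_islands", "data.frame"))
}

#' Write islands as BED6+3
#'
#' 0-based half-open; name = island index, score = -log10 q (capped at 1000),
#' extra columns chip_count, expected, q_value.
#'
#' @param islands a `cw_islands` data.frame.
#' @param path output file.
#' @param contig contig id (defaults to the islands' own).
#' @return invisibly, `path`.
#' @export
write_islands_bed <- function(islands, path, contig = attr(islands, "contig")) {
  score <- pmin(round(-log10(pmax(islands$q_value, 1e-100)), 2), 1000)
  df <- data.frame(chrom = contig, start = islands$start - 1L,
                   end = islands$end, name = paste0("island_", seq_len(nrow(islands))),
                   score = score, strand = ".",
                   chip_count = islands$chip_count,
                   expected = signif(islands$expected, 6),
                   q_value = signif(islands$q_value, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
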