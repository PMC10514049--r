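## Domain comparison: turn called islands into CENP-A domains (span, area,
## apex, sub-peaks, asymmetry), and classify cross-tissue/sample conservation
## of the domain position versus sliding.

#' Summarize islands into CENP-A domains
#'
#' Islands separated by at most `merge_gap` bp are merged into one domain;
#' area (sum of positive difference signal), apex (position of the maximum
#' difference bin) and an apex asymmetry statistic (signed difference of
#' positive signal mass right minus left of the apex, as a fraction of the
#' area) are computed from the difference track.
#'
#' @param islands a `cw_islands` data.frame (sorted, non-overlapping).
#' @param diff_track a `cw_track` of kind `"difference"`.
#' @param merge_gap maximum bp between islands merged into one domain.
#' @return `cw_domains` data.frame: start, end, area, apex, asymmetry.
#' @export
domains_from_islands <- function(islands, diff_track, merge_gap = 10000L) {
  stopifnot(inherits(diff_track, "cw_track"), diff_track$kind == "difference")
  if (nrow(islands) == 0) {
    return(structure(data.frame(start = integer(), end = integer(),
                                area = numeric(), apex = numeric(),
                                asymmetry = numeric()),
                     class = c("cw_domains", "data.frame")))
  }
  gapto <- c(Inf, islands$start[-1] - islands$end[-nrow(islands)] - 1L)
  grp <- cumsum(gapto > merge_gap)
  bs <- diff_track$bin_size
  rows <- lapply(split(seq_len(nrow(islands)), grp), function(i) {
    s <- islands$start[i[1]]; e <- islands$end[i[length(i)]]
    w0 <- (s - 1L) %/% bs + 1L
    w1 <- min((e - 1L) %/% bs + 1L, length(diff_track$values))
    v <- diff_track$values[w0:w1]
    apex_bin <- w0 + which.max(v) - 1L
    apex <- (apex_bin - 1L) * bs + (bs + 1) / 2   # bin midpoint position
    pos_v <- pmax(v, 0)
    area <- sum(pos_v)
    rel <- apex_bin - w0 + 1L
    asym <- if (area > 0)
      (sum(pos_v[seq_along(pos_v) > rel]) - sum(pos_v[seq_along(pos_v) < rel])) / area
    else 0
    data.frame(start = s, end = e, area = area, apex = apex, asymmetry = asym)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, contig = attr(islands, "contig"),
            class = c("cw_domains", "data.frame"))
}

#' Overlap coefficient of two intervals
#'
#' `|a intersect b| / min(|a|, |b|)`; 0 when disjoint; 1 iff the
#' intersection equals the smaller interval.
#'
#' @param a,b `c(start, end)` 1-based inclusive intervals.
#' @return fraction in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  inter / min(a[2] - a[1] + 1, b[2] - b[1] + 1)
}

#' Absolute midpoint shift between two intervals
#'
#' @param a,b `c(start, end)` intervals.
#' @return shift in bp.
#' @export
center_shift <- function(a, b) {
  abs((a[1] + a[2]) / 2 - (b[1] + b[2]) / 2)
}

#' Split a domain into sub-peaks at deep valleys
#'
#' A split occurs at every maximal run of at least `min_valley_bp` where the
#' difference signal drops below `valley_fraction` times the smaller of the
#' flanking sub-peak maxima (computed as running maxima on either side of
#' each bin, so valleys at the domain edges never split).
#'
#' @param domain one-row `cw_domains` entry (or list with start, end).
#' @param diff_track a `cw_track` of kind `"difference"`.
#' @param valley_fraction valley depth relative to flanking peak height.
#' @param min_valley_bp minimum valley width in bp.
#' @return data.frame of subdomain intervals (start, end), at least one row.
#' @export
split_subdomains <- function(domain, diff_track, valley_fraction = 0.25,
                             min_valley_bp = 2000L) {
  bs <- diff_track$bin_size
  w0 <- (domain$start - 1L) %/% bs + 1L
  w1 <- min((domain$end - 1L) %/% bs + 1L, length(diff_track$values))
  v <- pmax(diff_track$values[w0:w1], 0)
  if (sum(v) <= 0) stop("domain has no positive signal area")
  n <- length(v)
  # running max strictly left / right of each bin
  lmax <- c(-Inf, cummax(v)[-n])
  rmax <- rev(c(-Inf, cummax(rev(v))[-n]))
  low <- v < valley_fraction * pmin(lmax, rmax)
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  splits <- which(r$values & r$lengths * bs >= min_valley_bp)
  if (!length(splits)) {
    out <- data.frame(start = domain$start, end = domain$end)
  } else {
    cut_lo <- starts[splits]; cut_hi <- ends[splits]
    seg_lo <- c(1L, cut_hi + 1L)
    seg_hi <- c(cut_lo - 1L, n)
    keep <- seg_lo <= seg_hi
    out <- data.frame(
      start = pmax((w0 + seg_lo[keep] - 2L) * bs + 1L, domain$start),
      end = pmin((w0 + seg_hi[keep] - 1L) * bs, domain$end))
  }
  rownames(out) <- NULL
  out
}

#' Classify cross-sample conservation of the CENP-A domain position
#'
#' The reference sample's primary domain (largest area) anchors the
#' comparison; for each tissue the best-matching domain (maximal overlap
#' coefficient, ties broken by smaller center shift) is scored. A tissue is
#' `conserved` iff overlap >= `min_overlap` and center shift <=
#' `max_shift_bp`, `slid` otherwise, and `absent` when it has no domains.
#' The summary is `conserved` iff every tissue is conserved and none absent.
#'
#' @param reference `cw_domains` of the reference sample (non-empty).
#' @param tissues named list of `cw_domains`, one per tissue.
#' @param min_overlap minimum overlap coefficient for conservation.
#' @param max_shift_bp maximum center shift; defaults to half the reference
#'   primary domain span.
#' @return a `cw_conservation` list: `per_tissue` data.frame (tissue,
#'   overlap, shift_bp, asymmetry, label) and `summary` (`"conserved"` or
#'   `"not_conserved"`).
#' @export
classify_panel <- function(reference, tissues, min_overlap = 0.5,
                           max_shift_bp = NULL) {
  if (nrow(reference) == 0) stop("reference sample has no domains")
  ref <- reference[which.max(reference$area), ]
  ref_iv <- c(ref$start, ref$end)
  if (is.null(max_shift_bp)) max_shift_bp <- (ref$end - ref$start + 1) / 2
  rows <- lapply(names(tissues), function(t) {
    d <- tissues[[t]]
    if (is.null(d) || nrow(d) == 0) {
      return(data.frame(tissue = t, overlap = NA_real_, shift_bp = NA_real_,
                        asymmetry = NA_real_, label = "absent",
                        stringsAsFactors = FALSE))
    }
    ov <- vapply(seq_len(nrow(d)), function(i)
      overlap_coefficient(ref_iv, c(d$start[i], d$end[i])), numeric(1))
    sh <- vapply(seq_len(nrow(d)), function(i)
      center_shift(ref_iv, c(d$start[i], d$end[i])), numeric(1))
    best <- order(-ov, sh)[1]
    lab <- if (ov[best] >= min_overlap && sh[best] <= max_shift_bp)
      "conserved" else "slid"
    data.frame(tissue = t, overlap = ov[best], shift_bp = sh[best],
               asymmetry = if ("asymmetry" %in% names(d)) d$asymmetry[best] else NA_real_,
               label = lab, stringsAsFactors = FALSE)
  })
  per_tissue <- do.call(rbind, rows)
  summary <- if (all(per_tissue$label == "conserved")) "conserved" else "not_conserved"
  structure(list(per_tissue = per_tissue, summary = summary,
                 min_overlap = min_overlap, max_shift_bp = max_shift_bp),
            class = "cw_conservation")
}

#' Write domains as BED (0-based half-open)
#'
#' @param domains a `cw_domains` data.frame.
#' @param path output file.
#' @param contig contig id.
#' @return invisibly, `path`.
#' @export
write_domains_bed <- function(domains, path, contig = attr(domains, "contig")) {
  if (is.null(contig)) contig <- "locus"
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(domains$start, domains$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a conservation call as TSV
#'
#' Per-tissue rows (tissue, overlap, shift_bp, asymmetry, label) followed by
#' a one-line `# summary:` comment.
#'
#' @param call a `cw_conservation`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_conservation_tsv <- function(call, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# summary: ", call$summary,
                    " (min_overlap=", call$min_overlap,
                    ", max_shift_bp=", round(call$max_shift_bp, 1), ")"), con)
  write.table(call$per_tissue, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
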