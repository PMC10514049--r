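## Reference patching: excise a misassembled locus, splice in the walked
## contig, drop redundant unplaced contigs, emit an old->new liftover block
## map, compute N-content QC, and adjudicate single-copy vs duplicated
## structure with long reads.

#' A 1-based inclusive genomic interval
#'
#' @param contig contig id.
#' @param start,end 1-based inclusive coordinates (`start <= end`).
#' @return a `cw_interval` list.
#' @export
genomic_interval <- function(contig, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start < 1) stop("start must be >= 1")
  if (start > end) stop("start > end")
  structure(list(contig = contig, start = start, end = end),
            class = "cw_interval")
}

#' Length of a genomic interval
#'
#' 1-based inclusive, so `end - start + 1`.
#'
#' @param iv a [genomic_interval()].
#' @return interval length in nt.
#' @examples
#' interval_length(genomic_interval("chr11", 27592872, 28352430))  # 759559
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "cw_interval"))
  iv$end - iv$start + 1
}

#' Assembly QC: length, N count, N per 100 kb
#'
#' `n_per_100kb = n_count * 100000 / length`, rounded to 2 decimals.
#'
#' @param seq sequence (character scalar).
#' @return list with `length`, `n_count`, `n_per_100kb`.
#' @export
assembly_stats <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop("assembly_stats needs one non-empty sequence")
  len <- nchar(seq)
  n_count <- as.integer(Biostrings::letterFrequency(Biostrings::DNAString(seq), "N"))
  list(length = len, n_count = n_count,
       n_per_100kb = round(n_count * 1e5 / len, 2))
}

#' Per-contig assembly QC table
#'
#' @param genome named character vector of contigs.
#' @return data.frame with contig, length, n_count, n_per_100kb.
#' @export
genome_stats <- function(genome) {
  rows <- lapply(names(genome), function(nm) {
    s <- assembly_stats(genome[[nm]])
    data.frame(contig = nm, length = s$length, n_count = s$n_count,
               n_per_100kb = s$n_per_100kb, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replace an interval of a reference contig and emit a liftover map
#'
#' The target contig becomes prefix + `new_seq` + suffix; contigs listed in
#' `drop_contigs` (e.g. a redundant unplaced duplicate) are removed. The
#' liftover map records: positions before the interval map identically,
#' positions after it shift by `nchar(new_seq) - interval_length(iv)`, and
#' positions inside map to deleted (as do dropped contigs).
#'
#' @param genome named character vector of contigs.
#' @param iv a [genomic_interval()] on a contig of `genome`.
#' @param new_seq replacement sequence (non-empty).
#' @param drop_contigs contig ids to remove.
#' @return list with `genome` (patched) and `map` (a `cw_liftover`).
#' @export
replace_interval <- function(genome, iv, new_seq, drop_contigs = character()) {
  stopifnot(inherits(iv, "cw_interval"), nzchar(new_seq))
  if (!iv$contig %in% names(genome)) stop("unknown contig: ", iv$contig)
  missing_drop <- setdiff(drop_contigs, names(genome))
  if (length(missing_drop))
    stop("drop contig not present: ", paste(missing_drop, collapse = ", "))
  old <- genome[[iv$contig]]
  L <- nchar(old)
  if (iv$end > L) stop("interval exceeds contig length")
  shift <- nchar(new_seq) - interval_length(iv)

  patched <- paste0(substr(old, 1, iv$start - 1), new_seq,
                    substr(old, iv$end + 1, L))
  out <- genome
  out[[iv$contig]] <- patched
  out <- out[setdiff(names(out), drop_contigs)]

  blocks <- data.frame(
    contig = iv$contig,
    old_start = c(if (iv$start > 1) 1, iv$start, if (iv$end < L) iv$end + 1),
    old_end = c(if (iv$start > 1) iv$start - 1, iv$end, if (iv$end < L) L),
    status = c(if (iv$start > 1) "match", "deleted", if (iv$end < L) "match"),
    offset = c(if (iv$start > 1) 0, NA, if (iv$end < L) shift),
    stringsAsFactors = FALSE)
  if (length(drop_contigs)) {
    blocks <- rbind(blocks, data.frame(
      contig = drop_contigs, old_start = 1, old_end = nchar(genome[drop_contigs]),
      status = "deleted", offset = NA, stringsAsFactors = FALSE))
  }
  map <- structure(list(blocks = blocks,
                        contig_lengths = setNames(nchar(genome), names(genome))),
                   class = "cw_liftover")
  list(genome = out, map = map)
}

#' Lift positions through a liftover map
#'
#' @param map a `cw_liftover` from [replace_interval()].
#' @param contig contig id in the old reference.
#' @param pos vector of 1-based old positions.
#' @return numeric vector of new positions, `NA` where the position falls in
#'   a deleted block.
#' @export
lift <- function(map, contig, pos) {
  stopifnot(inherits(map, "cw_liftover"))
  if (!contig %in% names(map$contig_lengths)) stop("unknown contig: ", contig)
  if (any(pos < 1 | pos > map$contig_lengths[[contig]]))
    stop("position outside old contig")
  b <- map$blocks[map$blocks$contig == contig, , drop = FALSE]
  if (nrow(b) == 0) return(pos)  # untouched contig: identity
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(b))) {
    in_blk <- pos >= b$old_start[i] & pos <= b$old_end[i]
    if (b$status[i] == "match") out[in_blk] <- pos[in_blk] + b$offset[i]
  }
  out
}

#' Write a liftover map as a block TSV
#'
#' @param map a `cw_liftover`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_liftover <- function(map, path) {
  write.table(map$blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Longest common prefix / suffix lengths of two strings.
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ra <- charToRaw(substr(a, 1, n)); rb <- charToRaw(substr(b, 1, n))
  d <- which(ra != rb)
  if (!length(d)) n else d[1] - 1L
}
lcs_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ra <- rev(charToRaw(a))[seq_len(n)]; rb <- rev(charToRaw(b))[seq_len(n)]
  d <- which(ra != rb)
  if (!length(d)) n else d[1] - 1L
}

#' Adjudicate single-copy vs duplicated structure with long reads
#'
#' Builds, for each candidate structure, the diagnostic junction string
#' (`anchor_len` trusted bases on either side of the region where the two
#' candidates diverge) and counts long reads containing it - exactly, or with
#' at most `max_mismatch_frac` mismatches. A read supports at most one
#' structure.
#'
#' @param candidate_single,candidate_dup the two candidate sequences (e.g.
#'   collapsed vs tandem-duplicated locus).
#' @param long_reads character vector of long reads.
#' @param anchor_len trusted flank length around the diagnostic junction.
#' @param max_mismatch_frac allowed mismatch fraction when scanning reads
#'   (0 = exact).
#' @return named integer vector `c(support_single = , support_dup = )`.
#' @export
validate_structure <- function(candidate_single, candidate_dup, long_reads,
                               anchor_len = 500L, max_mismatch_frac = 0) {
  lcp <- lcp_len(candidate_single, candidate_dup)
  lcs <- lcs_len(candidate_single, candidate_dup)
  if (lcp < anchor_len || lcs < anchor_len)
    stop("candidates do not share anchor_len of identical flank around the junction")
  # Diagnostic string: anchors around the region that is ambiguous for this
  # candidate. With a tandem duplication the common prefix and suffix overlap
  # (lcp + lcs exceeds the collapsed candidate's length): the diagnostic for
  # the collapsed structure must then span the entire repeated block, since
  # the short collapsed junction also occurs at the second copy's exit in the
  # duplicated structure.
  diag_of <- function(x) {
    lo <- min(lcp, nchar(x) - lcs)
    hi <- max(lcp, nchar(x) - lcs)
    if (lo < anchor_len || hi + anchor_len > nchar(x))
      stop("candidates do not share anchor_len of identical flank around the junction")
    substr(x, lo - anchor_len + 1L, hi + anchor_len)
  }
  d_single <- diag_of(candidate_single)
  d_dup <- diag_of(candidate_dup)
  for (anc in list(substr(d_single, 1L, anchor_len),
                   substr(d_single, nchar(d_single) - anchor_len + 1L,
                          nchar(d_single)))) {
    for (cand in c(candidate_single, candidate_dup)) {
      if (Biostrings::countPattern(anc, Biostrings::DNAString(cand)) != 1)
        stop("anchor not unique within a candidate sequence")
    }
  }
  reads <- Biostrings::DNAStringSet(long_reads)
  count_diag <- function(diag) {
    mm <- floor(max_mismatch_frac * nchar(diag))
    fwd <- Biostrings::vcountPattern(diag, reads, max.mismatch = mm)
    rev <- Biostrings::vcountPattern(revcomp(diag), reads, max.mismatch = mm)
    (fwd + rev) > 0
  }
  hit_s <- count_diag(d_single)
  hit_d <- count_diag(d_dup)
  both <- hit_s & hit_d
  c(support_single = sum(hit_s & !both), support_dup = sum(hit_d & !both))
}
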