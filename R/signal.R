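## Normalized ChIP-minus-input signal: minimal unique-best read placement
## (exact seed + full-length verification), binned counts, RPKM
## normalization, subtractive comparison. The aligner is a deliberately
## minimal stand-in with a fixed contract: exact seed both orientations,
## bounded-substitution verification, unique best placement or unmapped.

#' Precompute a k-mer seed index of a reference
#'
#' Reusable across libraries mapped to the same reference; building it
#' dominates small-genome alignment cost.
#'
#' @param genome named character vector of contigs.
#' @param seed_len seed k-mer length.
#' @return a `cw_index` object.
#' @export
genome_index <- function(genome, seed_len = 30L) {
  stopifnot(!is.null(names(genome)), seed_len >= 1)
  tabs <- lapply(names(genome), function(nm) {
    L <- nchar(genome[[nm]])
    if (L < seed_len) return(NULL)
    pos <- seq_len(L - seed_len + 1L)
    data.table(kmer = substring(genome[[nm]], pos, pos + seed_len - 1L),
               contig = nm, pos = pos)
  })
  idx <- rbindlist(tabs)
  setkey(idx, kmer)
  structure(list(index = idx, seed_len = as.integer(seed_len),
                 genome_raw = lapply(genome, charToRaw),
                 contig_lengths = setNames(nchar(genome), names(genome))),
            class = "cw_index")
}

## Mismatch counts of oriented reads vs reference windows, vectorised per
## contig and read length via raw-byte matrix comparison.
count_mismatches <- function(cand, idx) {
  cand[, nm := NA_integer_]
  for (ct in names(idx$genome_raw)) {
    G <- idx$genome_raw[[ct]]
    sel <- which(cand$contig == ct)
    if (!length(sel)) next
    for (s2 in split(sel, cand$len[sel])) {
      L <- cand$len[s2[1]]
      keep <- s2[cand$pos[s2] + L - 1L <= length(G)]
      if (!length(keep)) next
      gm <- matrix(G[outer(cand$pos[keep], 0:(L - 1L), `+`)], nrow = length(keep))
      rm_ <- matrix(charToRaw(paste(cand$oriented[keep], collapse = "")),
                    nrow = length(keep), byrow = TRUE)
      cand$nm[keep] <- as.integer(rowSums(gm != rm_))
    }
  }
  cand[!is.na(nm)]
}

#' Place reads on a reference: exact seed, verified, unique best
#'
#' For each mate the first `seed_len` bases (in both orientations) are looked
#' up exactly in the reference; every seed hit is verified over the full read
#' length allowing at most `max_mismatch` substitutions; the unique best
#' placement is reported. Ties or no verified placement leave the mate
#' unmapped - downstream counts stay deterministic.
#'
#' @param reads a `cw_readset`, `cw_pairs` table, or character vector of
#'   sequences.
#' @param genome named character vector of contigs (ignored when `index`
#'   given).
#' @param seed_len seed length (must not exceed the read length).
#' @param max_mismatch maximum substitutions over the full read.
#' @param index optional prebuilt [genome_index()].
#' @return `cw_alignments`: data.frame with id, mate, contig, start, end,
#'   strand, n_mismatch; attribute `n_reads` records the library size
#'   submitted.
#' @export
align_reads_minimal <- function(reads, genome = NULL, seed_len = 30L,
                                max_mismatch = 3L, index = NULL) {
  if (inherits(reads, "cw_readset")) reads <- reads$pairs
  if (is.data.frame(reads)) {
    seqs <- c(reads$mate1, reads$mate2)
    ids <- rep(reads$id, 2L)
    mates <- rep(c(1L, 2L), each = nrow(reads))
  } else {
    seqs <- reads
    ids <- if (!is.null(names(reads))) names(reads)
           else sprintf("read_%06d", seq_along(reads))
    mates <- rep(1L, length(reads))
  }
  if (is.null(index)) index <- genome_index(genome, seed_len)
  k <- index$seed_len
  if (any(nchar(seqs) < k)) stop("seed_len exceeds a read length")

  rc <- rc_(seqs)
  rt <- data.table(rid = seq_along(seqs), id = ids, mate = mates,
                   fwd = seqs, rev = rc, len = nchar(seqs))
  cand <- rbind(
    rt[, .(rid, id, mate, oriented = fwd, len, strand = "+",
           kmer = substr(fwd, 1L, k))],
    rt[, .(rid, id, mate, oriented = rev, len, strand = "-",
           kmer = substr(rev, 1L, k))])
  cand <- index$index[cand, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  empty <- data.frame(id = character(), mate = integer(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_mismatch = integer(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0) {
    out <- empty
  } else {
    cand <- count_mismatches(cand, index)
    cand <- cand[nm <= max_mismatch]
    if (nrow(cand) == 0) {
      out <- empty
    } else {
      cand[, best := nm == min(nm), by = rid]
      cand <- cand[best == TRUE]
      cand[, ties := .N, by = rid]
      cand <- cand[ties == 1L]
      setorder(cand, contig, pos, id, mate)
      out <- data.frame(id = cand$id, mate = cand$mate, contig = cand$contig,
                        start = cand$pos, end = cand$pos + cand$len - 1L,
                        strand = cand$strand, n_mismatch = cand$nm,
                        stringsAsFactors = FALSE)
    }
  }
  structure(out, n_reads = length(seqs), class = c("cw_alignments", "data.frame"))
}

#' Fraction of submitted mates with a unique best placement
#'
#' @param aln a `cw_alignments` object.
#' @return fraction in `[0, 1]`.
#' @export
mapped_fraction <- function(aln) {
  nrow(aln) / attr(aln, "n_reads")
}

#' Bin alignment start positions into a raw coverage track
#'
#' Each mapped mate contributes 1 to the bin containing its leftmost
#' coordinate.
#'
#' @param aln a `cw_alignments` object.
#' @param contig contig to count on.
#' @param contig_length length of that contig.
#' @param bin_size bin width in bp.
#' @return a `cw_track` (kind `"raw"`): list with contig, bin_size, values,
#'   kind, total_mapped (all mapped mates in the library).
#' @export
count_bins <- function(aln, contig, contig_length, bin_size = 50L) {
  stopifnot(bin_size >= 1)
  nbins <- ceiling(contig_length / bin_size)
  on_ctg <- aln$start[aln$contig == contig]
  values <- tabulate((on_ctg - 1L) %/% bin_size + 1L, nbins)
  structure(list(contig = contig, bin_size = as.integer(bin_size),
                 contig_length = contig_length, values = values, kind = "raw",
                 total_mapped = nrow(aln)),
            class = "cw_track")
}

#' RPKM-normalize a raw track
#'
#' `value / ((bin_size/1000) * (total_mapped/1e6))`.
#'
#' @param track a raw `cw_track`.
#' @param total_mapped library size; defaults to the track's own.
#' @return a `cw_track` of kind `"rpkm"`.
#' @export
rpkm_normalize <- function(track, total_mapped = track$total_mapped) {
  stopifnot(inherits(track, "cw_track"), track$kind == "raw")
  if (is.null(total_mapped) || total_mapped < 1) stop("total_mapped must be >= 1")
  track$values <- track$values / ((track$bin_size / 1000) * (total_mapped / 1e6))
  track$kind <- "rpkm"
  track$total_mapped <- total_mapped
  track
}

#' Subtract an input track from a ChIP track
#'
#' Bin-wise `chip - input`; negative values are preserved.
#'
#' @param chip,input `cw_track`s of kind `"rpkm"` with identical contig,
#'   bin size and length.
#' @return a `cw_track` of kind `"difference"`.
#' @export
subtract_tracks <- function(chip, input) {
  stopifnot(inherits(chip, "cw_track"), inherits(input, "cw_track"))
  if (chip$contig != input$contig || chip$bin_size != input$bin_size ||
      length(chip$values) != length(input$values))
    stop("tracks differ in contig, bin size or length")
  chip$values <- chip$values - input$values
  chip$kind <- "difference"
  chip
}

#' ChIP-minus-input difference track from two alignment sets
#'
#' Convenience composition: count, RPKM-normalize, subtract.
#'
#' @param chip_aln,input_aln `cw_alignments`.
#' @param contig contig id.
#' @param contig_length its length.
#' @param bin_size bin width in bp.
#' @return a `cw_track` of kind `"difference"`.
#' @export
difference_track <- function(chip_aln, input_aln, contig, contig_length,
                             bin_size = 50L) {
  chip <- rpkm_normalize(count_bins(chip_aln, contig, contig_length, bin_size))
  inp <- rpkm_normalize(count_bins(input_aln, contig, contig_length, bin_size))
  subtract_tracks(chip, inp)
}

#' Write a coverage track as bedGraph (0-based half-open)
#'
#' @param track a `cw_track`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track$values)
  gr <- GenomicRanges::GRanges(
    track$contig,
    IRanges::IRanges(start = (seq_len(n) - 1L) * track$bin_size + 1L,
                     end = pmin(seq_len(n) * track$bin_size,
                                track$contig_length)),
    score = track$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write alignments as minimal SAM
#'
#' `@SQ` header plus the mandatory 11 fields; sequence and quality are
#' omitted (`*`) since placements, not bases, are the downstream input.
#'
#' @param aln a `cw_alignments` object.
#' @param contig_lengths named vector of reference contig lengths.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  if (nrow(aln)) {
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    writeLines(sprintf("%s/%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       aln$id, aln$mate, flag, aln$contig, aln$start,
                       aln$end - aln$start + 1L, aln$n_mismatch), con)
  }
  invisible(path)
}
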