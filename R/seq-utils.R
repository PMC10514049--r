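#' cenwalk: chromosome walking assembly and CENP-A domain mapping
#'
#' Tools for resolving misassembled satellite-free centromeric loci by
#' iterative chromosome walking, patching a reference with a coordinate
#' liftover map, profiling CENP-A ChIP-seq enrichment (RPKM-subtractive),
#' calling broad enrichment islands, and testing whether the CENP-A domain
#' position is conserved across tissues.
#'
#' @keywords internal
#' @import Biostrings
#' @importFrom data.table data.table setkey setkeyv := .N .SD setorder rbindlist as.data.table
#' @importFrom stats runif rexp rbinom ppois p.adjust median setNames
#' @importFrom utils write.table read.table
"_PACKAGE"

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Validate a DNA sequence string
#'
#' @param seq character scalar or vector.
#' @param allow_n allow the ambiguity base N.
#' @return invisibly, `seq`.
#' @keywords internal
check_dna <- function(seq, allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T", if (allow_n) ",N", "}")
  }
  invisible(seq)
}

#' Reverse complement of DNA sequences
#'
#' Vectorised over a character vector; the alphabet is restricted to
#' {A,C,G,T,N} and N maps to N.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(seq) {
  check_dna(seq)
  rc_(seq)
}

## internal reverse complement without alphabet validation (hot path)
rc_ <- function(seq) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))))
}

## Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## Derive a reproducible sub-seed (< 2^31) from a base seed and a label.
derive_seed <- function(seed, label) {
  ch <- utf8ToInt(as.character(label))
  h <- sum(ch * seq_along(ch))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector as FASTA (line width 60)
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)), all(nzchar(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair table
#'
#' Mates are matched by id after stripping a trailing `/1` or `/2`.
#'
#' @param r1,r2 FASTQ (optionally gzipped) files for mate 1 and mate 2.
#' @return a `cw_pairs` data.frame with columns id, mate1, mate2.
#' @export
read_fastq_pairs <- function(r1, r2) {
  m1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  m2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  id1 <- sub("/[12]$", "", sub("\\s.*$", "", names(m1)))
  id2 <- sub("/[12]$", "", sub("\\s.*$", "", names(m2)))
  pairs_table(id1, as.character(m1), as.character(m2)[match(id1, id2)])
}

pairs_table <- function(id, mate1, mate2) {
  stopifnot(!anyNA(mate1), !anyNA(mate2))
  out <- data.frame(id = id, mate1 = unname(mate1), mate2 = unname(mate2),
                    stringsAsFactors = FALSE)
  class(out) <- c("cw_pairs", "data.frame")
  out
}

#' Write a read-pair table as a pair of gzipped FASTQ files
#'
#' @param pairs a `cw_pairs` data.frame (columns id, mate1, mate2).
#' @param prefix output prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_R1.fastq.gz")
  p2 <- paste0(prefix, "_R2.fastq.gz")
  m1 <- Biostrings::DNAStringSet(setNames(pairs$mate1, pairs$id))
  m2 <- Biostrings::DNAStringSet(setNames(pairs$mate2, pairs$id))
  Biostrings::writeXStringSet(m1, p1, format = "fastq", compress = TRUE)
  Biostrings::writeXStringSet(m2, p2, format = "fastq", compress = TRUE)
  invisible(c(p1, p2))
}
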