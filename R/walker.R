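## Iterative chromosome walker: design a query from the end of a known
## sequence, retrieve every joined read containing it verbatim (either mate,
## either orientation), extend the consensus by majority vote, redesign the
## query on the new end, repeat. Gaps are closed by walking inward from both
## flanks until the two consensi overlap exactly.

#' Walking-assembler parameters
#'
#' `query_len` defaults to 60 nt, the short end of the 60-95 nt query range:
#' with 75-nt mates a query can only be extended by reads that contain it
#' with room to spare, so shorter queries leave more extension per step.
#'
#' @param query_len query length in nt (60-95 recommended; outside that range
#'   the search warns).
#' @param min_support minimum number of reads covering a column for it to be
#'   emitted.
#' @param min_agreement minimum majority fraction at a column (in (0.5, 1]).
#' @param branch_fraction if two bases each reach this fraction of a
#'   well-covered column, the walk stops and reports a branch instead of
#'   choosing silently.
#' @param max_iterations cap on find/extend cycles per walk.
#' @param min_merge_overlap exact suffix/prefix overlap (nt) required to close
#'   a gap between two inward walks.
#' @param min_query_len when a step yields no extension (too few reads hold
#'   the full query with room to spare), the step is retried with shorter
#'   queries down to this floor - the in-silico analogue of varying the query
#'   length when a walk stalls. Set equal to `query_len` to disable.
#' @return a `cw_walkparams` list.
#' @export
walk_params <- function(query_len = 60L, min_support = 5L, min_agreement = 0.8,
                        branch_fraction = 0.3, max_iterations = 500L,
                        min_merge_overlap = 100L, min_query_len = 40L) {
  stopifnot(min_agreement > 0.5, min_agreement <= 1,
            branch_fraction < min_agreement, query_len >= 1,
            min_support >= 1, max_iterations >= 1, min_merge_overlap >= 1,
            min_query_len >= 1, min_query_len <= query_len)
  structure(list(query_len = as.integer(query_len),
                 min_support = as.integer(min_support),
                 min_agreement = min_agreement,
                 branch_fraction = branch_fraction,
                 max_iterations = as.integer(max_iterations),
                 min_merge_overlap = as.integer(min_merge_overlap),
                 min_query_len = as.integer(min_query_len)),
            class = "cw_walkparams")
}

#' Join mate pairs into searchable units
#'
#' One `JoinedRead` per pair; both mates remain independently searchable
#' (mate-pair distance is not used). Accepts a `cw_pairs` table, a
#' `cw_readset`, or two parallel character vectors.
#'
#' @param pairs a `cw_pairs` data.frame / `cw_readset`, or mate-1 sequences.
#' @param mate2 mate-2 sequences when `pairs` is a character vector.
#' @param id pair ids (defaults to an index).
#' @return a `cw_joined` object holding the pair table and a preindexed
#'   [Biostrings::DNAStringSet] of all mates.
#' @export
join_pairs <- function(pairs, mate2 = NULL, id = NULL) {
  if (inherits(pairs, "cw_readset")) pairs <- pairs$pairs
  if (is.character(pairs)) {
    if (is.null(mate2)) stop("mate2 required when pairs is a character vector")
    if (length(pairs) != length(mate2))
      stop("orphan mates: mate1 and mate2 differ in length")
    if (is.null(id)) id <- sprintf("pair_%06d", seq_along(pairs))
    pairs <- pairs_table(id, pairs, mate2)
  }
  if (anyNA(pairs$mate1) || anyNA(pairs$mate2) ||
      any(!nzchar(pairs$mate1)) || any(!nzchar(pairs$mate2))) {
    bad <- pairs$id[is.na(pairs$mate1) | is.na(pairs$mate2) |
                    !nzchar(pairs$mate1) | !nzchar(pairs$mate2)]
    stop("orphan mates for ids: ", paste(head(bad, 10), collapse = ", "))
  }
  n <- nrow(pairs)
  seqs <- c(pairs$mate1, pairs$mate2)
  # all mates concatenated with N separators: one fixed-string search scans
  # the whole library, and a query without N can never match across an N
  structure(list(pairs = pairs,
                 seqs = seqs,
                 mate_id = rep(pairs$id, 2L),
                 mate_no = rep(c(1L, 2L), each = n),
                 super = paste(seqs, collapse = "N"),
                 starts = cumsum(c(1L, nchar(seqs) + 1L))[seq_len(2L * n)]),
            class = "cw_joined")
}

#' @export
length.cw_joined <- function(x) nrow(x$pairs)

#' Find all exact occurrences of a query in the joined reads
#'
#' Reports every exact occurrence of `query`, or of its reverse complement,
#' in either mate of every joined read; deduplicated and ordered by read id,
#' mate, offset.
#'
#' @param query query string (60-95 nt recommended; no N).
#' @param joined a [join_pairs()] object.
#' @return data.frame with columns id, mate, offset (0-based position of the
#'   match in the mate as stored) and orientation (`"F"` forward,
#'   `"R"` reverse-complement).
#' @export
find_reads_by_query <- function(query, joined) {
  stopifnot(inherits(joined, "cw_joined"))
  if (grepl("N", query, fixed = TRUE)) stop("query contains N: cannot anchor")
  check_dna(query, allow_n = FALSE)
  qlen <- nchar(query)
  if (qlen < 60 || qlen > 95)
    warning("query length ", qlen, " outside the recommended 60-95 nt range")
  hit_one <- function(pat, orient) {
    g <- gregexpr(pat, joined$super, fixed = TRUE)[[1]]
    if (g[1] == -1L) return(NULL)
    pos <- as.integer(g)
    idx <- findInterval(pos, joined$starts)
    data.frame(id = joined$mate_id[idx], mate = joined$mate_no[idx],
               offset = pos - joined$starts[idx], orientation = orient,
               stringsAsFactors = FALSE)
  }
  out <- rbind(hit_one(query, "F"), hit_one(revcomp(query), "R"))
  if (is.null(out)) {
    return(data.frame(id = character(), mate = integer(), offset = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out[order(out$id, out$mate, out$offset, out$orientation), , drop = FALSE]
}

## Pull, for each hit, the mate oriented so the query reads forward, plus the
## tail extending rightward past the query occurrence.
hit_tails <- function(anchor, hits, joined) {
  qlen <- nchar(anchor)
  n <- nrow(joined$pairs)
  seqs <- joined$seqs[match(hits$id, joined$pairs$id) + (hits$mate - 1L) * n]
  len <- nchar(seqs)
  fwd <- hits$orientation == "F"
  oriented <- seqs
  off <- hits$offset  # 0-based start in stored mate
  if (any(!fwd)) {
    oriented[!fwd] <- rc_(seqs[!fwd])
    # revcomp(query) matched at [off+1, off+qlen]; in oriented coords the
    # forward query starts at len - (off + qlen) (0-based)
    off[!fwd] <- len[!fwd] - (hits$offset[!fwd] + qlen)
  }
  substr(oriented, off + qlen + 1L, len)
}

#' Extend a consensus past an anchor by majority vote
#'
#' Reads are oriented so the anchor matches forward; for every column beyond
#' it, the majority base is emitted while coverage stays at or above
#' `min_support` and the majority fraction at or above `min_agreement`. If two
#' bases each reach `branch_fraction` of a well-covered column the extension
#' stops there and the base counts are reported as a branch event.
#'
#' @param anchor the current consensus end (the query that produced `hits`).
#' @param hits data.frame from [find_reads_by_query()].
#' @param joined a [join_pairs()] object.
#' @param params a [walk_params()] object.
#' @return list with `extension` (string, possibly empty), `support`
#'   (integer coverage per emitted column) and `branch` (`NULL` or
#'   `list(position, counts)` where position is 1-based past the anchor).
#' @export
extend_consensus <- function(anchor, hits, joined, params = walk_params()) {
  if (nrow(hits) == 0) stop("walk stalled: no reads contain the query")
  tails <- hit_tails(anchor, hits, joined)
  tails <- tails[nzchar(tails)]
  ext <- character(0); support <- integer(0); branch <- NULL
  if (length(tails)) {
    tlen <- nchar(tails)
    for (j in seq_len(max(tlen))) {
      bases <- substr(tails[tlen >= j], j, j)
      cov <- length(bases)
      if (cov < params$min_support) break
      counts <- sort(table(bases), decreasing = TRUE)
      top <- counts[1] / cov
      big <- sum(counts / cov >= params$branch_fraction)
      if (big >= 2) {
        branch <- list(position = j, counts = counts)
        break
      }
      if (top < params$min_agreement) break
      ext[j] <- names(counts)[1]
      support[j] <- cov
    }
  }
  list(extension = paste(ext, collapse = ""), support = support, branch = branch)
}

## One find+extend step rightward from the end of `consensus`. A step that
## yields no extension at the nominal query length is retried with shorter
## queries (down to min_query_len), which admit more reads with bases to
## spare past the frontier.
walk_step <- function(consensus, joined, params) {
  n <- nchar(consensus)
  for (qlen in unique(c(seq(params$query_len, params$min_query_len, by = -10L),
                        params$min_query_len))) {
    qlen <- min(qlen, n)
    query <- substr(consensus, n - qlen + 1L, n)
    hits <- suppressWarnings(find_reads_by_query(query, joined))
    if (nrow(hits) == 0) next
    ex <- extend_consensus(query, hits, joined, params)
    if (!is.null(ex$branch))
      return(list(consensus = paste0(consensus, ex$extension), grew = nzchar(ex$extension),
                  status = "branched", support = ex$support, branch = ex$branch))
    if (nzchar(ex$extension))
      return(list(consensus = paste0(consensus, ex$extension), grew = TRUE,
                  status = "ok", support = ex$support, branch = NULL))
  }
  list(consensus = consensus, grew = FALSE, status = "open",
       support = integer(0), branch = NULL)
}

#' Walk outward from a seed query
#'
#' Repeats find -> extend -> redesign-query (the distal `query_len` bases of
#' the growing consensus). Leftward walks run on the reverse complement and
#' are flipped back at the end.
#'
#' @param joined a [join_pairs()] object.
#' @param seed_query starting query (found verbatim in the reads or an error
#'   is raised).
#' @param direction `"rightward"` or `"leftward"`.
#' @param params a [walk_params()] object.
#' @return a `cw_walk` result: list with `sequence`, `status` (`"open"`,
#'   `"branched"` or `"max_iter"`), `iterations`, `support` (coverage of every
#'   extended column, in final-sequence orientation) and `branch_events`.
#' @export
walk <- function(joined, seed_query, direction = c("rightward", "leftward"),
                 params = walk_params()) {
  direction <- match.arg(direction)
  seed0 <- if (direction == "leftward") revcomp(seed_query) else seed_query
  pre <- suppressWarnings(find_reads_by_query(seed0, joined))
  if (nrow(pre) == 0) stop("seed query not found in reads")
  consensus <- seed0
  support <- integer(0); branches <- list(); status <- "max_iter"; it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    st <- walk_step(consensus, joined, params)
    if (length(st$support))
      support <- c(support, st$support)
    if (!is.null(st$branch)) {
      st$branch$position <- nchar(st$consensus) + 1L
      branches[[length(branches) + 1L]] <- st$branch
    }
    consensus <- st$consensus
    if (st$status != "ok") { status <- st$status; break }
  }
  if (direction == "leftward") {
    consensus <- revcomp(consensus)
    support <- rev(support)
    branches <- lapply(branches, function(b) {
      b$position <- nchar(consensus) - b$position + 1L; b
    })
  }
  structure(list(sequence = consensus, status = status, iterations = it,
                 support = support, branch_events = branches),
            class = "cw_walk")
}

## Largest k >= min_overlap with suffix_k(left) == prefix_k(right); 0 if none.
suffix_prefix_overlap <- function(left, right, min_overlap) {
  nl <- nchar(left); nr <- nchar(right)
  if (nl < min_overlap || nr < min_overlap) return(0L)
  probe <- substr(left, nl - min_overlap + 1L, nl)
  occ <- gregexpr(probe, right, fixed = TRUE)[[1]]
  if (occ[1] == -1L) return(0L)
  best <- 0L
  for (p in occ) {
    k <- p + min_overlap - 1L
    if (k <= nl && k <= nr &&
        substr(right, 1L, k) == substr(left, nl - k + 1L, nl))
      best <- max(best, k)
  }
  best
}

#' Close a gap by walking inward from both flanks
#'
#' Walks rightward from `left_flank` and leftward from `right_flank`,
#' checking after every extension whether a suffix of the left consensus
#' equals a prefix of the right consensus over at least `min_merge_overlap`
#' exactly matching bases. On success the merged, gap-free sequence spanning
#' flank to flank is returned.
#'
#' @param left_flank,right_flank trusted sequence on either side of the gap
#'   (each at least `query_len` long).
#' @param joined a [join_pairs()] object.
#' @param params a [walk_params()] object.
#' @return list with `status` (`"closed"` or `"open"`), `sequence` (merged
#'   sequence when closed, else `NULL`), `overlap` (nt merged across), and the
#'   two walk states `left` and `right`.
#' @export
close_gap <- function(left_flank, right_flank, joined, params = walk_params()) {
  qlen <- params$query_len
  if (nchar(left_flank) < qlen || nchar(right_flank) < qlen)
    stop("flanks must be at least query_len long")
  Lcons <- left_flank
  Rrc <- revcomp(right_flank)   # right walk proceeds rightward on the revcomp
  l_live <- TRUE; r_live <- TRUE
  l_status <- "open"; r_status <- "open"; it <- 0L

  try_merge <- function() {
    k <- suffix_prefix_overlap(Lcons, rc_(Rrc), params$min_merge_overlap)
    if (k == 0L) return(NULL)
    R <- rc_(Rrc)
    paste0(Lcons, substr(R, k + 1L, nchar(R)))
  }

  merged <- try_merge()
  while (is.null(merged) && (l_live || r_live) && it < params$max_iterations) {
    it <- it + 1L
    if (l_live) {
      st <- walk_step(Lcons, joined, params)
      Lcons <- st$consensus
      if (st$status != "ok") { l_live <- FALSE; l_status <- st$status }
      if (st$grew) merged <- try_merge()
    }
    if (is.null(merged) && r_live) {
      st <- walk_step(Rrc, joined, params)
      Rrc <- st$consensus
      if (st$status != "ok") { r_live <- FALSE; r_status <- st$status }
      if (st$grew) merged <- try_merge()
    }
  }
  left_state <- list(sequence = Lcons, status = if (l_live) "max_iter" else l_status)
  right_state <- list(sequence = rc_(Rrc),
                      status = if (r_live) "max_iter" else r_status)
  if (!is.null(merged)) {
    list(status = "closed", sequence = merged,
         overlap = suffix_prefix_overlap(Lcons, right_state$sequence,
                                         params$min_merge_overlap),
         iterations = it, left = left_state, right = right_state)
  } else {
    list(status = "open", sequence = NULL, overlap = 0L, iterations = it,
         left = left_state, right = right_state)
  }
}

#' Rebuild a misassembled interval of a draft contig from raw reads
#'
#' Takes trusted flanks of `query_len` bases immediately outside `interval`,
#' closes the intervening region with [close_gap()], and splices the walked
#' sequence back into the draft. A false tandem duplication collapses to a
#' single copy when the reads support only one junction.
#'
#' @param draft draft contig sequence (character scalar).
#' @param interval `c(start, end)` 1-based inclusive region to rebuild.
#' @param joined a [join_pairs()] object built from raw reads.
#' @param params a [walk_params()] object.
#' @return list with `status` (`"resolved"` or `"open"`), `contig` (the
#'   corrected contig when resolved, else `NULL`) and `walk` (the
#'   [close_gap()] result).
#' @export
resolve_region <- function(draft, interval, joined, params = walk_params()) {
  L <- nchar(draft); qlen <- params$query_len
  s <- interval[1]; e <- interval[2]
  stopifnot(s >= 1, s <= e, e <= L)
  if (s - qlen < 1 || e + qlen > L)
    stop("interval leaves less than query_len of trusted flank on one side")
  left_flank <- substr(draft, s - qlen, s - 1L)
  right_flank <- substr(draft, e + 1L, e + qlen)
  cg <- close_gap(left_flank, right_flank, joined, params)
  if (cg$status != "closed")
    return(list(status = "open", contig = NULL, walk = cg))
  contig <- paste0(substr(draft, 1L, s - qlen - 1L), cg$sequence,
                   substr(draft, e + qlen + 1L, L))
  list(status = "resolved", contig = contig, walk = cg)
}
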