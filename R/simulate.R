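## Synthetic-data generator: a unique (satellite-free) centromeric locus, a
## corrupted draft reference (false tandem duplication + N-gaps + unplaced
## duplicate contig), and seeded WGS / ChIP / input / long-read sets with
## per-homolog CENP-A domains across simulated tissues.

#' Read-simulation parameters
#'
#' Paired-end fragments are drawn uniformly from 200-800 bp (the sonication
#' range of the emulated libraries) and sequenced as `read_len`-nt mates from
#' either end. Errors are substitutions only.
#'
#' @param read_len read length in nt.
#' @param frag_min,frag_max fragment length range in bp; `frag_min` must be at
#'   least `read_len`.
#' @param depth fold sequence coverage the library should reach.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed; all simulation is deterministic given it.
#' @return a `cw_readsim` parameter list.
#' @export
read_sim_params <- function(read_len = 75L, frag_min = 200L, frag_max = 800L,
                            depth = 30, error_rate = 0, seed = 1L) {
  stopifnot(frag_min >= read_len, frag_max >= frag_min,
            error_rate >= 0, error_rate < 1, depth > 0)
  structure(list(read_len = as.integer(read_len), frag_min = as.integer(frag_min),
                 frag_max = as.integer(frag_max), depth = depth,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "cw_readsim")
}

#' Per-homolog CENP-A domain specification
#'
#' Each homolog carries one CENP-A binding interval on the true locus;
#' distinct intervals model positional epialleles. ChIP fragments whose
#' midpoint falls inside the chosen homolog's domain are sampled with weight
#' `fold`, all other positions with weight 1 (plateau model).
#'
#' @param hom1,hom2 1-based inclusive `c(start, end)` intervals.
#' @param fold enrichment fold (>= 1) inside the domain.
#' @param mixture probability that a fragment derives from homolog 1.
#' @return a `cw_domainspec` list.
#' @export
domain_spec <- function(hom1, hom2 = hom1, fold = 8, mixture = 0.5) {
  stopifnot(length(hom1) == 2, length(hom2) == 2,
            hom1[1] >= 1, hom1[1] <= hom1[2], hom2[1] >= 1, hom2[1] <= hom2[2],
            mixture >= 0, mixture <= 1)
  if (fold < 1) stop("enrichment fold must be >= 1")
  structure(list(hom1 = as.integer(hom1), hom2 = as.integer(hom2),
                 fold = fold, mixture = mixture),
            class = "cw_domainspec")
}

#' Generate a random satellite-free locus
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc`; such a sequence is unique
#' (repeat-free) with overwhelming probability at the k-mer sizes the walker
#' and aligner use, standing in for a satellite-free centromeric region.
#'
#' @param length locus length in nt (>= 1000).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a character scalar over `{A,C,G,T}`.
#' @export
make_true_locus <- function(length, gc = 0.42, seed = 1L) {
  if (length < 1000) stop("locus length must be >= 1000 nt")
  stopifnot(gc >= 0, gc <= 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Corrupt a true locus into a misassembled draft reference
#'
#' Reproduces the anatomy of the misassembly the pipeline is designed to fix:
#' the `dup` block is falsely duplicated in tandem, the two copies separated
#' by the first gap's N-run; any further gaps are inserted as N-runs at the
#' stated (true-locus) positions; optionally an unplaced contig identical to
#' the duplicated block is emitted.
#'
#' @param locus true locus sequence (character scalar).
#' @param dup `c(start, end)` 1-based inclusive block to duplicate, or `NULL`.
#' @param gaps list of `c(position, length)` N-run insertions (position on the
#'   true locus; the run is inserted after that position). When `dup` is given
#'   the first gap separates the two copies.
#' @param emit_unplaced also return an unplaced contig equal to the block.
#' @param contig_name,unplaced_name contig ids for the output.
#' @return list with `contigs` (named character vector) and `map`, a block
#'   table (data.frame: old_start, old_end, new_start, new_end, type) relating
#'   true-locus to corrupted-contig coordinates.
#' @export
corrupt_reference <- function(locus, dup = NULL, gaps = list(),
                              emit_unplaced = FALSE,
                              contig_name = "chrS", unplaced_name = "unplaced") {
  check_dna(locus)
  L <- nchar(locus)
  if (!is.null(dup)) {
    stopifnot(length(dup) == 2, dup[1] >= 1, dup[1] <= dup[2], dup[2] <= L)
    if (length(gaps) == 0)
      stop("a duplication requires at least one gap (the between-copy N-run)")
  }
  for (g in gaps) {
    stopifnot(length(g) == 2, g[2] >= 1, g[1] >= 0, g[1] <= L)
    if (!is.null(dup) && g[1] >= dup[1] && g[1] < dup[2])
      stop("gap placement overlaps the duplicated block")
  }

  blocks <- list()  # accumulated (old_start, old_end, new_start, new_end, type)
  pieces <- character()
  new_at <- 0L
  add <- function(os, oe, type, seq) {
    n <- nchar(seq)
    blocks[[length(blocks) + 1L]] <<- data.frame(
      old_start = os, old_end = oe, new_start = new_at + 1L,
      new_end = new_at + n, type = type)
    pieces[[length(pieces) + 1L]] <<- seq
    new_at <<- new_at + n
  }

  rest_gaps <- gaps
  if (!is.null(dup)) {
    gap1 <- gaps[[1]]
    rest_gaps <- gaps[-1]
    add(1L, dup[2], "match", substr(locus, 1, dup[2]))
    add(NA, NA, "gap", strrep("N", gap1[2]))
    add(dup[1], dup[2], "dup_copy", substr(locus, dup[1], dup[2]))
    tail_start <- dup[2] + 1L
  } else {
    tail_start <- 1L
  }
  # remaining sequence, with residual gaps inserted at their true positions
  pos <- tail_start
  if (length(rest_gaps)) {
    ord <- order(vapply(rest_gaps, `[`, numeric(1), 1))
    rest_gaps <- rest_gaps[ord]
    for (g in rest_gaps) {
      if (g[1] < pos) stop("gap placements overlap the duplicated block or each other")
      if (g[1] >= pos) {
        add(pos, g[1], "match", substr(locus, pos, g[1]))
        add(NA, NA, "gap", strrep("N", g[2]))
        pos <- g[1] + 1L
      }
    }
  }
  if (pos <= L) add(pos, L, "match", substr(locus, pos, L))

  contigs <- c(paste(pieces, collapse = ""))
  names(contigs) <- contig_name
  if (emit_unplaced) {
    if (is.null(dup)) stop("emit_unplaced requires a duplicated block")
    contigs[unplaced_name] <- substr(locus, dup[1], dup[2])
  }
  map <- do.call(rbind, blocks)
  map$contig <- contig_name
  list(contigs = contigs, map = map)
}

## Vectorised substitution-error injection; never produces N, never mutates N.
add_substitutions <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), error_rate)
  hit <- which(n_err > 0)
  if (!length(hit)) return(reads)
  read_i <- rep.int(hit, n_err[hit])
  pos <- 1L + floor(runif(length(read_i)) * nchar(reads)[read_i])
  old <- substring(reads[read_i], pos, pos)
  # substitute with one of the three other bases, chosen uniformly
  bases <- c("A", "C", "G", "T")
  shift <- 1L + floor(runif(length(read_i)) * 3)
  new <- bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
  keep <- old != "N"
  read_i <- read_i[keep]; pos <- pos[keep]; new <- new[keep]
  for (j in seq_along(read_i)) {
    i <- read_i[j]
    substr(reads[i], pos[j], pos[j]) <- new[j]
  }
  reads
}

## Build mates + origin records from fragment coordinates on one contig.
fragments_to_pairs <- function(genome_seq, contig, fstart, flen, p, id_prefix) {
  frag <- substring(genome_seq, fstart, fstart + flen - 1L)
  rl <- p$read_len
  mate1 <- substr(frag, 1L, rl)
  mate2 <- rc_(substring(frag, flen - rl + 1L, flen))
  mate1 <- add_substitutions(mate1, p$error_rate)
  mate2 <- add_substitutions(mate2, p$error_rate)
  id <- paste0(id_prefix, "_", seq_along(fstart))
  origins <- data.frame(
    id = rep(id, 2L), mate = rep(c(1L, 2L), each = length(id)),
    contig = contig,
    start = c(fstart, fstart + flen - rl),
    strand = rep(c("+", "-"), each = length(id)),
    stringsAsFactors = FALSE)
  list(pairs = pairs_table(id, mate1, mate2), origins = origins)
}

#' Simulate whole-genome paired-end reads
#'
#' Fragments are uniform over positions; mate 1 is the fragment's 5' end,
#' mate 2 the reverse complement of its 3' end. The pair count is
#' `round(depth * total_length / (2 * read_len))`.
#'
#' @param genome named character vector of contigs, each at least
#'   `frag_max` long.
#' @param p a [read_sim_params()] object.
#' @param id_prefix read-id prefix.
#' @return a `cw_readset`: list with `pairs` (a `cw_pairs` data.frame) and
#'   `origins` (data.frame id, mate, contig, start, strand).
#' @export
simulate_wgs_pairs <- function(genome, p = read_sim_params(), id_prefix = "wgs") {
  stopifnot(length(genome) >= 1, !is.null(names(genome)))
  if (any(nchar(genome) < p$frag_max))
    stop("every contig must be at least frag_max long")
  total_len <- sum(nchar(genome))
  n_pairs <- round(p$depth * total_len / (2 * p$read_len))
  with_seed(p$seed, {
    ctg <- sample(names(genome), n_pairs, replace = TRUE,
                  prob = nchar(genome) / total_len)
    flen <- p$frag_min + sample.int(p$frag_max - p$frag_min + 1L, n_pairs,
                                    replace = TRUE) - 1L
    out <- vector("list", length(genome))
    k <- 0L
    for (nm in names(genome)) {
      sel <- which(ctg == nm)
      if (!length(sel)) next
      L <- nchar(genome[[nm]])
      fstart <- 1L + floor(runif(length(sel)) * (L - flen[sel] + 1L))
      k <- k + 1L
      out[[k]] <- fragments_to_pairs(genome[[nm]], nm, fstart, flen[sel], p,
                                     paste0(id_prefix, "_", nm))
    }
    out <- out[seq_len(k)]
    pr <- do.call(rbind, lapply(out, function(x) as.data.frame(x$pairs)))
    structure(list(pairs = pairs_table(pr$id, pr$mate1, pr$mate2),
                   origins = do.call(rbind, lapply(out, `[[`, "origins"))),
              class = "cw_readset")
  })
}

## Weighted fragment-start sampler for one homolog's domain (plateau model):
## starts whose midpoint is inside [ds, de] have weight fold, others weight 1.
sample_domain_starts <- function(L, flen, ds, de, fold) {
  half <- flen %/% 2L
  lo <- pmax(ds - half, 1L)
  hi <- pmin(de - half, L - flen + 1L)
  n_in <- pmax(hi - lo + 1L, 0L)
  n_tot <- L - flen + 1L
  n_out <- n_tot - n_in
  p_in <- (n_in * fold) / (n_in * fold + n_out)
  inside <- runif(length(flen)) < p_in
  start <- integer(length(flen))
  if (any(inside))
    start[inside] <- lo[inside] + floor(runif(sum(inside)) * n_in[inside])
  if (any(!inside)) {
    r <- 1L + floor(runif(sum(!inside)) * n_out[!inside])  # rank among outside starts
    lo_o <- lo[!inside]
    start[!inside] <- ifelse(r < lo_o, r, r + n_in[!inside])
  }
  start
}

#' Simulate CENP-A ChIP paired-end reads with per-homolog domains
#'
#' A homolog is chosen per fragment with probability `mixture` (homolog 1);
#' fragment starts are sampled with weight `fold` when the fragment midpoint
#' lies in that homolog's CENP-A domain, weight 1 otherwise.
#'
#' @param locus true locus sequence (character scalar).
#' @param d a [domain_spec()].
#' @param p a [read_sim_params()].
#' @param id_prefix read-id prefix.
#' @param contig_name contig id recorded in the origins table.
#' @return a `cw_readset` (see [simulate_wgs_pairs()]).
#' @export
simulate_chip_pairs <- function(locus, d, p = read_sim_params(),
                                id_prefix = "chip", contig_name = "locus") {
  stopifnot(inherits(d, "cw_domainspec"))
  L <- nchar(locus)
  if (d$hom1[2] > L || d$hom2[2] > L) stop("domain outside locus")
  if (L < p$frag_max) stop("locus shorter than frag_max")
  n_pairs <- round(p$depth * L / (2 * p$read_len))
  with_seed(p$seed, {
    flen <- p$frag_min + sample.int(p$frag_max - p$frag_min + 1L, n_pairs,
                                    replace = TRUE) - 1L
    hom1 <- runif(n_pairs) < d$mixture
    start <- integer(n_pairs)
    if (any(hom1))
      start[hom1] <- sample_domain_starts(L, flen[hom1], d$hom1[1], d$hom1[2], d$fold)
    if (any(!hom1))
      start[!hom1] <- sample_domain_starts(L, flen[!hom1], d$hom2[1], d$hom2[2], d$fold)
    out <- fragments_to_pairs(locus, contig_name, start, flen, p, id_prefix)
    structure(out, class = "cw_readset")
  })
}

#' Simulate a multi-tissue ChIP/input panel
#'
#' Each tissue uses the base domains translated by `slides[tissue]` bp; the
#' matched input library is simulated with fold 1 (no enrichment). Per-tissue
#' seeds are derived deterministically from `p$seed`.
#'
#' @param locus true locus sequence.
#' @param base a [domain_spec()] shared by all tissues before sliding.
#' @param slides named numeric vector, tissue -> offset in bp (0 = conserved).
#' @param p a [read_sim_params()].
#' @return a `cw_panel`: list with `tissues` (per-tissue list of `chip` and
#'   `input` read sets) and `truth` (per-tissue [domain_spec()]).
#' @export
make_tissue_panel <- function(locus, base, slides, p = read_sim_params()) {
  stopifnot(inherits(base, "cw_domainspec"), length(slides) >= 1,
            !is.null(names(slides)))
  L <- nchar(locus)
  tissues <- list(); truth <- list()
  for (t in names(slides)) {
    off <- as.integer(slides[[t]])
    d <- domain_spec(base$hom1 + off, base$hom2 + off, base$fold, base$mixture)
    if (d$hom1[1] < 1 || d$hom1[2] > L || d$hom2[1] < 1 || d$hom2[2] > L)
      stop("slid domain out of locus bounds for tissue ", t)
    p_chip <- p; p_chip$seed <- derive_seed(p$seed, paste0("chip_", t))
    p_inp <- p; p_inp$seed <- derive_seed(p$seed, paste0("input_", t))
    flat <- domain_spec(d$hom1, d$hom2, fold = 1, mixture = d$mixture)
    tissues[[t]] <- list(
      chip  = simulate_chip_pairs(locus, d, p_chip, id_prefix = paste0("chip_", t)),
      input = simulate_chip_pairs(locus, flat, p_inp, id_prefix = paste0("input_", t)))
    truth[[t]] <- d
  }
  structure(list(tissues = tissues, truth = truth), class = "cw_panel")
}

#' Simulate long reads (PacBio-like, substitution errors only)
#'
#' Read lengths are exponential around `mean_len`, truncated to
#' `[1000, contig length]`; starts uniform; strands random.
#'
#' @param genome named character vector of contigs.
#' @param mean_len mean read length (>= 1000 nt).
#' @param depth fold coverage.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `origins`
#'   (data.frame id, contig, start, strand).
#' @export
simulate_long_reads <- function(genome, mean_len = 5000, depth = 20,
                                error_rate = 0, seed = 1L) {
  if (mean_len < 1000) stop("mean_len must be >= 1000")
  stopifnot(!is.null(names(genome)))
  total_len <- sum(nchar(genome))
  n <- max(1L, round(depth * total_len / mean_len))
  with_seed(seed, {
    ctg <- sample(names(genome), n, replace = TRUE, prob = nchar(genome) / total_len)
    len <- pmin(pmax(round(rexp(n, 1 / mean_len)), 1000L), nchar(genome)[ctg])
    start <- 1L + floor(runif(n) * (nchar(genome)[ctg] - len + 1L))
    fwd <- runif(n) < 0.5
    reads <- substring(genome[ctg], start, start + len - 1L)
    reads[!fwd] <- rc_(reads[!fwd])
    reads <- add_substitutions(reads, error_rate)
    id <- sprintf("long_%05d", seq_len(n))
    names(reads) <- id
    list(reads = reads,
         origins = data.frame(id = id, contig = unname(ctg), start = unname(start),
                              strand = ifelse(fwd, "+", "-"),
                              stringsAsFactors = FALSE))
  })
}

#' Write a read-origin truth table
#'
#' Plain text: read_id TAB contig TAB start TAB strand (and mate when
#' present).
#'
#' @param origins origins data.frame from a simulator.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_truth_table <- function(origins, path) {
  write.table(origins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
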