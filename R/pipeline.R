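## End-to-end orchestration: simulate -> walk -> patch -> profile ->
## callpeaks -> compare, with one seeded config, per-stage derived seeds,
## and a run manifest of output files and md5 hashes.

#' Build a pipeline configuration
#'
#' Every parameter has a default; the effective configuration is serialized
#' next to the outputs. Sizes default to a desk-scale mirror of the study
#' design: a unique locus corrupted by a false tandem duplication plus an
#' N-gap and an unplaced duplicate contig, ChIP/input libraries over a broad
#' CENP-A domain, and a multi-tissue panel.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param locus_len,gc true locus length and GC content.
#' @param dup,gaps corruption layout (see [corrupt_reference()]).
#' @param domain,fold CENP-A domain interval and enrichment fold.
#' @param tissues named vector of per-tissue slides (bp).
#' @param depth,read_len,frag_min,frag_max,error_rate read simulation.
#' @param long_depth,long_mean long-read simulation.
#' @param walk a [walk_params()].
#' @param islands an [island_params()].
#' @param bin_size profile bin size (bp).
#' @param seed_len,max_mismatch aligner settings.
#' @param stages character vector of stages to run.
#' @return a `cw_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            locus_len = 40000L, gc = 0.42,
                            dup = c(17001L, 19000L), gaps = list(c(0L, 1000L)),
                            domain = c(14001L, 22000L), fold = 8,
                            tissues = c(fibroblast = 0, brain = 0, lamina = 0,
                                        liver = 0, testis = 0),
                            depth = 30, read_len = 75L,
                            frag_min = 200L, frag_max = 800L, error_rate = 0.001,
                            long_depth = 20, long_mean = 5000,
                            walk = walk_params(), islands = island_params(),
                            bin_size = 50L, seed_len = 30L, max_mismatch = 3L,
                            stages = c("simulate", "walk", "patch", "profile",
                                       "callpeaks", "compare")) {
  structure(as.list(environment()), class = "cw_config")
}

write_config <- function(config, path) {
  flat <- function(x, prefix = "") {
    out <- character()
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(v)) out <- c(out, flat(v, key))
      else out <- c(out, paste0(key, " = ", paste(v, collapse = ",")))
    }
    out
  }
  writeLines(flat(unclass(config)), path)
  invisible(path)
}

#' Profile the same ChIP/input reads on two references
#'
#' Maps identical reads to the old (e.g. corrupted) and new (corrected)
#' references and reports, per reference: the uniquely-mapped fraction, the
#' ChIP-minus-input difference track, the called domain, and the in-domain
#' dip count (bins inside the called domain whose signal falls below 10% of
#' the domain's median signal).
#'
#' @param chip_reads,input_reads `cw_readset`s (or pair tables).
#' @param ref_old,ref_new named character vectors (single- or multi-contig);
#'   the locus contig is taken as the first.
#' @param bin_size profile bin size.
#' @param seed_len,max_mismatch aligner settings.
#' @param islands an [island_params()].
#' @param dip_fraction dip threshold as a fraction of the in-domain median.
#' @return list of two reports (`old`, `new`), each with `mapped_fraction`,
#'   `track`, `domain`, `dip_count`.
#' @export
profile_on_two_references <- function(chip_reads, input_reads, ref_old, ref_new,
                                      bin_size = 50L, seed_len = 30L,
                                      max_mismatch = 3L,
                                      islands = island_params(),
                                      dip_fraction = 0.1) {
  one <- function(ref) {
    idx <- genome_index(ref, seed_len)
    chip <- align_reads_minimal(chip_reads, index = idx, max_mismatch = max_mismatch)
    inp <- align_reads_minimal(input_reads, index = idx, max_mismatch = max_mismatch)
    ctg <- names(ref)[1]
    L <- nchar(ref[[ctg]])
    eff <- L - as.integer(Biostrings::letterFrequency(
      Biostrings::DNAString(ref[[ctg]]), "N"))
    isl <- call_islands(chip, inp, ctg, L, effective_len = eff, params = islands)
    diff <- difference_track(chip, inp, ctg, L, bin_size)
    doms <- domains_from_islands(isl, diff)
    dip <- NA_integer_
    if (nrow(doms)) {
      d <- doms[which.max(doms$area), ]
      w0 <- (d$start - 1L) %/% bin_size + 1L
      w1 <- min((d$end - 1L) %/% bin_size + 1L, length(diff$values))
      v <- diff$values[w0:w1]
      dip <- sum(v < dip_fraction * median(v))
    }
    list(mapped_fraction = (nrow(chip) + nrow(inp)) /
           (attr(chip, "n_reads") + attr(inp, "n_reads")),
         track = diff, domain = doms, dip_count = dip)
  }
  list(old = one(ref_old), new = one(ref_new))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order; each stage consumes only
#' prior-stage artifacts; all randomness derives from the config seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return a `cw_manifest` data.frame (stage, file, md5, seconds), written to
#'   `manifest.tsv` alongside the outputs.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "cw_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(outdir, "config.txt"))
  manifest <- list()
  note <- function(stage, files, secs) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files)), seconds = round(secs, 2),
      stringsAsFactors = FALSE)
  }
  state <- new.env(parent = emptyenv())

  stage_simulate <- function() {
    locus <- make_true_locus(config$locus_len, config$gc,
                             derive_seed(config$seed, "locus"))
    cr <- corrupt_reference(locus, dup = config$dup, gaps = config$gaps,
                            emit_unplaced = TRUE)
    base <- domain_spec(config$domain, fold = config$fold)
    p <- read_sim_params(config$read_len, config$frag_min, config$frag_max,
                         config$depth, config$error_rate,
                         derive_seed(config$seed, "panel"))
    panel <- make_tissue_panel(locus, base, config$tissues, p)
    p_wgs <- read_sim_params(config$read_len, config$frag_min, config$frag_max,
                             50, 0, derive_seed(config$seed, "wgs"))
    wgs <- simulate_wgs_pairs(c(locus = locus), p_wgs)
    long <- simulate_long_reads(c(locus = locus), config$long_mean,
                                config$long_depth, 0,
                                derive_seed(config$seed, "long"))
    state$locus <- locus; state$corrupted <- cr; state$panel <- panel
    state$wgs <- wgs; state$long <- long
    files <- c(
      write_fasta(c(locus_true = locus), file.path(outdir, "locus_true.fasta")),
      write_fasta(cr$contigs, file.path(outdir, "reference_corrupted.fasta")),
      write_fasta(long$reads, file.path(outdir, "long_reads.fasta")),
      write_fastq_pairs(wgs$pairs, file.path(outdir, "wgs")),
      write_truth_table(wgs$origins, file.path(outdir, "wgs_origins.tsv")))
    for (t in names(panel$tissues)) {
      files <- c(files,
                 write_fastq_pairs(panel$tissues[[t]]$chip$pairs,
                                   file.path(outdir, paste0("chip_", t))),
                 write_fastq_pairs(panel$tissues[[t]]$input$pairs,
                                   file.path(outdir, paste0("input_", t))))
    }
    files
  }

  stage_walk <- function() {
    if (is.null(state$wgs)) stop("walk stage: missing simulated reads ",
                                 "(run simulate or provide FASTQ inputs)")
    joined <- join_pairs(state$wgs)
    main <- state$corrupted$contigs[[1]]
    # corrupted interval: from the duplication start through the second copy
    dup_len <- config$dup[2] - config$dup[1] + 1L
    iv <- c(config$dup[1], config$dup[2] + config$gaps[[1]][2] + dup_len)
    res <- resolve_region(main, iv, joined, config$walk)
    if (res$status != "resolved")
      stop("walk stage failed: region left open (", res$walk$left$status, "/",
           res$walk$right$status, ")")
    state$walked <- res$contig
    write_fasta(c(locus_walked = res$contig),
                file.path(outdir, "locus_walked.fasta"))
  }

  stage_patch <- function() {
    main_name <- names(state$corrupted$contigs)[1]
    genome <- state$corrupted$contigs
    iv <- genomic_interval(main_name, 1, nchar(genome[[main_name]]))
    pr <- replace_interval(genome, iv, state$walked,
                           drop_contigs = setdiff(names(genome), main_name))
    state$patched <- pr$genome
    stats <- rbind(cbind(reference = "corrupted", genome_stats(genome)),
                   cbind(reference = "patched", genome_stats(pr$genome)))
    sup <- validate_structure(
      state$walked,
      state$corrupted$contigs[[main_name]],
      state$long$reads, anchor_len = 500L)
    sup_df <- data.frame(structure = c("single", "dup"),
                         support = as.integer(sup))
    f1 <- file.path(outdir, "reference_patched.fasta")
    f2 <- file.path(outdir, "liftover.tsv")
    f3 <- file.path(outdir, "assembly_stats.tsv")
    f4 <- file.path(outdir, "structure_support.tsv")
    write_fasta(pr$genome, f1)
    write_liftover(pr$map, f2)
    write.table(stats, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sup_df, f4, sep = "\t", quote = FALSE, row.names = FALSE)
    c(f1, f2, f3, f4)
  }

  stage_profile <- function() {
    ref <- state$patched
    idx <- genome_index(ref, config$seed_len)
    ctg <- names(ref)[1]
    L <- nchar(ref[[ctg]])
    state$aln <- list(); state$tracks <- list()
    files <- character()
    for (t in names(state$panel$tissues)) {
      chip <- align_reads_minimal(state$panel$tissues[[t]]$chip, index = idx,
                                  max_mismatch = config$max_mismatch)
      inp <- align_reads_minimal(state$panel$tissues[[t]]$input, index = idx,
                                 max_mismatch = config$max_mismatch)
      state$aln[[t]] <- list(chip = chip, input = inp)
      tr <- difference_track(chip, inp, ctg, L, config$bin_size)
      state$tracks[[t]] <- tr
      f <- file.path(outdir, paste0("diff_", t, ".bedgraph"))
      write_bedgraph(tr, f)
      files <- c(files, f)
    }
    files
  }

  stage_callpeaks <- function() {
    ref <- state$patched
    ctg <- names(ref)[1]
    L <- nchar(ref[[ctg]])
    eff <- L - as.integer(Biostrings::letterFrequency(
      Biostrings::DNAString(ref[[ctg]]), "N"))
    state$domains <- list()
    files <- character()
    for (t in names(state$aln)) {
      isl <- call_islands(state$aln[[t]]$chip, state$aln[[t]]$input, ctg, L,
                          effective_len = eff, params = config$islands)
      state$domains[[t]] <- domains_from_islands(isl, state$tracks[[t]])
      f <- file.path(outdir, paste0("islands_", t, ".bed"))
      write_islands_bed(isl, f)
      files <- c(files, f)
    }
    files
  }

  stage_compare <- function() {
    ref_t <- names(state$domains)[1]
    call <- classify_panel(state$domains[[ref_t]],
                           state$domains[names(state$domains) != ref_t])
    f <- file.path(outdir, "conservation.tsv")
    write_conservation_tsv(call, f)
    f
  }

  runners <- list(simulate = stage_simulate, walk = stage_walk,
                  patch = stage_patch, profile = stage_profile,
                  callpeaks = stage_callpeaks, compare = stage_compare)
  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(runners[[stage]](), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    note(stage, files, proc.time()[["elapsed"]] - t0)
  }
  out <- do.call(rbind, manifest)
  write.table(out, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  structure(out, class = c("cw_manifest", "data.frame"))
}
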