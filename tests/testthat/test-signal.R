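test_that("aligner places error-free reads at their recorded origins", {
  idx <- genome_index(c(locus = fx_locus), 30)
  aln <- align_reads_minimal(fx_wgs, index = idx)
  expect_gt(mapped_fraction(aln), 0.99)
  key_a <- paste(aln$id, aln$mate)
  o <- fx_wgs$origins
  m <- match(key_a, paste(o$id, o$mate))
  expect_false(anyNA(m))
  expect_equal(aln$start, o$start[m])
  expect_equal(aln$strand, o$strand[m])
  expect_true(all(aln$n_mismatch == 0))
})

test_that("reads from a duplicated block tie and are left unmapped", {
  cr <- corrupt_reference(fx_locus, dup = c(4001, 6000), gaps = list(c(0, 1000)),
                          emit_unplaced = FALSE)
  idx <- genome_index(cr$contigs, 30)
  inside <- substr(fx_locus, 4500, 4574)   # occurs twice in corrupted contig
  unique_read <- substr(fx_locus, 1000, 1074)
  aln <- align_reads_minimal(c(dupread = inside, uniq = unique_read), index = idx)
  expect_false("dupread" %in% aln$id)
  expect_true("uniq" %in% aln$id)
  # random sequence absent from the genome is unmapped
  set.seed(3)
  aln2 <- align_reads_minimal(c(r = rand_dna(75)), index = idx)
  expect_equal(nrow(aln2), 0)
  expect_equal(mapped_fraction(aln2), 0)
})

test_that("aligner tolerates substitutions up to max_mismatch", {
  idx <- genome_index(c(locus = fx_locus), 30)
  r <- substr(fx_locus, 2000, 2074)
  substr(r, 60, 60) <- setdiff(c("A", "C", "G", "T"), substr(r, 60, 60))[1]
  substr(r, 70, 70) <- setdiff(c("A", "C", "G", "T"), substr(r, 70, 70))[1]
  aln <- align_reads_minimal(c(mut = r), index = idx, max_mismatch = 3)
  expect_equal(aln$start, 2000)
  expect_equal(aln$n_mismatch, 2)
  aln0 <- align_reads_minimal(c(mut = r), index = idx, max_mismatch = 1)
  expect_equal(nrow(aln0), 0)
})

test_that("count_bins counts leftmost coordinates and conserves totals", {
  aln <- make_aln(c(1, 50, 250))
  tr <- count_bins(aln, "locus", 1000, bin_size = 200)
  expect_equal(tr$values, c(2, 1, 0, 0, 0))
  expect_equal(sum(tr$values), nrow(aln))
  empty <- count_bins(make_aln(integer(0)), "locus", 1000, 200)
  expect_equal(empty$values, rep(0, 5))
})

test_that("rpkm_normalize applies the RPKM formula and is linear", {
  tr <- make_track(c(10, 0, 300), bin_size = 1000, total_mapped = 1e6)
  expect_equal(rpkm_normalize(tr)$values[1], 10)
  expect_equal(rpkm_normalize(tr)$values[2], 0)
  tr2 <- make_track(c(300), bin_size = 200, total_mapped = 2e7)
  expect_equal(rpkm_normalize(tr2)$values, 75)  # 300 / (0.2 * 20)
  doubled <- make_track(c(20, 0, 600), bin_size = 1000, total_mapped = 1e6)
  expect_equal(rpkm_normalize(doubled, 1e6)$values,
               2 * rpkm_normalize(tr, 1e6)$values)
  expect_error(rpkm_normalize(make_track(c(1)), total_mapped = 0), "total_mapped")
})

test_that("subtract_tracks keeps negatives and rejects mismatched binning", {
  a <- make_track(c(10, 2), bin_size = 50, total_mapped = 1e6, kind = "raw")
  b <- make_track(c(4, 5), bin_size = 50, total_mapped = 1e6, kind = "raw")
  d <- subtract_tracks(rpkm_normalize(a), rpkm_normalize(b))
  expect_equal(d$kind, "difference")
  expect_gt(d$values[1], 0)
  expect_lt(d$values[2], 0)
  self <- subtract_tracks(rpkm_normalize(a), rpkm_normalize(a))
  expect_equal(self$values, c(0, 0))
  c_wide <- make_track(c(1, 1), bin_size = 100, total_mapped = 1e6)
  expect_error(subtract_tracks(rpkm_normalize(a), rpkm_normalize(c_wide)),
               "differ")
})

test_that("difference signal reflects the simulated enrichment fold", {
  L <- make_true_locus(40000, 0.42, 33)
  idx <- genome_index(c(locus = L), 30)
  d <- domain_spec(c(14001, 22000), fold = 8)
  chip <- simulate_chip_pairs(L, d, read_sim_params(depth = 30, seed = 61))
  inp <- simulate_chip_pairs(L, domain_spec(c(14001, 22000), fold = 1),
                             read_sim_params(depth = 30, seed = 62),
                             id_prefix = "input")
  tr <- difference_track(align_reads_minimal(chip, index = idx),
                         align_reads_minimal(inp, index = idx),
                         "locus", 40000)
  bins_in <- (14001 %/% 50 + 1):(22000 %/% 50)
  # leave a fragment-length margin around the plateau edges
  core <- bins_in[bins_in > min(bins_in) + 20 & bins_in < max(bins_in) - 20]
  outside <- setdiff(seq_along(tr$values), (13000 %/% 50):(23000 %/% 50))
  # RPKM scaling redistributes ChIP reads into the domain, so the
  # subtractive signal is strongly positive inside and mildly negative
  # outside (chip background density falls below the input's)
  expect_gt(mean(tr$values[core]), 0)
  expect_lt(mean(tr$values[outside]), 0)
  expect_gt(mean(tr$values[core]), 3 * abs(mean(tr$values[outside])))
})

test_that("mapping the fixture panel to the corrected reference beats the corrupted one", {
  L <- make_true_locus(30000, 0.42, 41)
  cr <- corrupt_reference(L, dup = c(14001, 16000), gaps = list(c(0, 1000)),
                          emit_unplaced = TRUE)
  d <- domain_spec(c(11001, 19000), fold = 8)
  chip <- simulate_chip_pairs(L, d, read_sim_params(depth = 20, seed = 71))
  aln_new <- align_reads_minimal(chip, genome = c(locus = L))
  aln_old <- align_reads_minimal(chip, genome = cr$contigs)
  expect_gt(mapped_fraction(aln_new), mapped_fraction(aln_old))
})

test_that("SAM and bedGraph writers emit well-formed text", {
  tmp <- withr::local_tempdir()
  aln <- make_aln(c(1, 120, 400))
  sam <- file.path(tmp, "a.sam")
  write_sam(aln, c(locus = 1000), sam)
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ\tSN:locus\tLN:1000$", lines)))
  expect_equal(sum(!grepl("^@", lines)), 3)
  expect_equal(length(strsplit(lines[length(lines)], "\t")[[1]]), 12)
  tr <- make_track(c(1.5, 0, -2), bin_size = 100, total_mapped = 10,
                   kind = "difference")
  bg <- file.path(tmp, "t.bedGraph")
  write_bedgraph(tr, bg)
  got <- read.table(bg, sep = "\t")
  expect_equal(nrow(got), 3)
  expect_equal(got$V2[1], 0)   # 0-based starts
  expect_equal(got$V3[3], 300)
  expect_equal(got$V4, c(1.5, 0, -2))
})
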