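test_that("make_true_locus respects length, alphabet, GC and seeding", {
  s <- make_true_locus(10000, 0.42, 7)
  expect_equal(nchar(s), 10000)
  expect_false(grepl("[^ACGT]", s))
  expect_identical(s, make_true_locus(10000, 0.42, 7))
  expect_false(identical(s, make_true_locus(10000, 0.42, 8)))
  gc_only <- make_true_locus(10000, 1.0, 7)
  expect_false(grepl("[AT]", gc_only))
  expect_error(make_true_locus(500, 0.4, 1), "1000")
})

test_that("corrupt_reference builds the expected misassembly anatomy", {
  L <- fx_locus
  cr <- corrupt_reference(L, dup = c(4001, 6000), gaps = list(c(0, 1000)),
                          emit_unplaced = TRUE)
  expect_equal(nchar(cr$contigs[[1]]), 10000 + 2000 + 1000)
  expect_identical(unname(cr$contigs[[2]]), substr(L, 4001, 6000))
  # copy 1, N-run, copy 2 laid out in tandem
  expect_identical(substr(cr$contigs[[1]], 1, 6000), substr(L, 1, 6000))
  expect_identical(substr(cr$contigs[[1]], 6001, 7000), strrep("N", 1000))
  expect_identical(substr(cr$contigs[[1]], 7001, 9000), substr(L, 4001, 6000))
  expect_identical(substr(cr$contigs[[1]], 9001, 13000), substr(L, 6001, 10000))
  # identity when nothing is corrupted
  id <- corrupt_reference(L)
  expect_identical(unname(id$contigs[[1]]), L)
  # a second gap lands shifted in the corrupted contig
  cr2 <- corrupt_reference(L, dup = c(4001, 6000),
                           gaps = list(c(0, 1000), c(8000, 500)))
  expect_equal(nchar(cr2$contigs[[1]]), 13500)
  expect_identical(substr(cr2$contigs[[1]], 11001, 11500), strrep("N", 500))
  expect_error(corrupt_reference(L, dup = c(4001, 6000),
                                 gaps = list(c(0, 1000), c(5000, 10))),
               "overlap")
})

test_that("simulate_wgs_pairs: pair count, exact substrings, determinism", {
  p <- read_sim_params(depth = 30, error_rate = 0, seed = 9)
  rs <- simulate_wgs_pairs(c(locus = fx_locus), p)
  expect_equal(nrow(rs$pairs), round(30 * 10000 / 150))
  expect_setequal(rs$origins$id, rs$pairs$id)
  # error-free mates are exact substrings at their recorded origins
  for (i in sample(nrow(rs$pairs), 25)) {
    o1 <- rs$origins[rs$origins$id == rs$pairs$id[i] & rs$origins$mate == 1, ]
    o2 <- rs$origins[rs$origins$id == rs$pairs$id[i] & rs$origins$mate == 2, ]
    expect_identical(rs$pairs$mate1[i], substr(fx_locus, o1$start, o1$start + 74))
    expect_identical(rs$pairs$mate2[i],
                     revcomp(substr(fx_locus, o2$start, o2$start + 74)))
  }
  expect_identical(rs, simulate_wgs_pairs(c(locus = fx_locus), p))
  expect_error(simulate_wgs_pairs(c(tiny = substr(fx_locus, 1, 500)), p),
               "frag_max")
})

test_that("ChIP fragment midpoints converge to the enrichment fold", {
  L <- make_true_locus(40000, 0.42, 21)
  ds <- 14001; de <- 22000
  p <- read_sim_params(depth = 375, error_rate = 0, seed = 4)  # ~1e5 fragments
  rs <- simulate_chip_pairs(L, domain_spec(c(ds, de), fold = 8), p)
  o1 <- rs$origins[rs$origins$mate == 1, ]
  o2 <- rs$origins[rs$origins$mate == 2, ]
  mid <- (o1$start + (o2$start + 74)) / 2
  n_in <- sum(mid >= ds & mid <= de)
  n <- length(mid)
  w_in <- de - ds + 1; w_out <- 40000 - w_in
  dens_ratio <- (n_in / w_in) / ((n - n_in) / w_out)
  p_in <- (w_in * 8) / (w_in * 8 + w_out)
  sd3 <- 3 * sqrt(p_in * (1 - p_in) / n)
  expect_gt(n_in / n, p_in - sd3)
  expect_lt(n_in / n, p_in + sd3)
  expect_gt(dens_ratio, 6.5)
  expect_lt(dens_ratio, 9.5)
  # fold = 1 is uniform
  rs1 <- simulate_chip_pairs(L, domain_spec(c(ds, de), fold = 1), p)
  o1 <- rs1$origins[rs1$origins$mate == 1, ]
  o2 <- rs1$origins[rs1$origins$mate == 2, ]
  mid <- (o1$start + (o2$start + 74)) / 2
  frac_in <- mean(mid >= ds & mid <= de)
  p0 <- w_in / 40000
  expect_lt(abs(frac_in - p0), 3 * sqrt(p0 * (1 - p0) / n))
  expect_error(domain_spec(c(ds, de), fold = 0.5), "fold")
})

test_that("homolog mixture routes fragments to the chosen homolog's domain", {
  L <- make_true_locus(40000, 0.42, 22)
  d <- domain_spec(hom1 = c(5001, 9000), hom2 = c(30001, 34000),
                   fold = 10, mixture = 0)
  rs <- simulate_chip_pairs(L, d, read_sim_params(depth = 40, seed = 5))
  o1 <- rs$origins[rs$origins$mate == 1, ]
  o2 <- rs$origins[rs$origins$mate == 2, ]
  mid <- (o1$start + (o2$start + 74)) / 2
  # all enrichment sits on homolog 2's domain
  frac1 <- mean(mid >= 5001 & mid <= 9000)
  frac2 <- mean(mid >= 30001 & mid <= 34000)
  expect_gt(frac2, 3 * frac1)
})

test_that("make_tissue_panel: cardinality, shared truth, sliding, bounds", {
  L <- make_true_locus(40000, 0.42, 23)
  base <- domain_spec(c(14001, 22000), fold = 8)
  p <- read_sim_params(depth = 5, seed = 11)
  panel <- make_tissue_panel(L, base, c(a = 0, b = 0, c = 0, d = 0, e = 0), p)
  expect_length(panel$tissues, 5)
  expect_true(all(vapply(panel$tissues, function(t)
    inherits(t$chip, "cw_readset") && inherits(t$input, "cw_readset"),
    logical(1))))
  expect_true(all(vapply(panel$truth, function(d)
    identical(d$hom1, base$hom1), logical(1))))
  slid <- make_tissue_panel(L, base, c(brain = 0, liver = 12000), p)
  expect_identical(slid$truth$liver$hom1, c(14001L, 22000L) + 12000L)
  # 12 kb slide on an 8 kb domain forces disjoint truth intervals
  expect_equal(overlap_coefficient(slid$truth$brain$hom1, slid$truth$liver$hom1), 0)
  expect_error(make_tissue_panel(L, base, c(a = 0, b = 30000), p), "bounds")
})

test_that("simulate_long_reads: counts, truncation, exact substrings", {
  lr <- simulate_long_reads(c(locus = fx_locus), mean_len = 2000, depth = 20,
                            error_rate = 0, seed = 13)
  expect_gt(length(lr$reads), 0.5 * 20 * 10000 / 2000)
  expect_true(all(nchar(lr$reads) >= 1000))
  expect_true(all(nchar(lr$reads) <= 10000))
  for (i in sample(length(lr$reads), 10)) {
    o <- lr$origins[i, ]
    truth <- substr(fx_locus, o$start, o$start + nchar(lr$reads[i]) - 1L)
    if (o$strand == "-") truth <- revcomp(truth)
    expect_identical(unname(lr$reads[i]), truth)
  }
  expect_identical(lr$reads,
                   simulate_long_reads(c(locus = fx_locus), 2000, 20, 0, 13)$reads)
  expect_error(simulate_long_reads(c(locus = fx_locus), 500, 20, 0, 1), "1000")
})

test_that("FASTQ/FASTA round trips preserve sequence and pairing", {
  tmp <- withr::local_tempdir()
  rs <- simulate_wgs_pairs(c(locus = substr(fx_locus, 1, 2000)),
                           read_sim_params(depth = 3, seed = 2))
  write_fastq_pairs(rs$pairs, file.path(tmp, "t"))
  back <- read_fastq_pairs(file.path(tmp, "t_R1.fastq.gz"),
                           file.path(tmp, "t_R2.fastq.gz"))
  expect_identical(back$mate1, rs$pairs$mate1)
  expect_identical(back$mate2, rs$pairs$mate2)
  write_fasta(c(locus = fx_locus), file.path(tmp, "g.fasta"))
  expect_identical(unname(read_fasta(file.path(tmp, "g.fasta"))[1]), fx_locus)
})
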