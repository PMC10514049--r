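test_that("revcomp is the involutive DNA reverse complement", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAAC"), "GTTT")
  expect_identical(revcomp("ANT"), "ANT")
  set.seed(1)
  for (i in 1:20) {
    s <- rand_dna(sample(10:80, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_error(revcomp("ACGU"), "alphabet|characters")
})

test_that("join_pairs keeps cardinality and order and rejects orphans", {
  j <- join_pairs(fx_wgs)
  expect_equal(length(j), nrow(fx_wgs$pairs))
  expect_identical(j$pairs$mate1[1], fx_wgs$pairs$mate1[1])
  expect_error(join_pairs(c("ACGT", "GGTT"), c("AAAA")), "orphan")
  bad <- fx_wgs$pairs
  bad$mate2[3] <- NA
  expect_error(join_pairs(bad), bad$id[3])
})

test_that("find_reads_by_query agrees with the brute-force oracle", {
  set.seed(42)
  for (case in 1:200) {
    n_reads <- sample(4:10, 1)
    pairs <- join_pairs(replicate(n_reads, rand_dna(80)),
                        replicate(n_reads, rand_dna(80)))
    query <- rand_dna(60)
    # plant the query (or its revcomp) in a few mates at random offsets
    n_plant <- sample(0:3, 1)
    for (k in seq_len(n_plant)) {
      i <- sample(n_reads, 1); m <- sample(1:2, 1); off <- sample(0:20, 1)
      pat <- if (runif(1) < 0.5) query else revcomp(query)
      col <- paste0("mate", m)
      s <- pairs$pairs[[col]][i]
      pairs$pairs[[col]][i] <- paste0(substr(s, 1, off), pat,
                                      substr(s, off + 61, nchar(s)))
    }
    pairs <- join_pairs(pairs$pairs)   # rebuild search structures
    got <- find_reads_by_query(query, pairs)
    want <- brute_find(query, pairs$pairs)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("query search warns off-range and refuses N", {
  expect_warning(find_reads_by_query(rand_dna(40), fx_joined), "60-95")
  expect_error(find_reads_by_query(paste0(rand_dna(30), "N", rand_dna(30)),
                                   fx_joined), "N")
  expect_equal(nrow(find_reads_by_query(strrep("AC", 30), fx_joined)), 0)
})

test_that("extend_consensus: unanimous extension, coverage cutoff, branching", {
  set.seed(7)
  base <- rand_dna(160)
  anchor <- substr(base, 1, 60)
  # 10 unanimous reads extending >= 50 bases
  reads <- rep(substr(base, 1, 120), 10)
  j <- join_pairs(reads, replicate(10, rand_dna(75)))
  hits <- find_reads_by_query(anchor, j)
  ex <- extend_consensus(anchor, hits, j, walk_params())
  expect_gte(nchar(ex$extension), 50)
  expect_identical(ex$extension, substr(base, 61, 60 + nchar(ex$extension)))
  expect_null(ex$branch)
  expect_true(all(ex$support >= 5))

  # coverage drops to 4 after 20 columns -> extension length exactly 20
  reads <- c(rep(substr(base, 1, 80), 5), rep(substr(base, 1, 110), 4))
  j <- join_pairs(reads, replicate(9, rand_dna(75)))
  hits <- find_reads_by_query(anchor, j)
  ex <- extend_consensus(anchor, hits, j,
                         walk_params(min_support = 5))
  expect_equal(nchar(ex$extension), 20)
  expect_equal(ex$support, c(rep(9L, 20)))

  # planted 50/50 disagreement -> branch event, extension stops before it
  alt <- base
  substr(alt, 71, 71) <- setdiff(c("A", "C", "G", "T"),
                                 substr(base, 71, 71))[1]
  reads <- c(rep(substr(base, 1, 120), 5), rep(substr(alt, 1, 120), 5))
  j <- join_pairs(reads, replicate(10, rand_dna(75)))
  hits <- find_reads_by_query(anchor, j)
  ex <- extend_consensus(anchor, hits, j, walk_params())
  expect_equal(nchar(ex$extension), 10)
  expect_equal(ex$branch$position, 11)
  expect_error(extend_consensus(anchor, hits[0, ], j, walk_params()), "stalled")
})

test_that("walk reproduces a unique segment exactly in both directions", {
  seg <- substr(fx_locus, 3001, 5000)
  rs <- simulate_wgs_pairs(c(seg = seg),
                           read_sim_params(depth = 60, error_rate = 0, seed = 17))
  j <- join_pairs(rs)
  # seed a little inside the end: coverage ramps over a fragment length there
  wr <- walk(j, substr(seg, 201, 260), "rightward", walk_params())
  expect_identical(wr$sequence, substr(seg, 201, 200 + nchar(wr$sequence)))
  expect_gt(nchar(wr$sequence), 1500)
  expect_equal(wr$status, "open")
  wl <- walk(j, substr(seg, 1741, 1800), "leftward", walk_params())
  expect_identical(wl$sequence,
                   substr(seg, 1800 - nchar(wl$sequence) + 1, 1800))
  expect_gt(nchar(wl$sequence), 1500)
  # determinism
  expect_identical(wr, walk(j, substr(seg, 201, 260), "rightward", walk_params()))
  # iteration bound
  w1 <- walk(j, substr(seg, 201, 260), "rightward", walk_params(max_iterations = 1))
  expect_lte(nchar(w1$sequence), 60 + 35)  # at most one extension step
  expect_error(walk(j, strrep("AG", 30), "rightward"), "not found")
})

test_that("close_gap stitches a gapped interval back to the truth", {
  lf <- substr(fx_locus, 3901, 4000)
  rf <- substr(fx_locus, 6001, 6100)
  cg <- close_gap(lf, rf, fx_joined, walk_params())
  expect_equal(cg$status, "closed")
  expect_identical(cg$sequence, substr(fx_locus, 3901, 6100))
  expect_gte(cg$overlap, 100)
  # withholding reads over a central window leaves both sides open
  o1 <- fx_wgs$origins[fx_wgs$origins$mate == 1, ]
  o2 <- fx_wgs$origins[fx_wgs$origins$mate == 2, ]
  drop <- (o2$start + 74) >= 4500 & o1$start <= 5500
  j2 <- join_pairs(fx_wgs$pairs[!drop, ])
  cg2 <- close_gap(lf, rf, j2, walk_params())
  expect_equal(cg2$status, "open")
  expect_equal(cg2$left$status, "open")
  expect_equal(cg2$right$status, "open")
  # an unreachable merge-overlap requirement also stays open
  cg3 <- close_gap(substr(fx_locus, 1, 100), substr(fx_locus, 9901, 10000),
                   fx_joined, walk_params(max_iterations = 3,
                                          min_merge_overlap = 5000))
  expect_equal(cg3$status, "open")
})

test_that("extension length is monotone in support and agreement thresholds", {
  set.seed(11)
  for (case in 1:10) {
    q <- substr(fx_locus, 1000 + 500 * case, 1059 + 500 * case)
    hits <- find_reads_by_query(q, fx_joined)
    lens <- vapply(list(walk_params(min_support = 3, min_agreement = 0.6),
                        walk_params(min_support = 5, min_agreement = 0.8),
                        walk_params(min_support = 8, min_agreement = 0.95)),
                   function(p) nchar(extend_consensus(q, hits, fx_joined, p)$extension),
                   numeric(1))
    expect_true(all(diff(lens) <= 0))
  }
})

test_that("resolve_region collapses a false duplication; keeps a real one", {
  L <- fx_locus
  cr <- corrupt_reference(L, dup = c(4001, 6000), gaps = list(c(0, 1000)),
                          emit_unplaced = TRUE)
  res <- resolve_region(cr$contigs[[1]], c(4001, 9000), fx_joined, walk_params())
  expect_equal(res$status, "resolved")
  expect_identical(res$contig, L)
  # reads drawn from a genuinely duplicated sequence: short reads alone
  # cannot distinguish one copy from two, and the inward walks meet inside
  # the repeat, collapsing it to a single copy - the documented limitation
  # of overlap merging across repeats longer than min_merge_overlap. The
  # long-read structure check is the guard that catches exactly this.
  dupseq <- paste0(substr(L, 1, 6000), substr(L, 4001, 10000))
  wgs_dup <- simulate_wgs_pairs(c(dup = dupseq),
                                read_sim_params(depth = 50, error_rate = 0, seed = 8))
  j_dup <- join_pairs(wgs_dup)
  res2 <- resolve_region(dupseq, c(4001, 8000), j_dup, walk_params())
  if (res2$status == "resolved") {
    expect_identical(res2$contig, L)  # collapsed to a single copy
    lr <- simulate_long_reads(c(dup = dupseq), 3000, 20, 0, 9)
    sup <- validate_structure(res2$contig, dupseq, lr$reads, anchor_len = 400)
    expect_gt(unname(sup["support_dup"]), unname(sup["support_single"]))
  } else {
    expect_true(any(c(res2$walk$left$status,
                      res2$walk$right$status) == "branched"))
  }
})
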