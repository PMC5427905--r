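test_that("toy locus is deterministic and satisfies its engineered constraints", {
  spec <- toy_locus_spec(seed = 7)
  l1 <- make_toy_locus(spec)
  l2 <- make_toy_locus(spec)
  expect_identical(l1$sequence, l2$sequence)
  expect_identical(l1$exons, l2$exons)
  # engineered shared suffix is exactly 3, not more
  expect_equal(shared_terminal_ambiguity(l1, "7b", "8a"), 3)
  # all flank-11 probes are specific on the transcript set
  fx <- toy_fixture()
  aud <- probe_cross_match_audit(fx$probes, fx$tx_all)
  expect_true(all(aud$summary$specific))
  # no probe occurs in the genomic sequence on either strand
  for (p in fx$probes$sequence) {
    expect_false(grepl(p, fx$locus$sequence, fixed = TRUE))
    expect_false(grepl(revcomp(p), fx$locus$sequence, fixed = TRUE))
  }
  # a different seed gives a different sequence with the same guarantees
  l3 <- make_toy_locus(toy_locus_spec(seed = 8))
  expect_false(identical(l1$sequence, l3$sequence))
  expect_equal(shared_terminal_ambiguity(l3, "7b", "8a"), 3)
})

test_that("error-free reads are exact substrings of their source transcript", {
  fx <- toy_fixture()
  cfg <- sim_config(n_reads = 300, error_rate = 0,
                    isoform_weights = c(VEGFA_121 = 1, VEGFA_165 = 2),
                    seed = 42)
  sim <- simulate_reads(fx$tx_canonical, cfg)
  expect_equal(length(sim$reads), 300)
  expect_equal(nrow(sim$truth), 300)
  for (i in seq_along(sim$reads)) {
    src <- fx$tx_canonical[[sim$truth$transcript[i]]]$sequence
    r <- sim$reads[[i]]
    expect_true(grepl(r, src, fixed = TRUE) ||
                  grepl(revcomp(r), src, fixed = TRUE))
  }
  # determinism under a fixed seed
  sim2 <- simulate_reads(fx$tx_canonical, cfg)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth_junctions, sim2$truth_junctions)
})

test_that("8b-free mixtures never produce 8b-junction truth records", {
  fx <- toy_fixture()
  cfg <- sim_config(n_reads = 10000, error_rate = 0,
                    isoform_weights = c(VEGFA_165 = 1), seed = 1)
  sim <- simulate_reads(fx$tx_canonical, cfg)
  expect_equal(sum(grepl("-8b$", sim$truth_junctions$junction)), 0)
})

test_that("junction-spanning fraction matches the uniform-start expectation", {
  fx <- toy_fixture()
  n <- 50000
  cfg <- sim_config(n_reads = n, error_rate = 0,
                    isoform_weights = c(VEGFA_165 = 1), seed = 9)
  sim <- simulate_reads(fx$tx_canonical, cfg)
  L <- nchar(fx$tx_canonical$VEGFA_165$sequence)
  rl <- 100; flank <- 11
  # spanning 7b-8a with >= 11 bases each side: rl - 2*11 + 1 start positions
  p <- (rl - 2 * flank + 1) / (L - rl + 1)
  tj <- sim$truth_junctions
  obs <- sum(tj$junction == "7b-8a" & tj$donor_overhang >= flank &
               tj$acceptor_overhang >= flank)
  expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("paired mode conserves reads and truth records", {
  fx <- toy_fixture()
  cfg <- sim_config(n_reads = 200, paired = TRUE, error_rate = 0,
                    isoform_weights = c(VEGFA_165 = 1), seed = 2)
  sim <- simulate_reads(fx$tx_canonical, cfg)
  expect_equal(length(sim$reads), 400)
  expect_equal(nrow(sim$truth), 400)
  expect_true(all(grepl("/[12]$", sim$truth$read_id)))
  # each mate is an exact (possibly reverse-complemented) substring
  src <- fx$tx_canonical$VEGFA_165$sequence
  ok <- vapply(sim$reads, function(r)
    grepl(r, src, fixed = TRUE) || grepl(revcomp(r), src, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
})

test_that("substitution errors hit at approximately the requested rate", {
  fx <- toy_fixture()
  cfg0 <- sim_config(n_reads = 2000, error_rate = 0,
                     isoform_weights = c(VEGFA_165 = 1), seed = 5)
  cfg1 <- sim_config(n_reads = 2000, error_rate = 0.01,
                     isoform_weights = c(VEGFA_165 = 1), seed = 5)
  clean <- simulate_reads(fx$tx_canonical, cfg0)
  noisy <- simulate_reads(fx$tx_canonical, cfg1)
  # same seed, same windows: only the error layer differs
  expect_identical(clean$truth, noisy$truth)
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$reads, noisy$reads)
  n_bases <- sum(nchar(clean$reads))
  expect_equal(nchar(clean$reads), nchar(noisy$reads),
               ignore_attr = TRUE)
  p <- 0.01
  expect_lt(abs(sum(mism) - n_bases * p), 3 * sqrt(n_bases * p * (1 - p)))
})

test_that("simulation rejects reads longer than the shortest transcript", {
  fx <- toy_fixture()
  short <- assemble_transcript(fx$locus, "tiny", "5")
  cfg <- sim_config(n_reads = 10, read_length = 100,
                    isoform_weights = c(tiny = 1))
  expect_error(simulate_reads(list(tiny = short), cfg), "read_length")
})

test_that("FASTQ round-trip preserves reads, including gzip", {
  fx <- toy_fixture()
  cfg <- sim_config(n_reads = 50, error_rate = 0,
                    isoform_weights = c(VEGFA_165 = 1), seed = 3)
  sim <- simulate_reads(fx$tx_canonical, cfg)
  for (ext in c(".fastq", ".fastq.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_fastq(sim$reads, path)
    back <- read_sequences(path)
    expect_identical(unname(back), unname(sim$reads))
    expect_identical(names(back), names(sim$reads))
  }
})

test_that("SJ fixtures use the 9-column dialect with 1-based intron coordinates", {
  cat6 <- vegfa_exon_catalog()
  jx <- build_junction_catalog(cat6, c("5", "7b"), "8a")
  rec <- sj_records_from_counts(jx, c(100, 200))
  path <- withr::local_tempfile(fileext = ".tab")
  write_sj_fixture(rec, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2)
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(length(f), 9)
  # junction 7b-8a intron from the printed exon coordinates
  expect_equal(as.integer(f[2]), 43749825)
  expect_equal(as.integer(f[3]), 43752277)
  expect_equal(as.integer(f[7]), 200)
  # empty counts give an empty file
  write_sj_fixture(rec[0, ], path)
  expect_equal(length(readLines(path)), 0)
})

test_that("amplicon pools record exact truth proportions", {
  fx <- toy_fixture()
  f <- substr(exon_seq(fx$locus, "7a"), 3, 22)
  r_site <- substr(exon_seq(fx$locus, "8b"), 40, 59)
  primers <- primer_pair(f, revcomp(r_site), "toy")
  pool <- simulate_amplicon_reads(
    fx$tx_all[c("VEGFA_165", "VEGFA_148")],
    c(VEGFA_165 = 0.995, VEGFA_148 = 0.005), primers, 2000, seed = 5)
  expect_equal(sum(pool$truth$template == "VEGFA_165"), 1990)
  expect_equal(sum(pool$truth$template == "VEGFA_148"), 10)
  # error_rate 0: every read equals its template amplicon
  expect_true(all(pool$reads == pool$products[pool$truth$template]))
  # single-template pool: all reads identical length
  one <- simulate_amplicon_reads(fx$tx_all["VEGFA_165"], c(VEGFA_165 = 1),
                                 primers, 100, seed = 1)
  expect_equal(length(unique(nchar(one$reads))), 1)
  # a template without a primer site refuses to amplify
  expect_error(
    simulate_amplicon_reads(fx$tx_all["VEGFA_111"], c(VEGFA_111 = 1),
                            primers, 10),
    class = "vegfsplice_no_product")
})
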