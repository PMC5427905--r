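test_that("default exon catalog matches the hg19 coordinate table", {
  cat6 <- vegfa_exon_catalog()
  expect_equal(nrow(cat6), 14)
  e8a <- cat6[cat6$name == "8a", ]
  expect_equal(e8a$start, 43752278)
  expect_equal(e8a$end, 43752343)
  expect_equal(e8a$end - e8a$start + 1, 66)
  # genomic contiguity of the sub-exon blocks
  get <- function(nm, f) cat6[[f]][cat6$name == nm]
  expect_equal(get("8b", "start"), get("8a", "end") + 1)
  expect_equal(get("6b", "start"), get("6a", "end") + 1)
  expect_equal(get("6c", "start"), get("6b", "end") + 1)
  expect_equal(get("1b", "start"), get("1a", "end") + 1)
  expect_equal(get("7b", "start"), get("7a", "end") + 1)
})

test_that("exon catalog round-trips through the tab format", {
  cat6 <- vegfa_exon_catalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_exon_catalog(cat6, path)
  expect_equal(load_exon_catalog(path), cat6)
})

test_that("catalog loading reports malformed input precisely", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tchrom\tstart\tend\tstrand",
               "x\tchr1\t10\t20\t+",
               "y\tchr1\tten\t20\t+"), path)
  expect_error(load_exon_catalog(path), "line 3")
  writeLines(c("name\tchrom\tstart\tend\tstrand",
               "x\tchr1\t10\t20"), path)
  expect_error(load_exon_catalog(path), "line 2")
  writeLines(c("name\tchrom\tstart\tend\tstrand",
               "x\tchr1\t10\t20\t+",
               "x\tchr1\t30\t40\t+"), path)
  expect_error(load_exon_catalog(path), "duplicate")
  writeLines(c("name\tchrom\tstart\tend\tstrand",
               "x\tchr1\t21\t20\t+"), path)
  expect_error(load_exon_catalog(path), "start > end")
})

test_that("junction catalog is the donor x acceptor product with intron arithmetic", {
  cat6 <- vegfa_exon_catalog()
  jx <- build_junction_catalog(cat6, c("4", "5", "6a", "7a", "7b"),
                               c("8a", "8b"))
  expect_equal(nrow(jx), 10)
  expect_equal(jx$name, paste(jx$donor_exon, jx$acceptor_exon, sep = "-"))
  j <- jx[jx$name == "7b-8a", ]
  expect_equal(j$intron_first, 43749825)
  expect_equal(j$intron_last, 43752277)
  expect_true(all(jx$intron_first == jx$donor_end + 1))
  expect_true(all(jx$intron_last == jx$acceptor_start - 1))
  expect_true(all(jx$intron_first <= jx$intron_last))
  # reversed orientation is rejected
  expect_error(build_junction_catalog(cat6, "8a", "7b"),
               "not a forward junction")
})

test_that("probes concatenate donor suffix and acceptor prefix, validated against slicing", {
  fx <- toy_fixture()
  probes <- fx$probes
  expect_true(all(nchar(probes$sequence) == 22))
  expect_equal(probes$sequence, paste0(probes$donor_half,
                                       probes$acceptor_half))
  # direct-slice oracle for every junction and several flanks
  for (flank in c(1, 2, 11)) {
    for (i in seq_len(nrow(fx$junctions))) {
      j <- fx$junctions[i, ]
      p <- extract_probe(fx$locus, j, flank)
      donor <- exon_seq(fx$locus, j$donor_exon)
      acceptor <- exon_seq(fx$locus, j$acceptor_exon)
      expect_identical(
        p$sequence,
        paste0(substr(donor, nchar(donor) - flank + 1, nchar(donor)),
               substr(acceptor, 1, flank)))
      expect_equal(nchar(p$sequence), 2 * flank)
    }
  }
  # flank exceeding an exon length names the offending exon
  expect_error(
    extract_probe(fx$locus, fx$junctions[fx$junctions$name == "5-8a", ], 31),
    "exon '5'")
})

test_that("transcript assembly concatenates exons and validates chain order", {
  fx <- toy_fixture()
  # real coordinates: contiguous 8a+8b spans 66 + 1880 bases
  cat6 <- vegfa_exon_catalog()
  lens <- cat6$end - cat6$start + 1
  expect_equal(sum(lens[cat6$name %in% c("8a", "8b")]), 1946)
  # on the toy locus, transcript length equals the sum of chain exon lengths
  tx <- fx$tx_all$VEGFA_165
  chain_len <- sum(vapply(tx$exon_chain,
                          function(e) nchar(exon_seq(fx$locus, e)),
                          numeric(1)))
  expect_equal(nchar(tx$sequence), chain_len)
  # single-exon chain is the exon subsequence
  single <- assemble_transcript(fx$locus, "just8a", "8a")
  expect_identical(single$sequence, exon_seq(fx$locus, "8a"))
  expect_error(assemble_transcript(fx$locus, "bad", c("8a", "7b")),
               "out of genomic order")
  expect_error(assemble_transcript(fx$locus, "bad", c("6a", "6b", "6a")),
               "out of genomic order")
})

test_that("shared terminal ambiguity is symmetric and matches the brute-force oracle", {
  fx <- toy_fixture()
  expect_equal(shared_terminal_ambiguity(fx$locus, "7b", "8a"), 3)
  expect_equal(shared_terminal_ambiguity(fx$locus, "8a", "7b"), 3)
  # identity: an exon shares its full length with itself
  expect_equal(shared_terminal_ambiguity(fx$locus, "5", "5"),
               nchar(exon_seq(fx$locus, "5")))
  # oracle equivalence over all exon pairs
  nms <- fx$locus$exons$name
  for (a in nms) for (b in nms) {
    expect_equal(
      shared_terminal_ambiguity(fx$locus, a, b),
      oracle_shared_suffix(exon_seq(fx$locus, a), exon_seq(fx$locus, b)))
  }
  # disjoint alphabets share nothing
  toy <- locus_reference("c", 1, 8, "AAAACCCC",
                         data.frame(name = c("x", "y"), chrom = "c",
                                    start = c(1, 5), end = c(4, 8),
                                    strand = "+"))
  expect_equal(shared_terminal_ambiguity(toy, "x", "y"), 0)
})

test_that("ambiguity report carries min safe overhang = shared + 1", {
  fx <- toy_fixture()
  rep <- ambiguity_report(fx$locus, c("7a", "7b", "8a", "8b"))
  expect_true(all(rep$min_safe_overhang == rep$shared_suffix_len + 1))
  expect_equal(
    rep$shared_suffix_len[rep$exon_a == "7b" & rep$exon_b == "8a"], 3)
})

test_that("probe cross-match audit flags non-specific probes and clears specific ones", {
  fx <- toy_fixture()
  aud <- probe_cross_match_audit(fx$probes, fx$tx_all)
  expect_true(all(aud$summary$specific))
  # the 7b-8a probe is found in the transcripts carrying that junction
  hits <- aud$hits
  h <- hits[hits$junction == "7b-8a" & hits$contained, ]
  expect_true(all(h$has_junction))
  expect_true(nrow(h) >= 1)
  # the 7b-8b probe is NOT contained in the contiguous exon-8 transcripts:
  # its donor half differs from the 8a terminus beyond the 3 shared bases
  h8b <- hits[hits$junction == "7b-8b", ]
  expect_false(any(h8b$contained & !h8b$has_junction))
  # a flank-2 probe (flank below the engineered shared suffix of 3) for
  # 7b-8b is identical to the contiguous 8a|8b 4-mer context: non-specific
  p2 <- build_probes(fx$locus, fx$junctions[fx$junctions$name == "7b-8b", ],
                     flank = 2)
  aud2 <- probe_cross_match_audit(p2, fx$tx_all["VEGFA_165"])
  expect_false(aud2$summary$specific)
})

test_that("locus reference validates window and sequence", {
  exons <- data.frame(name = "x", chrom = "c", start = 5, end = 8,
                      strand = "+")
  expect_error(locus_reference("c", 1, 10, "ACGT", exons), "length")
  expect_error(locus_reference("c", 6, 10, "ACGTA", exons), "outside")
  lr <- locus_reference("c", 1, 10, "ACGTACGTAC", exons)
  expect_identical(exon_seq(lr, "x"), "ACGT")
  expect_identical(locus_subseq(lr, 2, 4), "CGT")
  expect_error(locus_subseq(lr, 0, 4), "not contained")
})
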