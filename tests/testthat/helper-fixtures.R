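# Shared fixtures, built once per test run. The toy locus (seed 7) mirrors
# the VEGFA exon structure with an engineered 3-base shared suffix between
# exons 7b and 8a.

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      locus <- make_toy_locus(toy_locus_spec(seed = 7))
      junctions <- build_junction_catalog(
        locus$exons, c("4", "5", "6a", "7a", "7b"), c("8a", "8b"))
      probes <- build_probes(locus, junctions, flank = 11)
      tx_all <- assemble_transcripts(
        locus, vegfa_transcript_chains(include_8b = TRUE))
      tx_canonical <- tx_all[!grepl("b$", names(tx_all))]
      cache <<- list(locus = locus, junctions = junctions, probes = probes,
                     tx_all = tx_all, tx_canonical = tx_canonical)
    }
    cache
  }
})

# mixture weights giving each transcript a target share of the
# junction-spanning reads: spanning probability is uniform over start
# positions, so weight ~ share * (valid start positions)
weights_for_span_share <- function(transcripts, shares, read_length = 100) {
  L <- vapply(transcripts[names(shares)], function(t) nchar(t$sequence),
              numeric(1))
  shares * (L - read_length + 1)
}

# brute-force probe-scan oracle: test every probe against every read (and
# its reverse complement) by plain substring search
oracle_scan_counts <- function(reads, probes, both_strands = TRUE) {
  vapply(probes$sequence, function(p) {
    hit <- vapply(reads, function(r) grepl(p, r, fixed = TRUE), logical(1))
    if (both_strands) {
      rc <- revcomp(p)
      hit <- hit | vapply(reads, function(r) grepl(rc, r, fixed = TRUE),
                          logical(1))
    }
    sum(hit)
  }, integer(1), USE.NAMES = FALSE)
}

# brute-force shared-suffix oracle: compare suffixes of increasing length
oracle_shared_suffix <- function(a, b) {
  s <- 0
  while (s < min(nchar(a), nchar(b))) {
    if (substr(a, nchar(a) - s, nchar(a)) !=
        substr(b, nchar(b) - s, nchar(b))) break
    s <- s + 1
  }
  s
}
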