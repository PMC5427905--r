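## In-silico PCR and junction classification of amplicon sequencing reads.

#' Primer pair
#'
#' The forward primer is given 5'->3' on the sense strand; the reverse
#' primer 5'->3' on the antisense strand (the convention primer sequences
#' are printed in). The predicted product therefore includes both primer
#' footprints.
#'
#' @param forward,reverse primer sequences (ACGT only).
#' @param name label for the pair.
#' @return list of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, name = "primer_pair") {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (!nzchar(forward) || !nzchar(reverse) ||
      !is_dna(forward) || !is_dna(reverse))
    stop("primers must be non-empty ACGT sequences")
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' VEGFA RT-PCR primer pairs
#'
#' The exon 7/8 junction-spanning pair (`ex7_ex8`: forward in exon 7,
#' reverse in exon 8; on real VEGFA cDNA this yields 235 bp across 7b-8a
#' and 169 bp across 7b-8b) and the universal exon 4/5 pair
#' (`universal_ex4_ex5`; 115 bp on both isoform families).
#'
#' @return named list of [primer_pair()] objects.
#' @export
vegfa_primer_pairs <- function() {
  list(
    ex7_ex8 = primer_pair("CAAGATCCGCAGACGTGTAA",
                          "TCTGTCGATGGTGATGGTGT", "ex7_ex8"),
    universal_ex4_ex5 = primer_pair("TGCGGATCAAACCTCACCAA",
                                    "GGCCCACAGGGATTTTCTTG",
                                    "universal_ex4_ex5")
  )
}

# all match starts of pattern in subject (fixed), integer(0) if none
fixed_match_starts <- function(pattern, subject) {
  g <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (g[1] == -1L) integer(0) else as.integer(g)
}

#' Predict the PCR product of a primer pair on a template
#'
#' Locates the forward primer as-is and the reverse primer as its reverse
#' complement; the product spans from the first base of the forward site to
#' the last base of the reverse-complement site, inclusive. Matching is
#' exact (no mismatches).
#'
#' @param template `transcript_model` or character sequence (optionally
#'   named).
#' @param primers a [primer_pair()].
#' @return list of class `amplicon_prediction`: `template`,
#'   `product_length`, `product_sequence`, `forward_site`, `reverse_site`
#'   (both `c(start, end)`, 1-based inclusive template coordinates).
#'   Throws a condition of class `vegfsplice_no_product` when either primer
#'   has no site (or the reverse site is not downstream), and
#'   `vegfsplice_nonunique_priming` when either primer has multiple sites.
#' @export
insilico_pcr <- function(template, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  if (inherits(template, "transcript_model")) {
    tname <- template$name; tseq <- template$sequence
  } else {
    tname <- if (!is.null(names(template))) names(template)[1] else "template"
    tseq <- toupper(as.character(template)[1])
  }
  fwd <- primers$forward
  rev_rc <- revcomp(primers$reverse)
  f_starts <- fixed_match_starts(fwd, tseq)
  r_starts <- fixed_match_starts(rev_rc, tseq)
  pcr_stop <- function(cls, msg) {
    stop(structure(class = c(cls, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  if (length(f_starts) == 0L)
    pcr_stop("vegfsplice_no_product",
             paste0("no product: forward primer has no site on '",
                    tname, "'"))
  if (length(r_starts) == 0L)
    pcr_stop("vegfsplice_no_product",
             paste0("no product: reverse primer has no site on '",
                    tname, "'"))
  if (length(f_starts) > 1L)
    pcr_stop("vegfsplice_nonunique_priming",
             paste0("non-unique priming: forward primer sites at ",
                    paste(f_starts, collapse = ", "), " on '", tname, "'"))
  if (length(r_starts) > 1L)
    pcr_stop("vegfsplice_nonunique_priming",
             paste0("non-unique priming: reverse primer sites at ",
                    paste(r_starts, collapse = ", "), " on '", tname, "'"))
  f_site <- c(f_starts, f_starts + nchar(fwd) - 1L)
  r_site <- c(r_starts, r_starts + nchar(rev_rc) - 1L)
  if (r_starts <= f_site[2])
    pcr_stop("vegfsplice_no_product",
             paste0("no product: reverse site not downstream of forward ",
                    "site on '", tname, "'"))
  product <- substr(tseq, f_site[1], r_site[2])
  structure(
    list(template = tname, product_length = r_site[2] - f_site[1] + 1L,
         product_sequence = product, forward_site = f_site,
         reverse_site = r_site),
    class = "amplicon_prediction"
  )
}

#' @export
print.amplicon_prediction <- function(x, ...) {
  cat("<amplicon_prediction> ", x$template, ": ", x$product_length,
      " bp (forward ", x$forward_site[1], "-", x$forward_site[2],
      ", reverse ", x$reverse_site[1], "-", x$reverse_site[2], ")\n",
      sep = "")
  invisible(x)
}

#' Classify amplicon reads by junction probe content
#'
#' Each read is assigned to the unique junction whose probe (or its reverse
#' complement) it contains; reads matching no probe are `unclassified` and
#' reads matching two or more probes are counted as `ambiguous` and
#' reported separately. Classification uses probe containment rather than
#' full-amplicon alignment, which suffices because every legitimate product
#' spans exactly one junction of interest.
#'
#' @param reads FASTQ/FASTA path, character vector or `DNAStringSet`.
#' @param probes probe data.frame from [build_probes()].
#' @param primers optional [primer_pair()]; when supplied, reads are
#'   primer-trimmed with [primer_trim()] before classification (the class
#'   assignments are unchanged since probes lie inside the insert).
#' @return object of class `amplicon_class_summary`: list with `total`,
#'   and `classes` (data.frame `class`, `count`, `percent` — percentages of
#'   total, reported to two decimals; counts over classes, ambiguous and
#'   unclassified sum to the total).
#' @export
classify_amplicon_reads <- function(reads, probes, primers = NULL) {
  seqs <- read_sequences(reads)
  if (!is.null(primers)) seqs <- primer_trim(seqs, primers)$insert
  sr <- suppressWarnings(
    scan_reads(seqs, probes, both_strands = TRUE, detail = TRUE))
  nhit <- if (length(seqs)) rowSums(sr$hits) else integer(0)
  counts <- vapply(probes$junction, function(j)
    sum(sr$hits[, j] & nhit == 1L), integer(1))
  ambiguous <- sum(nhit > 1L)
  unclassified <- sum(nhit == 0L)
  classes <- data.frame(
    class = c(probes$junction, "ambiguous", "unclassified"),
    count = as.integer(c(counts, ambiguous, unclassified)),
    stringsAsFactors = FALSE)
  total <- length(seqs)
  classes$percent <- if (total > 0) round(classes$count / total * 100, 2)
  else NA_real_
  structure(list(total = total, classes = classes),
            class = "amplicon_class_summary")
}

#' @export
print.amplicon_class_summary <- function(x, ...) {
  cat("<amplicon_class_summary> ", x$total, " reads\n", sep = "")
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Trim primer footprints from amplicon reads
#'
#' A forward-orientation read starts with the forward primer and ends with
#' the reverse complement of the reverse primer; a reverse-complemented
#' read starts with the reverse primer and ends with the reverse complement
#' of the forward primer. Matching is exact. Reads without recognisable
#' primers pass through untrimmed with `trimmed = FALSE`.
#'
#' @param reads character vector of read sequences.
#' @param primers a [primer_pair()].
#' @return data.frame with columns `insert`, `trimmed`, `orientation`
#'   (`"forward"`, `"reverse"` or `NA`).
#' @export
primer_trim <- function(reads, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  reads <- toupper(reads)
  fwd <- primers$forward
  rev <- primers$reverse
  rc_rev <- revcomp(rev)
  rc_fwd <- revcomp(fwd)
  n <- nchar(reads)
  fwd_orient <- startsWith(reads, fwd) & endsWith(reads, rc_rev) &
    n >= nchar(fwd) + nchar(rev)
  rev_orient <- !fwd_orient & startsWith(reads, rev) &
    endsWith(reads, rc_fwd) & n >= nchar(fwd) + nchar(rev)
  insert <- reads
  insert[fwd_orient] <- substr(reads[fwd_orient], nchar(fwd) + 1L,
                               n[fwd_orient] - nchar(rev))
  insert[rev_orient] <- substr(reads[rev_orient], nchar(rev) + 1L,
                               n[rev_orient] - nchar(fwd))
  data.frame(insert = insert, trimmed = fwd_orient | rev_orient,
             orientation = ifelse(fwd_orient, "forward",
                                  ifelse(rev_orient, "reverse",
                                         NA_character_)),
             stringsAsFactors = FALSE)
}
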