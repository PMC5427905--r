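## Locus model: exon catalog, junction catalog, junction probes, transcripts
## and terminal-sequence ambiguity.
##
## All genomic coordinates are 1-based inclusive, matching the convention of
## the hg19 exon table the default catalog reproduces. BED export (see
## junction_scan) converts to 0-based half-open.

#' Default VEGFA exon catalog (hg19)
#'
#' The fourteen fully specified VEGFA exons on chromosome 6 (plus strand),
#' 1-based inclusive coordinates. Exon 8a is the canonical proximal acceptor
#' of the terminal exon; exon 8b starts immediately after 8a ends, so the
#' canonical terminal exon is the contiguous 8a+8b block and use of the 8b
#' acceptor (skipping 8a) would generate the VEGFA_xxx_b isoforms. Putative
#' first exons with unknown start coordinates (1B, 1C, 1D) are not included;
#' supply a user catalog via [load_exon_catalog()] to add them.
#'
#' @return data.frame with columns `name`, `chrom`, `start`, `end`, `strand`.
#' @export
#' @examples
#' cat6 <- vegfa_exon_catalog()
#' subset(cat6, name %in% c("8a", "8b"))
vegfa_exon_catalog <- function() {
  catalog <- data.frame(
    name  = c("1a", "1b", "1A", "2", "3", "4", "5",
              "6a", "6b", "6c", "7a", "7b", "8a", "8b"),
    chrom = "chr6",
    start = c(43737946L, 43738363L, 43739722L, 43742078L, 43745206L,
              43746197L, 43746626L, 43748469L, 43748523L, 43748541L,
              43749693L, 43749790L, 43752278L, 43752344L),
    end   = c(43738362L, 43739049L, 43739838L, 43742129L, 43745402L,
              43746273L, 43746655L, 43748522L, 43748540L, 43748591L,
              43749789L, 43749824L, 43752343L, 43754223L),
    strand = "+",
    stringsAsFactors = FALSE
  )
  validate_exon_catalog(catalog)
}

#' Validate an exon catalog
#'
#' Checks column presence, coordinate sanity (`start <= end`), strand values
#' and uniqueness of exon names.
#'
#' @param catalog data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return the validated catalog (invisibly unchanged).
#' @export
validate_exon_catalog <- function(catalog) {
  required <- c("name", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(catalog))
  if (length(missing))
    stop("exon catalog lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(catalog$name))
    stop("duplicate exon name(s): ",
         paste(unique(catalog$name[duplicated(catalog$name)]), collapse = ", "))
  bad <- which(catalog$start > catalog$end)
  if (length(bad))
    stop("exon '", catalog$name[bad[1]], "': start > end")
  if (!all(catalog$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  catalog$start <- as.integer(catalog$start)
  catalog$end <- as.integer(catalog$end)
  catalog
}

#' Load an exon catalog from a tab-delimited file
#'
#' Expected header: `name chrom start end strand`; coordinates 1-based
#' inclusive. Malformed rows are reported with their line number.
#'
#' @param path path to the tab-delimited table.
#' @return validated exon catalog data.frame.
#' @export
load_exon_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty exon catalog file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("name", "chrom", "start", "end", "strand")))
    stop("line 1: expected header 'name\\tchrom\\tstart\\tend\\tstrand'")
  rows <- lapply(seq_along(lines)[-1], function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 5L)
      stop("line ", i, ": expected 5 tab-delimited fields, found ",
           length(fields))
    start <- suppressWarnings(as.integer(fields[3]))
    end <- suppressWarnings(as.integer(fields[4]))
    if (is.na(start) || is.na(end))
      stop("line ", i, ": non-integer coordinate")
    data.frame(name = fields[1], chrom = fields[2], start = start,
               end = end, strand = fields[5], stringsAsFactors = FALSE)
  })
  validate_exon_catalog(do.call(rbind, rows))
}

#' Write an exon catalog to the tab-delimited exchange format
#'
#' @param catalog exon catalog data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exon_catalog <- function(catalog, path) {
  catalog <- validate_exon_catalog(catalog)
  write_tsv(catalog[, c("name", "chrom", "start", "end", "strand")], path)
}

# lengths of exons (named integer vector)
exon_lengths <- function(catalog) {
  stats::setNames(catalog$end - catalog$start + 1L, catalog$name)
}

catalog_row <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) stop("unknown exon: '", name, "'")
  catalog[i, , drop = FALSE]
}

#' Build a donor x acceptor junction catalog
#'
#' One junction per (donor, acceptor) pair, named `"donor-acceptor"`, with
#' intron coordinates `donor_end + 1 .. acceptor_start - 1`. Output order is
#' deterministic: donors in genomic order, then acceptors in genomic order.
#'
#' @param catalog exon catalog data.frame.
#' @param donors character vector of donor exon names.
#' @param acceptors character vector of acceptor exon names.
#' @return data.frame with columns `name`, `donor_exon`, `acceptor_exon`,
#'   `donor_end`, `acceptor_start`, `intron_first`, `intron_last`.
#' @export
#' @examples
#' jx <- build_junction_catalog(vegfa_exon_catalog(),
#'                              c("4", "5", "6a", "7a", "7b"), c("8a", "8b"))
#' nrow(jx)  # ten junctions
build_junction_catalog <- function(catalog, donors, acceptors) {
  catalog <- validate_exon_catalog(catalog)
  for (nm in c(donors, acceptors)) catalog_row(catalog, nm)
  donors <- donors[order(catalog$start[match(donors, catalog$name)])]
  acceptors <- acceptors[order(catalog$start[match(acceptors, catalog$name)])]
  grid <- expand.grid(acceptor_exon = acceptors, donor_exon = donors,
                      stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[order(match(grid$donor_exon, donors),
                     match(grid$acceptor_exon, acceptors)), ]
  donor_end <- catalog$end[match(grid$donor_exon, catalog$name)]
  acceptor_start <- catalog$start[match(grid$acceptor_exon, catalog$name)]
  bad <- which(donor_end + 1L >= acceptor_start)
  if (length(bad))
    stop("not a forward junction: ", grid$donor_exon[bad[1]], "-",
         grid$acceptor_exon[bad[1]],
         " (donor must end at least two bases before acceptor starts)")
  out <- data.frame(
    name = paste(grid$donor_exon, grid$acceptor_exon, sep = "-"),
    donor_exon = grid$donor_exon,
    acceptor_exon = grid$acceptor_exon,
    donor_end = donor_end,
    acceptor_start = acceptor_start,
    intron_first = donor_end + 1L,
    intron_last = acceptor_start - 1L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Construct a locus reference
#'
#' A contiguous reference window with its sequence and exon catalog.
#'
#' @param chrom chromosome name.
#' @param region_start,region_end 1-based inclusive window bounds.
#' @param sequence DNA string covering the window (`A`,`C`,`G`,`T`,`N`).
#' @param exons exon catalog data.frame; every exon must lie in the window.
#' @return object of class `locus_reference`.
#' @export
locus_reference <- function(chrom, region_start, region_end, sequence, exons) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != region_end - region_start + 1L)
    stop("sequence length (", nchar(sequence), ") != region span (",
         region_end - region_start + 1L, ")")
  if (!grepl("^[ACGTN]+$", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  exons <- validate_exon_catalog(exons)
  if (!all(exons$chrom == chrom))
    stop("all exons must be on '", chrom, "'")
  out_of_window <- exons$start < region_start | exons$end > region_end
  if (any(out_of_window))
    stop("exon '", exons$name[which(out_of_window)[1]],
         "' lies outside the reference window")
  structure(
    list(chrom = chrom, region_start = as.integer(region_start),
         region_end = as.integer(region_end), sequence = sequence,
         exons = exons),
    class = "locus_reference"
  )
}

#' @export
print.locus_reference <- function(x, ...) {
  cat("<locus_reference> ", x$chrom, ":", x$region_start, "-", x$region_end,
      " (", nchar(x$sequence), " bases, ", nrow(x$exons), " exons)\n",
      sep = "")
  invisible(x)
}

#' Extract genomic subsequence from a locus reference
#'
#' @param locus `locus_reference`.
#' @param start,end 1-based inclusive genomic coordinates.
#' @return character scalar.
#' @export
locus_subseq <- function(locus, start, end) {
  stopifnot(inherits(locus, "locus_reference"))
  if (start < locus$region_start || end > locus$region_end || start > end)
    stop("requested interval ", start, "-", end,
         " not contained in reference window")
  substr(locus$sequence, start - locus$region_start + 1L,
         end - locus$region_start + 1L)
}

#' Sequence of a named exon
#'
#' @param locus `locus_reference`.
#' @param name exon name.
#' @return character scalar.
#' @export
exon_seq <- function(locus, name) {
  row <- catalog_row(locus$exons, name)
  locus_subseq(locus, row$start, row$end)
}

#' Extract a junction-spanning probe
#'
#' The probe is the last `flank` bases of the donor exon concatenated with
#' the first `flank` bases of the acceptor exon (2 x `flank` bases total;
#' 22 at the default flank of 11). Exact containment of the probe in a read
#' is evidence for the junction.
#'
#' @param locus `locus_reference` covering both exons.
#' @param junction one-row junction data.frame (see
#'   [build_junction_catalog()]) or a junction name present in `junctions`.
#' @param flank bases taken from each side of the splice (default 11).
#' @return list of class `junction_probe` with elements `junction_name`,
#'   `flank`, `donor_half`, `acceptor_half`, `sequence`.
#' @export
extract_probe <- function(locus, junction, flank = 11L) {
  stopifnot(inherits(locus, "locus_reference"), flank >= 1L)
  j <- junction
  if (is.data.frame(j)) stopifnot(nrow(j) == 1L)
  donor <- catalog_row(locus$exons, j$donor_exon)
  acceptor <- catalog_row(locus$exons, j$acceptor_exon)
  if (flank > donor$end - donor$start + 1L)
    stop("flank ", flank, " exceeds length of donor exon '", donor$name, "'")
  if (flank > acceptor$end - acceptor$start + 1L)
    stop("flank ", flank, " exceeds length of acceptor exon '",
         acceptor$name, "'")
  donor_half <- locus_subseq(locus, donor$end - flank + 1L, donor$end)
  acceptor_half <- locus_subseq(locus, acceptor$start,
                                acceptor$start + flank - 1L)
  structure(
    list(junction_name = j$name, flank = as.integer(flank),
         donor_half = donor_half, acceptor_half = acceptor_half,
         sequence = paste0(donor_half, acceptor_half)),
    class = "junction_probe"
  )
}

#' Build the probe set for a junction catalog
#'
#' @param locus `locus_reference`.
#' @param junctions junction catalog data.frame.
#' @param flank bases per side (default 11, giving 22-base probes).
#' @return data.frame with columns `junction`, `flank`, `donor_half`,
#'   `acceptor_half`, `sequence`.
#' @export
build_probes <- function(locus, junctions, flank = 11L) {
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    p <- extract_probe(locus, junctions[i, ], flank)
    data.frame(junction = p$junction_name, flank = p$flank,
               donor_half = p$donor_half, acceptor_half = p$acceptor_half,
               sequence = p$sequence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write probes as FASTA (record id = junction name)
#'
#' @param probes probe data.frame from [build_probes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  write_fasta(stats::setNames(probes$sequence, probes$junction), path)
}

#' Assemble a transcript from an ordered exon chain
#'
#' The spliced sequence is the concatenation of the exon subsequences in
#' chain order. Chain exons must be strictly increasing and non-overlapping
#' on the genome. A chain ending `..., "8a", "8b"` (genomically contiguous)
#' models the canonical full terminal exon 8; a chain ending `..., "8b"`
#' models a VEGFA_xxx_b-type isoform using the distal acceptor.
#'
#' @param locus `locus_reference`.
#' @param name transcript name.
#' @param exon_chain character vector of exon names in transcript order.
#' @return object of class `transcript_model` with elements `name`,
#'   `exon_chain`, `sequence` and a `boundaries` data.frame giving, for each
#'   inter-exon boundary, the transcript coordinate of its last upstream
#'   base, its `donor-acceptor` name, and whether it is a true splice
#'   junction (intervening intron) or a contiguous block boundary.
#' @export
assemble_transcript <- function(locus, name, exon_chain) {
  stopifnot(inherits(locus, "locus_reference"), length(exon_chain) >= 1L)
  rows <- do.call(rbind, lapply(exon_chain, catalog_row,
                                catalog = locus$exons))
  if (length(exon_chain) > 1L) {
    prev_end <- rows$end[-nrow(rows)]
    next_start <- rows$start[-1]
    if (any(next_start <= prev_end))
      stop("exon chain is out of genomic order or overlapping at '",
           exon_chain[which(next_start <= prev_end)[1] + 1L], "'")
  }
  pieces <- vapply(exon_chain, function(e) exon_seq(locus, e), character(1))
  lens <- nchar(pieces)
  boundaries <- if (length(exon_chain) > 1L) {
    data.frame(
      pos = cumsum(lens)[-length(lens)],
      name = paste(exon_chain[-length(exon_chain)], exon_chain[-1], sep = "-"),
      donor_exon = exon_chain[-length(exon_chain)],
      acceptor_exon = exon_chain[-1],
      is_splice = rows$start[-1] > rows$end[-nrow(rows)] + 1L,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(pos = integer(0), name = character(0),
               donor_exon = character(0), acceptor_exon = character(0),
               is_splice = logical(0), stringsAsFactors = FALSE)
  }
  structure(
    list(name = name, exon_chain = exon_chain,
         sequence = paste(pieces, collapse = ""), boundaries = boundaries),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$name, ": ",
      paste(x$exon_chain, collapse = ","), " (", nchar(x$sequence),
      " bases)\n", sep = "")
  invisible(x)
}

#' Exon chains of the principal VEGFA-like isoforms
#'
#' Chains for seven canonical isoforms (all ending in the contiguous 8a+8b
#' terminal exon, i.e. using the canonical 8a acceptor) and, when
#' `include_8b = TRUE`, two VEGFA_xxx_b-type chains that splice directly to
#' the 8b acceptor. Chains are simplified to the exon catalog's resolution:
#' what matters downstream is which exon-8 junction each isoform carries
#' (4-8a for 111, 5-8a for 121, 6a-8a for 145, 7a-8a for 148, 7b-8a for
#' 165/183/189; 7b-8b and 5-8b for the "b" forms).
#'
#' @param include_8b also return the exon-8b-spliced chains.
#' @return named list of character vectors.
#' @export
vegfa_transcript_chains <- function(include_8b = FALSE) {
  chains <- list(
    VEGFA_111 = c("1a", "1b", "2", "3", "4", "8a", "8b"),
    VEGFA_121 = c("1a", "1b", "2", "3", "4", "5", "8a", "8b"),
    VEGFA_145 = c("1a", "1b", "2", "3", "4", "5", "6a", "8a", "8b"),
    VEGFA_148 = c("1a", "1b", "2", "3", "4", "5", "7a", "8a", "8b"),
    VEGFA_165 = c("1a", "1b", "2", "3", "4", "5", "7a", "7b", "8a", "8b"),
    VEGFA_183 = c("1a", "1b", "2", "3", "4", "5", "6a", "6b", "6c", "7a",
                  "7b", "8a", "8b"),
    VEGFA_189 = c("1a", "1b", "2", "3", "4", "5", "6a", "7a", "7b", "8a",
                  "8b")
  )
  if (include_8b) {
    chains$VEGFA_165b <- c("1a", "1b", "2", "3", "4", "5", "7a", "7b", "8b")
    chains$VEGFA_121b <- c("1a", "1b", "2", "3", "4", "5", "8b")
  }
  chains
}

#' Assemble several transcripts at once
#'
#' @param locus `locus_reference`.
#' @param chains named list of exon chains (default
#'   [vegfa_transcript_chains()]).
#' @return named list of `transcript_model` objects.
#' @export
assemble_transcripts <- function(locus, chains = vegfa_transcript_chains()) {
  stats::setNames(
    lapply(names(chains), function(nm) assemble_transcript(locus, nm,
                                                           chains[[nm]])),
    names(chains))
}

# longest common suffix of two character scalars
common_suffix_length <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  m <- min(la, lb)
  if (m == 0L) return(0L)
  av <- substring(a, la - m + seq_len(m), la - m + seq_len(m))
  bv <- substring(b, lb - m + seq_len(m), lb - m + seq_len(m))
  eq <- rev(av == bv)          # eq[1] compares the final bases
  mismatch <- which(!eq)
  if (length(mismatch) == 0L) m else mismatch[1] - 1L
}

common_prefix_length <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  if (m == 0L) return(0L)
  av <- substring(a, seq_len(m), seq_len(m))
  bv <- substring(b, seq_len(m), seq_len(m))
  mismatch <- which(av != bv)
  if (length(mismatch) == 0L) m else mismatch[1] - 1L
}

#' Shared terminal sequence between two exons
#'
#' Length of the longest common suffix of the two exon sequences: the number
#' of bases at their 3' ends that are identical. A spliced read whose donor
#' overhang is no longer than this value cannot be placed unambiguously
#' between the two exons (the basis of the exon-7/exon-8a misalignment
#' artifact, where this value is 3). Symmetric in its arguments; computed
#' from sequence, never assumed.
#'
#' @param locus `locus_reference`.
#' @param exon_a,exon_b exon names.
#' @return integer shared suffix length (>= 0).
#' @export
shared_terminal_ambiguity <- function(locus, exon_a, exon_b) {
  common_suffix_length(exon_seq(locus, exon_a), exon_seq(locus, exon_b))
}

#' Shared initial sequence between two exons
#'
#' Acceptor-side analogue of [shared_terminal_ambiguity()]: length of the
#' longest common prefix of the two exon sequences.
#'
#' @inheritParams shared_terminal_ambiguity
#' @return integer shared prefix length (>= 0).
#' @export
shared_initial_ambiguity <- function(locus, exon_a, exon_b) {
  common_prefix_length(exon_seq(locus, exon_a), exon_seq(locus, exon_b))
}

#' Terminal-ambiguity report over exon pairs
#'
#' For every ordered pair of distinct exons, the shared terminal suffix
#' length and the derived minimum safe donor overhang (shared length + 1).
#'
#' @param locus `locus_reference`.
#' @param exon_names exons to include (default: all in the catalog).
#' @return data.frame with columns `exon_a`, `exon_b`, `shared_suffix_len`,
#'   `min_safe_overhang`.
#' @export
ambiguity_report <- function(locus, exon_names = locus$exons$name) {
  grid <- expand.grid(exon_b = exon_names, exon_a = exon_names,
                      stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[grid$exon_a != grid$exon_b, ]
  seqs <- vapply(exon_names, function(e) exon_seq(locus, e), character(1))
  shared <- mapply(function(a, b) common_suffix_length(seqs[[a]], seqs[[b]]),
                   grid$exon_a, grid$exon_b)
  out <- data.frame(exon_a = grid$exon_a, exon_b = grid$exon_b,
                    shared_suffix_len = as.integer(shared),
                    min_safe_overhang = as.integer(shared) + 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Audit probe specificity against a transcript set
#'
#' For each probe, lists every transcript that contains the probe sequence
#' (or its reverse complement) contiguously, and flags the probe
#' "non-specific" if it occurs in a transcript that does not carry its
#' junction. With flank larger than any shared terminal sequence, a probe
#' should occur exactly in the transcripts carrying its junction — this is
#' why exact 2k-mer matching is immune to the short-overhang misalignment
#' artifact.
#'
#' @param probes probe data.frame from [build_probes()].
#' @param transcripts list of `transcript_model` objects.
#' @return list with `hits` (probe x transcript rows: `junction`,
#'   `transcript`, `contained`, `has_junction`) and `summary` (per-probe
#'   `junction`, `n_transcripts_hit`, `specific`).
#' @export
probe_cross_match_audit <- function(probes, transcripts) {
  tx_names <- vapply(transcripts, function(t) t$name, character(1))
  tx_seqs <- vapply(transcripts, function(t) t$sequence, character(1))
  tx_junctions <- lapply(transcripts, function(t)
    t$boundaries$name[t$boundaries$is_splice])
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    p <- probes$sequence[i]
    prc <- revcomp(p)
    contained <- grepl(p, tx_seqs, fixed = TRUE) |
      grepl(prc, tx_seqs, fixed = TRUE)
    has_junction <- vapply(tx_junctions, function(js)
      probes$junction[i] %in% js, logical(1))
    rows[[i]] <- data.frame(junction = probes$junction[i],
                            transcript = tx_names, contained = contained,
                            has_junction = has_junction,
                            stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  summary <- do.call(rbind, lapply(split(hits, hits$junction), function(h) {
    data.frame(junction = h$junction[1],
               n_transcripts_hit = sum(h$contained),
               specific = !any(h$contained & !h$has_junction),
               stringsAsFactors = FALSE)
  }))
  summary <- summary[match(probes$junction, summary$junction), ]
  rownames(summary) <- NULL
  list(hits = hits, summary = summary)
}
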