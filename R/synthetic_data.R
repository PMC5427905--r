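## Synthetic data: a seeded toy locus mirroring the VEGFA exon structure,
## transcript-mixture read simulation with per-read ground truth, amplicon
## pools and SJ-format fixtures.
##
## The toy locus is a scaled-down stand-in for the hg19 VEGFA window: same
## fourteen exons, same contiguity structure (1a|1b, 6a|6b|6c, 7a|7b and
## 8a|8b are genomically contiguous), with an engineered shared terminal
## suffix (default 3 bases) between exons 7b and 8a that reproduces the
## sequence feature behind the short-overhang misalignment artifact.

#' Specification for the toy locus generator
#'
#' Defaults give exons of 24-400 bases (exon 8b large enough to contain a
#' full 100-base read) and introns of 120-400 bases, for a total span of
#' about 3 kb — small enough that exhaustive substring oracles over the
#' whole locus run in milliseconds. Exons 7b and 8a keep their real lengths
#' (35 and 66 bases).
#'
#' @param exon_lengths named integer vector of exon lengths; names must be
#'   the fourteen catalog exon names.
#' @param intron_lengths named integer vector of intron lengths, keyed by
#'   the upstream exon; exon pairs absent from this map are genomically
#'   contiguous (as 1a|1b, 6a|6b, 6b|6c, 7a|7b, 8a|8b are in hg19).
#' @param shared_suffix engineered exact shared terminal suffix between
#'   exons 7b and 8a (default 3).
#' @param flank probe flank the generated locus must support uniquely
#'   (default 11).
#' @param seed integer seed for the generator.
#' @return list of class `toy_locus_spec`.
#' @export
toy_locus_spec <- function(exon_lengths = NULL, intron_lengths = NULL,
                           shared_suffix = 3L, flank = 11L, seed = 1L) {
  if (is.null(exon_lengths)) {
    exon_lengths <- c("1a" = 60L, "1b" = 40L, "1A" = 30L, "2" = 30L,
                      "3" = 48L, "4" = 40L, "5" = 30L, "6a" = 36L,
                      "6b" = 24L, "6c" = 30L, "7a" = 48L, "7b" = 35L,
                      "8a" = 66L, "8b" = 400L)
  }
  if (is.null(intron_lengths)) {
    intron_lengths <- c("1b" = 200L, "1A" = 150L, "2" = 250L, "3" = 300L,
                        "4" = 120L, "5" = 350L, "6c" = 400L, "7b" = 380L)
  }
  exon_order <- c("1a", "1b", "1A", "2", "3", "4", "5", "6a", "6b", "6c",
                  "7a", "7b", "8a", "8b")
  if (!setequal(names(exon_lengths), exon_order))
    stop("exon_lengths must name exactly the fourteen catalog exons")
  exon_lengths <- exon_lengths[exon_order]
  if (any(exon_lengths < 2L * flank + 2L))
    stop("all exon lengths must be at least 2*flank + 2 (",
         2L * flank + 2L, ")")
  if (shared_suffix < 0L || shared_suffix >= flank)
    stop("shared_suffix must be in [0, flank)")
  structure(
    list(exon_lengths = exon_lengths, intron_lengths = intron_lengths,
         shared_suffix = as.integer(shared_suffix), flank = as.integer(flank),
         seed = as.integer(seed)),
    class = "toy_locus_spec"
  )
}

# default junction set: all exon-8 junctions
default_junction_donors <- function() c("4", "5", "6a", "7a", "7b")
default_junction_acceptors <- function() c("8a", "8b")

#' Generate the toy locus
#'
#' Draws a random sequence with the exon/intron structure of the spec,
#' engineers the shared terminal suffix between exons 7b and 8a (exactly
#' `shared_suffix` bases, not more), and rejection-samples until
#' (a) every default exon-8 junction probe at the spec flank is unique —
#' absent from the locus on both strands and present in canonical and
#' 8b-spliced transcripts only across its own junction — and (b) no exon
#' pair other than (7b, 8a) shares a terminal suffix (or initial prefix) of
#' `flank` bases or more.
#'
#' @param spec a [toy_locus_spec()].
#' @param max_attempts rejection-sampling bound (default 100).
#' @return a `locus_reference` (chromosome `"chrT"`) whose `$exons` catalog
#'   mirrors the VEGFA exon names.
#' @export
#' @examples
#' locus <- make_toy_locus(toy_locus_spec(seed = 7))
#' shared_terminal_ambiguity(locus, "7b", "8a")  # engineered: 3
make_toy_locus <- function(spec = toy_locus_spec(), max_attempts = 100L) {
  stopifnot(inherits(spec, "toy_locus_spec"))
  pad <- 50L
  el <- spec$exon_lengths
  il <- spec$intron_lengths
  exon_names <- names(el)
  # genomic layout
  starts <- integer(length(el)); ends <- integer(length(el))
  pos <- pad + 1L
  for (i in seq_along(el)) {
    starts[i] <- pos
    ends[i] <- pos + el[i] - 1L
    gap <- if (i < length(el) && exon_names[i] %in% names(il))
      il[[exon_names[i]]] else 0L
    pos <- ends[i] + gap + 1L
  }
  region_end <- ends[length(el)] + pad
  catalog <- data.frame(name = exon_names, chrom = "chrT", start = starts,
                        end = ends, strand = "+", stringsAsFactors = FALSE)
  set.seed(spec$seed)
  s <- spec$shared_suffix
  i7b <- match("7b", exon_names); i8a <- match("8a", exon_names)
  for (attempt in seq_len(max_attempts)) {
    seqchars <- sample(c("A", "C", "G", "T"), region_end, replace = TRUE)
    # engineer: last s bases of 8a equal last s bases of 7b ...
    if (s > 0L)
      seqchars[(ends[i8a] - s + 1L):ends[i8a]] <-
        seqchars[(ends[i7b] - s + 1L):ends[i7b]]
    # ... and the next base upstream differs, so the shared suffix is exact
    p8a <- ends[i8a] - s; p7b <- ends[i7b] - s
    if (seqchars[p8a] == seqchars[p7b])
      seqchars[p8a] <- sample(setdiff(c("A", "C", "G", "T"),
                                      seqchars[p7b]), 1L)
    locus <- locus_reference("chrT", 1L, region_end,
                             paste(seqchars, collapse = ""), catalog)
    if (toy_locus_ok(locus, spec)) return(locus)
  }
  stop("could not satisfy probe-uniqueness constraints in ", max_attempts,
       " attempts; try longer exons or a different seed")
}

# constraint check for make_toy_locus
toy_locus_ok <- function(locus, spec) {
  flank <- spec$flank
  s <- spec$shared_suffix
  if (shared_terminal_ambiguity(locus, "7b", "8a") != s) return(FALSE)
  # no other exon pair ambiguous at probe scale (suffixes or prefixes)
  nm <- locus$exons$name
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    if (nm[i] == "7b" && nm[j] == "8a") next
    if (shared_terminal_ambiguity(locus, nm[i], nm[j]) >= flank) return(FALSE)
  }
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    if (shared_initial_ambiguity(locus, nm[i], nm[j]) >= flank) return(FALSE)
  }
  junctions <- build_junction_catalog(locus$exons,
                                      default_junction_donors(),
                                      default_junction_acceptors())
  probes <- build_probes(locus, junctions, flank)
  if (anyDuplicated(probes$sequence)) return(FALSE)
  # probes must not occur anywhere in the genomic sequence (either strand)
  for (p in probes$sequence) {
    if (grepl(p, locus$sequence, fixed = TRUE)) return(FALSE)
    if (grepl(revcomp(p), locus$sequence, fixed = TRUE)) return(FALSE)
  }
  # and must occur in transcripts exactly across their own junction
  tx <- assemble_transcripts(locus, vegfa_transcript_chains(include_8b = TRUE))
  for (i in seq_len(nrow(probes))) {
    p <- probes$sequence[i]
    for (t in tx) {
      n_occ <- length(gregexpr(p, t$sequence, fixed = TRUE)[[1]])
      if (!grepl(p, t$sequence, fixed = TRUE)) n_occ <- 0L
      carries <- probes$junction[i] %in%
        t$boundaries$name[t$boundaries$is_splice]
      if (carries && n_occ != 1L) return(FALSE)
      if (!carries && n_occ != 0L) return(FALSE)
      if (grepl(revcomp(p), t$sequence, fixed = TRUE)) return(FALSE)
    }
  }
  TRUE
}

#' Read-simulation configuration
#'
#' @param n_reads number of reads (fragments when `paired = TRUE`; each
#'   fragment yields two mates, counted downstream as two reads).
#' @param read_length read length in bases (default 100).
#' @param paired emit mate pairs from opposite fragment ends.
#' @param error_rate per-base substitution probability in `[0, 1)`;
#'   substitutions only, no indels.
#' @param isoform_weights named non-negative weights over transcript names;
#'   reads are drawn from transcripts with probability proportional to
#'   weight.
#' @param fragment_length fragment size for paired mode (default
#'   `2 * read_length + 50`).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_reads, read_length = 100L, paired = FALSE,
                       error_rate = 0, isoform_weights, fragment_length = NULL,
                       seed = 1L) {
  stopifnot(n_reads >= 0, read_length >= 2L,
            error_rate >= 0, error_rate < 1,
            length(isoform_weights) > 0, all(isoform_weights >= 0),
            sum(isoform_weights) > 0)
  if (is.null(names(isoform_weights)))
    stop("isoform_weights must be named by transcript")
  if (is.null(fragment_length)) fragment_length <- 2L * read_length + 50L
  structure(
    list(n_reads = as.integer(n_reads), read_length = as.integer(read_length),
         paired = isTRUE(paired), error_rate = error_rate,
         isoform_weights = isoform_weights,
         fragment_length = as.integer(fragment_length),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# vectorised iid substitution errors; handles mixed read lengths
inject_errors <- function(seqs, rate, chunk = 50000L) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (grp in split(seq_along(seqs), nchar(seqs))) {
    L <- nchar(seqs[grp[1]])
    for (ck in split(grp, ceiling(seq_along(grp) / chunk))) {
      n <- length(ck)
      hit <- which(stats::runif(n * L) < rate)
      if (length(hit) == 0L) next
      r <- ((hit - 1L) %/% L) + 1L   # read index within chunk
      p <- ((hit - 1L) %% L) + 1L    # position within read
      ord <- order(r); r <- r[ord]; p <- p[ord]
      rank <- stats::ave(seq_along(r), r, FUN = seq_along)
      for (k in unique(rank)) {
        sel <- rank == k
        ri <- ck[r[sel]]; pi <- p[sel]
        cur <- substr(seqs[ri], pi, pi)
        # random substitution to one of the three other bases
        off <- sample.int(3L, sum(sel), replace = TRUE)
        new <- bases[((match(cur, bases) - 1L + off) %% 4L) + 1L]
        tmp <- seqs[ri]
        substr(tmp, pi, pi) <- new
        seqs[ri] <- tmp
      }
    }
  }
  seqs
}

# truth junction table for a set of read windows on transcripts
truth_junction_table <- function(read_id, tx_index, win_start, win_end,
                                 transcripts) {
  out <- list()
  for (t in seq_along(transcripts)) {
    b <- transcripts[[t]]$boundaries
    b <- b[b$is_splice, , drop = FALSE]
    if (nrow(b) == 0L) next
    sel_t <- which(tx_index == t)
    if (length(sel_t) == 0L) next
    for (k in seq_len(nrow(b))) {
      pos <- b$pos[k]
      sp <- sel_t[win_start[sel_t] <= pos & win_end[sel_t] >= pos + 1L]
      if (length(sp) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        read_id = read_id[sp], junction = b$name[k],
        donor_overhang = pos - win_start[sp] + 1L,
        acceptor_overhang = win_end[sp] - pos,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), junction = character(0),
                      donor_overhang = integer(0),
                      acceptor_overhang = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$read_id, res$junction), , drop = FALSE]
}

#' Simulate sequencing reads from a transcript mixture
#'
#' Reads are drawn by (i) choosing a transcript with probability
#' proportional to its weight, (ii) a uniform start over valid positions,
#' (iii) a random strand (reverse complement with probability 0.5), and
#' (iv) iid substitution errors. In paired mode each fragment yields two
#' mates from opposite ends (`/1` and `/2`), each recorded as its own read.
#' A per-read truth table records the source transcript, window and strand,
#' and a junction table records every splice junction a read window spans
#' with at least one base on each side, with donor/acceptor overhangs.
#'
#' @param transcripts named list of `transcript_model` objects.
#' @param config a [sim_config()].
#' @return list with `reads` (named uppercase character vector), `truth`
#'   (data.frame `read_id`, `transcript`, `start`, `strand`) and
#'   `truth_junctions` (data.frame `read_id`, `junction`, `donor_overhang`,
#'   `acceptor_overhang`).
#' @export
simulate_reads <- function(transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$isoform_weights
  unknown <- setdiff(names(w), names(transcripts))
  if (length(unknown))
    stop("isoform_weights name unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  transcripts <- transcripts[names(w)[w > 0]]
  w <- w[w > 0]
  tx_seq <- vapply(transcripts, function(t) t$sequence, character(1))
  L <- nchar(tx_seq)
  rl <- config$read_length
  span <- if (config$paired) config$fragment_length else rl
  if (any(L < span))
    stop(if (config$paired) "fragment_length" else "read_length",
         " exceeds the length of transcript '",
         names(transcripts)[which(L < span)[1]], "'")
  set.seed(config$seed)
  n <- config$n_reads
  if (n == 0L) {
    return(list(reads = character(0),
                truth = data.frame(read_id = character(0),
                                   transcript = character(0),
                                   start = integer(0), strand = character(0),
                                   stringsAsFactors = FALSE),
                truth_junctions = truth_junction_table(character(0),
                                                       integer(0), integer(0),
                                                       integer(0),
                                                       transcripts)))
  }
  idx <- sample.int(length(transcripts), n, replace = TRUE,
                    prob = w / sum(w))
  max_start <- L[idx] - span + 1L
  fstart <- 1L + pmin(as.integer(floor(stats::runif(n) * max_start)),
                      max_start - 1L)
  flip <- stats::runif(n) < 0.5
  if (!config$paired) {
    ids <- sprintf("r%06d", seq_len(n))
    seqs <- substring(tx_seq[idx], fstart, fstart + rl - 1L)
    seqs[flip] <- revcomp(seqs[flip])
    win_start <- fstart; win_end <- fstart + rl - 1L
    read_tx <- idx
    strand <- ifelse(flip, "-", "+")
  } else {
    # mate 1 from the fragment 5' end, mate 2 reverse-complemented from the
    # 3' end; a flipped fragment swaps which physical end is read first
    s1 <- fstart
    s2 <- fstart + span - rl
    ids_base <- sprintf("r%06d", seq_len(n))
    m1 <- substring(tx_seq[idx], s1, s1 + rl - 1L)
    m2 <- revcomp(substring(tx_seq[idx], s2, s2 + rl - 1L))
    m1f <- revcomp(substring(tx_seq[idx], s2, s2 + rl - 1L))
    m2f <- substring(tx_seq[idx], s1, s1 + rl - 1L)
    mate1 <- ifelse(flip, m1f, m1)
    mate2 <- ifelse(flip, m2f, m2)
    ids <- c(rbind(paste0(ids_base, "/1"), paste0(ids_base, "/2")))
    seqs <- c(rbind(mate1, mate2))
    win_start <- c(rbind(ifelse(flip, s2, s1), ifelse(flip, s1, s2)))
    win_end <- win_start + rl - 1L
    read_tx <- rep(idx, each = 2L)
    strand <- c(rbind(ifelse(flip, "-", "+"), ifelse(flip, "+", "-")))
  }
  seqs <- inject_errors(seqs, config$error_rate)
  names(seqs) <- ids
  truth <- data.frame(read_id = ids,
                      transcript = names(transcripts)[read_tx],
                      start = win_start, strand = strand,
                      stringsAsFactors = FALSE)
  tj <- truth_junction_table(ids, read_tx, win_start, win_end, transcripts)
  list(reads = seqs, truth = truth, truth_junctions = tj)
}

#' Simulate an amplicon sequencing pool
#'
#' Every read is a full-length in-silico PCR product of its template, with
#' iid substitution errors. Per-template read counts are apportioned
#' deterministically from the weights (largest-remainder rounding), so the
#' recorded truth proportions match the requested mixture exactly; read
#' order is then shuffled under the seed.
#'
#' @param templates named list of `transcript_model` objects (or named
#'   character sequences); each must amplify uniquely with `primers`.
#' @param weights named non-negative mixture weights over template names.
#' @param primers a [primer_pair()].
#' @param n_reads pool size.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param revcomp_fraction fraction of reads emitted reverse-complemented
#'   (default 0: reads equal their template amplicon when `error_rate = 0`).
#' @return list with `reads` (named character), `truth` (data.frame
#'   `read_id`, `template`) and `products` (named character amplicons).
#' @export
simulate_amplicon_reads <- function(templates, weights, primers, n_reads,
                                    error_rate = 0, seed = 1L,
                                    revcomp_fraction = 0) {
  stopifnot(n_reads >= 0, error_rate >= 0, error_rate < 1)
  if (is.null(names(weights)) ||
      !all(names(weights) %in% names(templates)))
    stop("weights must be named by template")
  templates <- templates[names(weights)]
  products <- vapply(names(templates), function(nm) {
    insilico_pcr(templates[[nm]], primers)$product_sequence
  }, character(1))
  set.seed(seed)
  counts <- largest_remainder(n_reads, weights)
  reads <- rep(products, counts)
  template <- rep(names(templates), counts)
  if (n_reads > 0) {
    perm <- sample.int(n_reads)
    reads <- reads[perm]; template <- template[perm]
  }
  ids <- sprintf("a%06d", seq_len(n_reads))
  reads <- inject_errors(unname(reads), error_rate)
  if (revcomp_fraction > 0 && n_reads > 0) {
    flip <- stats::runif(n_reads) < revcomp_fraction
    reads[flip] <- revcomp(reads[flip])
  }
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, template = template,
                          stringsAsFactors = FALSE),
       products = products)
}

#' Write a splice-junction fixture in the 9-column SJ dialect
#'
#' Emits tab-delimited lines `chrom, intron_first, intron_last, strand code,
#' motif code, annotated flag, unique count, multimapping count, max
#' overhang` with 1-based intron coordinates and no header (the format
#' spliced aligners emit as `SJ.out.tab`). Defaults encode strand code 1
#' (plus) and motif code 1 (GT/AG); consumers must not rely on motif codes.
#'
#' @param records data.frame with columns `chrom`, `intron_first`,
#'   `intron_last`, `unique_count` and optionally `strand_code`,
#'   `motif_code`, `annotated`, `multi_count`, `max_overhang`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sj_fixture <- function(records, path) {
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "intron_first", "intron_last", "unique_count")
                %in% names(records)),
            all(records$unique_count >= 0))
  defaults <- list(strand_code = 1L, motif_code = 1L, annotated = 0L,
                   multi_count = 0L, max_overhang = 25L)
  for (nm in names(defaults))
    if (is.null(records[[nm]])) records[[nm]] <- defaults[[nm]]
  out <- records[, c("chrom", "intron_first", "intron_last", "strand_code",
                     "motif_code", "annotated", "unique_count",
                     "multi_count", "max_overhang")]
  write_tsv(out, path, col.names = FALSE)
}

#' Build SJ records from a junction catalog and counts
#'
#' Convenience for fixture construction: one SJ record per junction with
#' the given unique-read count.
#'
#' @param junctions junction catalog data.frame.
#' @param unique_counts integer vector (recycled) of unique-read counts.
#' @param chrom chromosome name for the records.
#' @param max_overhang reported maximum overhang (recycled).
#' @return data.frame suitable for [write_sj_fixture()].
#' @export
sj_records_from_counts <- function(junctions, unique_counts, chrom = "chr6",
                                   max_overhang = 25L) {
  data.frame(chrom = chrom,
             intron_first = junctions$intron_first,
             intron_last = junctions$intron_last,
             unique_count = as.integer(unique_counts),
             max_overhang = as.integer(max_overhang),
             stringsAsFactors = FALSE)
}
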