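## Small shared helpers: sequence string utilities and sequence-file IO.

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over character vectors (ACGTN alphabet,
#' case-insensitive; output is uppercase). Names are preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  # base-R path for small inputs; Biostrings (C) for large read sets
  if (length(x) * max(nchar(x), 1L) < 10000L) {
    comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
    out <- vapply(comp, function(s)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
      character(1), USE.NAMES = FALSE)
    out <- toupper(out)
  } else {
    out <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
  names(out) <- names(x)
  out
}

# TRUE for strings over {A,C,G,T} only (uppercase after normalisation)
is_dna <- function(x) grepl("^[ACGT]+$", toupper(x))

# uniform random DNA of total length n (character scalar)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# largest-remainder apportionment of n into counts proportional to w
largest_remainder <- function(n, w) {
  stopifnot(n >= 0, all(w >= 0), sum(w) > 0)
  quota <- n * w / sum(w)
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Read sequences from FASTA/FASTQ (plain or gzip)
#'
#' Auto-detects gzip by magic bytes and FASTA vs FASTQ by the first record
#' character, then delegates parsing to Biostrings. Character vectors and
#' `DNAStringSet` objects pass through (uppercased).
#'
#' @param x file path, character vector of sequences, or `DNAStringSet`.
#' @return named uppercase character vector of sequences.
#' @export
read_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
    return(out)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !is_dna(x)) {
    fmt <- sniff_sequence_format(x)
    ss <- Biostrings::readDNAStringSet(x, format = fmt)
    out <- toupper(as.character(ss))
    # keep only the record id (first whitespace-delimited token)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(x)) {
    out <- toupper(x)
    if (is.null(names(out)) && length(out) > 0)
      names(out) <- sprintf("seq%d", seq_along(out))
    return(out)
  }
  stop("cannot interpret 'x' as sequences (path, character vector or DNAStringSet)")
}

# gzip magic bytes + first-character format detection
sniff_sequence_format <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  con <- if (gz) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) stop("empty sequence file: ", path)
  if (startsWith(first, "@")) "fastq"
  else if (startsWith(first, ">")) "fasta"
  else stop("cannot detect FASTA/FASTQ format of ", path)
}

#' Write reads to FASTQ
#'
#' Phred+33 with a fixed quality character for every base.
#'
#' @param reads named character vector of read sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param quality_char single quality character (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
  ss <- Biostrings::DNAStringSet(unname(reads))
  names(ss) <- ids
  quals <- Biostrings::BStringSet(vapply(
    nchar(reads), function(n) strrep(quality_char, n), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

# write a data.frame as TSV (no quotes, no row names)
write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}
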