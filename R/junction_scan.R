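## Junction evidence, route 1 and route 2: exact probe matching in raw reads
## and extraction/annotation of splice-junction records from SJ tables.

#' Scan reads for exact junction-probe matches
#'
#' A read is counted for a probe if and only if the probe sequence occurs as
#' an exact, contiguous, case-insensitive substring of the read or (by
#' default) of its reverse complement. A read contributes at most once to a
#' given probe, tandem occurrences included; reads containing `N` at the
#' match site never match. Mates of a pair are scanned as independent reads
#' and counted separately.
#'
#' @param reads FASTQ/FASTA path (plain or gzip), character vector, or
#'   `DNAStringSet`.
#' @param probes probe data.frame from [build_probes()] (columns `junction`,
#'   `sequence`) or a named character vector of probe sequences.
#' @param both_strands also match the reverse complement of each probe
#'   (default `TRUE`).
#' @param sample sample label stored in the result.
#' @param detail keep the per-read hit matrix (reads x probes) in the
#'   result, for oracle comparisons.
#' @return object of class `scan_result`: list with `sample`,
#'   `total_reads`, `counts` (data.frame `junction`, `count`, `per_million`
#'   — the latter `NA` until [normalize_per_million()]) and, with
#'   `detail = TRUE`, a logical `hits` matrix.
#' @export
#' @examples
#' probes <- data.frame(junction = "j1", sequence = "ACGTACGTACGTACGTACGTAC")
#' scan_reads(c(paste0("TT", probes$sequence, "GG"), "AAAAAAAAAAAAAAAAAAAAAAAA"),
#'            probes)$counts
scan_reads <- function(reads, probes, both_strands = TRUE,
                       sample = "sample1", detail = FALSE) {
  if (is.character(probes) && is.null(dim(probes))) {
    nm <- names(probes)
    if (is.null(nm)) nm <- sprintf("probe%d", seq_along(probes))
    probes <- data.frame(junction = nm, sequence = unname(probes),
                         stringsAsFactors = FALSE)
  }
  stopifnot(nrow(probes) > 0)
  probes$sequence <- toupper(probes$sequence)
  if (anyDuplicated(probes$sequence))
    stop("probe sequences must be distinct")
  bad <- !is_dna(probes$sequence)
  if (any(bad))
    stop("probe '", probes$junction[which(bad)[1]],
         "' contains non-ACGT characters")
  seqs <- read_sequences(reads)
  rs <- Biostrings::DNAStringSet(unname(seqs))
  hits <- matrix(FALSE, nrow = length(seqs), ncol = nrow(probes),
                 dimnames = list(names(seqs), probes$junction))
  for (i in seq_len(nrow(probes))) {
    h <- Biostrings::vcountPattern(probes$sequence[i], rs, fixed = TRUE) > 0L
    if (both_strands)
      h <- h | Biostrings::vcountPattern(revcomp(probes$sequence[i]), rs,
                                         fixed = TRUE) > 0L
    hits[, i] <- h
  }
  multi <- sum(rowSums(hits) > 1L)
  if (multi > 0L)
    warning(multi, " read(s) matched more than one probe; ",
            "each counted once per probe")
  counts <- data.frame(junction = probes$junction,
                       count = as.integer(colSums(hits)),
                       per_million = NA_real_, stringsAsFactors = FALSE)
  out <- list(sample = sample, total_reads = length(seqs), counts = counts)
  if (detail) out$hits <- hits
  structure(out, class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> sample '", x$sample, "': ", x$total_reads,
      " reads scanned\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Normalise scan counts to hits per million reads
#'
#' The denominator is the total number of reads scanned, matched or not.
#' Raw counts are preserved alongside the normalised values.
#'
#' @param result a `scan_result`.
#' @return the `scan_result` with `counts$per_million` populated.
#' @export
normalize_per_million <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  if (result$total_reads <= 0L)
    stop("cannot normalise: total_reads is 0")
  result$counts$per_million <-
    result$counts$count / result$total_reads * 1e6
  result
}

#' Parse an SJ file, keeping junctions inside a genomic window
#'
#' Reads the 9-column tab-delimited splice-junction dialect (1-based
#' inclusive intron coordinates) and returns the records whose chromosome
#' matches and whose intron lies entirely within `[start, end]` (boundary
#' inclusive; records straddling the window edge are excluded).
#'
#' @param path SJ file path.
#' @param chrom window chromosome.
#' @param start,end window bounds, 1-based inclusive.
#' @return data.frame with columns `chrom`, `intron_first`, `intron_last`,
#'   `strand_code`, `motif_code`, `annotated`, `unique_count`,
#'   `multi_count`, `max_overhang`.
#' @export
parse_sj_file <- function(path, chrom, start, end) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("chrom", "intron_first", "intron_last", "strand_code",
            "motif_code", "annotated", "unique_count", "multi_count",
            "max_overhang")
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(integer(0)), 8L)), cols))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    i <- which(nf != 9L)[1]
    stop("line ", i, ": expected 9 tab-delimited columns, found ", nf[i])
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  ints <- suppressWarnings(matrix(as.integer(m[, 2:9]), ncol = 8L))
  if (anyNA(ints)) {
    i <- which(rowSums(is.na(ints)) > 0)[1]
    stop("line ", i, ": non-integer value in a coordinate/count column")
  }
  out <- data.frame(chrom = m[, 1], intron_first = ints[, 1],
                    intron_last = ints[, 2], strand_code = ints[, 3],
                    motif_code = ints[, 4], annotated = ints[, 5],
                    unique_count = ints[, 6], multi_count = ints[, 7],
                    max_overhang = ints[, 8], stringsAsFactors = FALSE)
  keep <- out$chrom == chrom & out$intron_first >= start &
    out$intron_last <= end
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate SJ records against a junction catalog
#'
#' A record whose intron coordinates equal a catalog junction's intron gets
#' that junction's name; any other record is labelled
#' `"novel:<intron_first>-<intron_last>"`. Records with identical introns
#' have their unique counts summed.
#'
#' @param records data.frame from [parse_sj_file()].
#' @param junctions junction catalog data.frame.
#' @param sample sample label for the output rows.
#' @return data.frame `sample`, `junction`, `unique_count` (one row per
#'   distinct intron).
#' @export
annotate_sj_records <- function(records, junctions, sample = "sample1") {
  if (nrow(records) == 0L)
    return(data.frame(sample = character(0), junction = character(0),
                      unique_count = integer(0), stringsAsFactors = FALSE))
  key <- paste(records$intron_first, records$intron_last, sep = "-")
  cat_key <- paste(junctions$intron_first, junctions$intron_last, sep = "-")
  name <- junctions$name[match(key, cat_key)]
  name[is.na(name)] <- paste0("novel:", key[is.na(name)])
  agg <- tapply(records$unique_count, name, sum)
  out <- data.frame(sample = sample, junction = names(agg),
                    unique_count = as.integer(agg), stringsAsFactors = FALSE)
  out <- out[order(match(out$junction, junctions$name), out$junction), ]
  rownames(out) <- NULL
  out
}

#' Pivot annotated SJ rows to a samples x junctions count table
#'
#' @param rows data.frame(s) from [annotate_sj_records()] (long format),
#'   rbind-ed across samples.
#' @return wide data.frame: first column `sample`, one integer column per
#'   junction (absent combinations are 0).
#' @export
junction_count_table <- function(rows) {
  samples <- unique(rows$sample)
  junctions <- unique(rows$junction)
  mat <- matrix(0L, nrow = length(samples), ncol = length(junctions),
                dimnames = list(samples, junctions))
  mat[cbind(match(rows$sample, samples), match(rows$junction, junctions))] <-
    as.integer(rows$unique_count)
  out <- data.frame(sample = samples, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter junction columns by total unique-read support
#'
#' Keeps the junction columns whose summed unique count across samples lies
#' in `[min_unique, max_unique]` (both bounds inclusive), the windowing used
#' to shortlist novel splice sites with intermediate support.
#'
#' @param table wide count table from [junction_count_table()].
#' @param min_unique,max_unique inclusive bounds on the column sum.
#' @return the table restricted to passing junction columns.
#' @export
filter_junctions <- function(table, min_unique, max_unique = Inf) {
  stopifnot(min_unique <= max_unique)
  jcols <- setdiff(names(table), "sample")
  sums <- vapply(jcols, function(j) sum(table[[j]]), numeric(1))
  keep <- jcols[sums >= min_unique & sums <= max_unique]
  table[, c("sample", keep), drop = FALSE]
}

#' Normalise a junction count table per billion aligned bases
#'
#' @param table wide count table from [junction_count_table()].
#' @param bases_aligned named numeric vector of per-sample aligned-base
#'   denominators (e.g. bases aligned to the chromosome carrying the gene).
#' @return the table with junction columns replaced by
#'   `count / bases_aligned * 1e9`.
#' @export
normalize_per_billion_bases <- function(table, bases_aligned) {
  denom <- bases_aligned[table$sample]
  if (anyNA(denom))
    stop("missing bases_aligned for sample(s): ",
         paste(table$sample[is.na(denom)], collapse = ", "))
  if (any(denom <= 0)) stop("bases_aligned must be positive")
  jcols <- setdiff(names(table), "sample")
  for (j in jcols) table[[j]] <- table[[j]] / denom * 1e9
  table
}

#' Export junction introns as BED
#'
#' Converts the internal 1-based inclusive intron coordinates to BED's
#' 0-based half-open convention (`chromStart = intron_first - 1`,
#' `chromEnd = intron_last`).
#'
#' @param junctions junction catalog data.frame.
#' @param path output path.
#' @param chrom chromosome name for the records.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path, chrom = "chr6") {
  bed <- data.frame(chrom = chrom,
                    chromStart = junctions$intron_first - 1L,
                    chromEnd = junctions$intron_last,
                    name = junctions$name,
                    stringsAsFactors = FALSE)
  write_tsv(bed, path, col.names = FALSE)
}
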