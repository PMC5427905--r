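## Detection-limit arithmetic, isoform ratios, cross-dataset correlation,
## and report assembly.

#' Proportion represented by a single read among n canonical reads
#'
#' With `n` reads observed at the canonical junction and zero at the
#' junction of interest, one hypothetical read of the latter would have
#' represented `100/n` percent of the transcripts — the informal
#' "one read would have represented" detection-limit statistic. Headline
#' reporting rounds to one significant figure (see
#' [round_signif_percent()]); the returned value is full precision.
#'
#' @param n_canonical count of canonical-junction reads (>= 1).
#' @return percent (numeric scalar).
#' @export
#' @examples
#' one_read_proportion(50230)             # 0.00199...
#' round_signif_percent(one_read_proportion(50230))  # 0.002
one_read_proportion <- function(n_canonical) {
  if (length(n_canonical) != 1L || is.na(n_canonical) || n_canonical < 1)
    stop("n_canonical must be a single count >= 1")
  100 / n_canonical
}

#' Round a percentage to significant figures for headline reporting
#'
#' @param percent numeric percentages.
#' @param digits significant figures (default 1).
#' @return rounded numeric vector.
#' @export
round_signif_percent <- function(percent, digits = 1L) {
  signif(percent, digits)
}

#' Upper confidence bound on a proportion after zero observations
#'
#' Given zero events in `n` trials, the exact (Clopper-Pearson-style) upper
#' bound at confidence `c` solves `(1 - p)^n = 1 - c`, i.e.
#' `p = 1 - (1 - c)^(1/n)`; the rule of three returns `3/n` for 95%
#' confidence. Both are returned as percentages. The exact bound
#' converges to the rule of three from above as `n` grows.
#'
#' @param n number of trials (>= 1).
#' @param confidence confidence level in (0, 1); default 0.95.
#' @param method `"exact"` (default) or `"rule_of_three"` (95% only).
#' @return percent (numeric scalar).
#' @export
#' @examples
#' zero_hit_upper_bound(300)                       # 0.9934...
#' zero_hit_upper_bound(300, method = "rule_of_three")  # 1
zero_hit_upper_bound <- function(n, confidence = 0.95,
                                 method = c("exact", "rule_of_three")) {
  method <- match.arg(method)
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a count >= 1")
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must lie strictly between 0 and 1")
  if (method == "rule_of_three") {
    if (!isTRUE(all.equal(confidence, 0.95)))
      stop("the rule of three is defined for confidence 0.95")
    return(100 * 3 / n)
  }
  100 * (1 - (1 - confidence)^(1 / n))
}

#' Detection-limit summary for a zero-observation junction
#'
#' Bundles the one-read proportion with the exact and rule-of-three upper
#' bounds, clearly labelled: the one-read statistic is the informal
#' "unlikely to be greater than" argument, the exact bound a formal 95%
#' limit.
#'
#' @param n_canonical canonical-junction read count (>= 1).
#' @param confidence confidence level for the exact bound.
#' @return one-row data.frame: `n_canonical`, `one_read_percent`,
#'   `one_read_percent_rounded`, `upper95_percent`,
#'   `rule_of_three_percent`.
#' @export
detection_limit <- function(n_canonical, confidence = 0.95) {
  one <- one_read_proportion(n_canonical)
  data.frame(
    n_canonical = n_canonical,
    one_read_percent = one,
    one_read_percent_rounded = round_signif_percent(one),
    upper95_percent = zero_hit_upper_bound(n_canonical, confidence, "exact"),
    rule_of_three_percent = if (isTRUE(all.equal(confidence, 0.95)))
      zero_hit_upper_bound(n_canonical, 0.95, "rule_of_three")
    else NA_real_)
}

#' Per-sample isoform junction ratio
#'
#' Ratio of counts for a numerator junction to a denominator junction
#' (default the exon 5-8a : 7b-8a ratio, which distinguishes the
#' diffusible-isoform fraction across tissues). Samples with a zero
#' denominator are excluded: their ratio is `NA` and a message logs them.
#'
#' @param counts either a named numeric vector of junction counts (one
#'   sample) or a wide count table from [junction_count_table()].
#' @param numerator,denominator junction column names.
#' @return named numeric vector of ratios (one per sample).
#' @export
isoform_ratio <- function(counts, numerator = "5-8a",
                          denominator = "7b-8a") {
  if (is.data.frame(counts)) {
    if (!all(c(numerator, denominator) %in% names(counts)))
      stop("count table lacks column '", numerator, "' or '", denominator,
           "'")
    num <- counts[[numerator]]
    den <- counts[[denominator]]
    labels <- if ("sample" %in% names(counts)) counts$sample
    else as.character(seq_len(nrow(counts)))
  } else {
    if (!all(c(numerator, denominator) %in% names(counts)))
      stop("counts lack entry '", numerator, "' or '", denominator, "'")
    num <- counts[[numerator]]
    den <- counts[[denominator]]
    labels <- "sample1"
  }
  ratio <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(ratio))
    message("excluded ", sum(is.na(ratio)),
            " sample(s) with zero '", denominator, "' count")
  stats::setNames(ratio, labels)
}

#' Squared Pearson correlation of ratios between two datasets
#'
#' Pairs with a missing ratio in either dataset are dropped; at least three
#' complete pairs with variance on both axes are required. Invariant under
#' affine rescaling of either axis and symmetric in the two datasets.
#'
#' @param ratio_a,ratio_b numeric vectors of per-sample ratios, aligned by
#'   position, or a single data.frame with columns `ratio_a` and `ratio_b`.
#' @return R-squared (numeric scalar).
#' @export
cross_dataset_r2 <- function(ratio_a, ratio_b = NULL) {
  if (is.data.frame(ratio_a)) {
    ratio_b <- ratio_a$ratio_b
    ratio_a <- ratio_a$ratio_a
  }
  ok <- is.finite(ratio_a) & is.finite(ratio_b)
  a <- ratio_a[ok]; b <- ratio_b[ok]
  if (length(a) < 3L)
    stop("need at least 3 samples with both ratios defined")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one dataset; R^2 undefined")
  stats::cor(a, b)^2
}

#' Format clean counts with bracketed artifact counts
#'
#' Renders summary-table entries such as `"0 (24)"`: the clean count, with
#' the number of artifact-flagged assignments in brackets when non-zero.
#'
#' @param clean integer vector of clean counts.
#' @param artifact integer vector of artifact counts.
#' @return character vector.
#' @export
format_count_with_artifact <- function(clean, artifact) {
  ifelse(artifact > 0, sprintf("%d (%d)", clean, artifact),
         as.character(clean))
}

#' Assemble a deterministic text + TSV report
#'
#' Writes `report.txt` plus `detection_limits.tsv`, `ratios.tsv` and
#' `junction_counts.tsv` for whichever inputs are supplied; omitted
#' sections are noted via a message. Headline percentages are rounded to
#' one significant figure; TSVs keep full precision. Identical inputs give
#' byte-identical output.
#'
#' @param dir output directory (created if needed).
#' @param scan_results list of `scan_result` objects (optional).
#' @param count_table wide junction count table (optional).
#' @param detection_limits data.frame from [detection_limit()] rows
#'   (optional).
#' @param ratios named numeric vector(s) from [isoform_ratio()] (optional).
#' @param assignment_summary `summary` data.frame of an
#'   `assignment_result` (optional); rendered with bracketed artifact
#'   counts.
#' @return named character vector of the files written, invisibly.
#' @export
build_report <- function(dir, scan_results = NULL, count_table = NULL,
                         detection_limits = NULL, ratios = NULL,
                         assignment_summary = NULL) {
  if (is.null(scan_results) && is.null(count_table) &&
      is.null(detection_limits) && is.null(ratios) &&
      is.null(assignment_summary))
    stop("at least one report input must be supplied")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  lines <- c("Junction evidence report", "========================")
  if (!is.null(scan_results)) {
    lines <- c(lines, "", "Probe scan (exact junction-probe hits):")
    for (sr in scan_results) {
      lines <- c(lines, sprintf("  sample %s: %d reads scanned", sr$sample,
                                sr$total_reads))
      lines <- c(lines, sprintf("    %-12s %8d  %s per million",
                                sr$counts$junction, sr$counts$count,
                                formatC(sr$counts$per_million, digits = 4,
                                        format = "fg")))
    }
  } else message("report: probe-scan section omitted (no input)")
  if (!is.null(assignment_summary)) {
    lines <- c(lines, "", "Spliced assignment (artifact counts bracketed):")
    lines <- c(lines, sprintf(
      "  %-12s %s", assignment_summary$junction,
      format_count_with_artifact(assignment_summary$clean,
                                 assignment_summary$artifact)))
  } else message("report: assignment section omitted (no input)")
  if (!is.null(detection_limits)) {
    lines <- c(lines, "", "Detection limits (zero-observation junctions):")
    lines <- c(lines, sprintf(
      paste0("  one read among %d canonical reads = %s%% ",
             "(exact 95%% upper bound %s%%)"),
      detection_limits$n_canonical,
      vapply(detection_limits$one_read_percent_rounded,
             function(v) format(v, scientific = FALSE), character(1)),
      vapply(round_signif_percent(detection_limits$upper95_percent, 2),
             function(v) format(v, scientific = FALSE), character(1))))
    f <- file.path(dir, "detection_limits.tsv")
    write_tsv(detection_limits, f)
    files["detection_limits"] <- f
  } else message("report: detection-limit section omitted (no input)")
  if (!is.null(ratios)) {
    lines <- c(lines, "", "Isoform junction ratios:")
    lines <- c(lines, sprintf("  %-16s %s", names(ratios),
                              formatC(ratios, digits = 4, format = "fg")))
    f <- file.path(dir, "ratios.tsv")
    write_tsv(data.frame(sample = names(ratios), ratio = unname(ratios),
                         stringsAsFactors = FALSE), f)
    files["ratios"] <- f
  } else message("report: ratio section omitted (no input)")
  if (!is.null(count_table)) {
    f <- file.path(dir, "junction_counts.tsv")
    write_tsv(count_table, f)
    files["junction_counts"] <- f
    lines <- c(lines, "",
               sprintf("Junction count table: %d sample(s) x %d junction(s)",
                       nrow(count_table), ncol(count_table) - 1L),
               sprintf("  written to %s", basename(f)))
  } else message("report: count-table section omitted (no input)")
  report_path <- file.path(dir, "report.txt")
  writeLines(lines, report_path)
  files["report"] <- report_path
  invisible(files)
}
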