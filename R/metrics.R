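#' Segmentation quality metrics, normalized scores and AM aggregation
#'
#' Three families of metrics evaluate a segmentation against its raw signal
#' and input reads: border contrast (median delta / MAD delta across segment
#' borders), segment homogeneity (inner standard deviation), and read
#' statistics (segmented/truncated counts; min, N50 and max segmented read
#' length). Raw metric values from several tools are normalized per metric
#' to 0-1 scores against the per-metric maximum, and summed per tool into an
#' aggregated metric (AM) score.
#'
#' @name metrics
NULL

#' Border contrast deltas
#'
#' For each internal segment border, compares a window of `window` samples
#' left of the border with `window` samples right of it: the absolute
#' difference of the two windows' medians (`stat = "median"`) or raw MADs
#' (`stat = "mad"`, no consistency factor). Borders with fewer than `window`
#' samples on either side are skipped, not padded. Higher deltas indicate
#' borders placed at genuine level/spread changes.
#'
#' @param signal a [signal_read] (or plain numeric vector).
#' @param segmentation a `segmentation` (or its `segments` data.frame with
#'   0-based `signal_start`).
#' @param window samples per side (default 6, the smallest segment size
#'   emitted by common basecaller move tables).
#' @param stat `"median"` or `"mad"`.
#' @return Numeric vector of per-border absolute differences (possibly
#'   empty). Dataset summaries take the median of these values over all
#'   reads.
#' @export
border_deltas <- function(signal, segmentation, window = 6,
                          stat = c("median", "mad")) {
  stat <- match.arg(stat)
  stopifnot(window >= 1)
  x <- if (inherits(signal, "signal_read")) signal$samples else as.numeric(signal)
  d <- if (inherits(segmentation, "segmentation")) segmentation$segments else
    segmentation
  borders <- d$signal_start[-1]                   # 0-based internal borders
  borders <- borders[borders - window >= 0 & borders + window <= length(x)]
  if (length(borders) == 0) return(numeric(0))
  f <- if (stat == "median") stats::median else raw_mad
  vapply(borders, function(b) {
    left <- x[(b - window + 1L):b]                # 0-based [b-w, b) -> 1-based
    right <- x[(b + 1L):(b + window)]             # 0-based [b, b+w)
    abs(f(left) - f(right))
  }, numeric(1))
}

#' Segment homogeneity
#'
#' Standard deviation of the inner fraction of each segment: segments
#' spanning at least `min_len` samples contribute the standard deviation of
#' their inner `inner_frac` (dropping `ceiling((1 - inner_frac)/2 * len)`
#' samples from each end, excluding border-transition samples); shorter
#' segments are skipped. Lower is better: a segment should contain signal
#' from a single k-mer.
#'
#' @inheritParams border_deltas
#' @param min_len minimum segment length in samples (default 10).
#' @param inner_frac central fraction retained (default 0.8).
#' @return Numeric vector of per-segment standard deviations (possibly
#'   empty); dataset summaries take the median.
#' @export
homogeneity <- function(signal, segmentation, min_len = 10, inner_frac = 0.8) {
  x <- if (inherits(signal, "signal_read")) signal$samples else as.numeric(signal)
  d <- if (inherits(segmentation, "segmentation")) segmentation$segments else
    segmentation
  len <- d$signal_end - d$signal_start
  keep <- which(len >= min_len)
  if (length(keep) == 0) return(numeric(0))
  vapply(keep, function(s) {
    l <- len[s]
    drop <- ceiling((1 - inner_frac) / 2 * l)
    from <- d$signal_start[s] + drop              # 0-based inclusive
    to <- d$signal_end[s] - drop                  # 0-based exclusive
    stats::sd(x[(from + 1L):to])
  }, numeric(1))
}

#' N50 length
#'
#' The length L such that reads of length >= L together hold at least half
#' of all bases.
#'
#' @param lengths numeric vector of read lengths.
#' @return The N50 value.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Read statistics of a segmentation run
#'
#' Compares input reads against a tool's segmentation output: how many reads
#' were segmented at all, how many were truncated (segmented base span
#' strictly smaller than the basecalled length: any uncovered nucleotide
#' counts), and the min/N50/max of the segmented base spans.
#'
#' @param read_lengths named numeric vector: basecalled length per input
#'   read_id.
#' @param seg_table segmentation table (data.frame with `read_id` rows, one
#'   per segment) as written by [write_segmentation()].
#' @param k k-mer length of the model the table was produced with (a read's
#'   segmented base span is its k-mer count + k - 1).
#' @return A one-row data.frame: `segmented`, `truncated`, `min_length`,
#'   `n50_length`, `max_length`.
#' @export
read_stats <- function(read_lengths, seg_table, k) {
  seg_ids <- unique(seg_table$read_id)
  segmented <- sum(names(read_lengths) %in% seg_ids)
  kmer_counts <- table(seg_table$read_id)
  spans <- as.numeric(kmer_counts) + k - 1
  names(spans) <- names(kmer_counts)
  shared <- intersect(names(read_lengths), names(spans))
  truncated <- sum(spans[shared] < read_lengths[shared])
  data.frame(segmented = segmented,
             truncated = truncated,
             min_length = if (length(spans)) min(spans) else NA_real_,
             n50_length = if (length(spans)) n50(spans) else NA_real_,
             max_length = if (length(spans)) max(spans) else NA_real_)
}

#' Normalize raw metric values to 0-1 scores
#'
#' Linear scaling against the per-metric maximum across tools: for
#' higher-better metrics `score = raw / max` (the maximum maps to 1, a raw 0
#' to 0); for lower-better metrics the scale is inverted, `score = 1 -
#' raw / max` (a raw 0 maps to 1, the maximum to 0). If all raws are zero
#' the scores are defined as 1 for lower-better and 0 for higher-better
#' metrics (logged).
#'
#' @param raw numeric vector of one metric's raw values, one per tool.
#' @param direction `"higher"` or `"lower"` (is a larger raw value better?).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
normalize_scores <- function(raw, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(raw)), all(raw >= 0))
  mx <- max(raw)
  if (mx == 0) {
    message("normalize_scores: all raw values are 0; scores set by direction")
    return(rep(if (direction == "lower") 1 else 0, length(raw)))
  }
  if (direction == "higher") raw / mx else 1 - raw / mx
}

#' Build a metric table and aggregate AM scores
#'
#' Assembles per-tool raw metric values into the benchmark layout: one row
#' per metric with a direction flag, one column per tool, normalized 0-1
#' scores per [normalize_scores()], and an aggregated metric (AM) row
#' holding each tool's column sum of unrounded scores. Generic externally
#' computed metrics (e.g. downstream assembly totals) are accepted the same
#' way via their direction flag.
#'
#' @param raw numeric matrix: metrics in rows, tools in columns, raw values.
#' @param directions character vector (`"higher"`/`"lower"`), one per row.
#' @return A `metric_table`: list with `raw`, `scores` (same shape),
#'   `directions` and `am` (named per-tool vector).
#' @export
metric_table <- function(raw, directions) {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == length(directions),
            all(directions %in% c("higher", "lower")))
  scores <- raw
  for (m in seq_len(nrow(raw))) {
    scores[m, ] <- normalize_scores(raw[m, ], directions[m])
  }
  structure(list(raw = raw, scores = scores, directions = directions,
                 am = colSums(scores)),
            class = "metric_table")
}

#' Aggregated metric (AM) score
#'
#' Column sum of normalized scores: one aggregate per tool. Rounding (to 2
#' decimals, half away from zero) happens only at presentation.
#'
#' @param scores a `metric_table` or a numeric score matrix (metrics x
#'   tools).
#' @return Named numeric vector of per-tool AM scores (unrounded).
#' @export
am_score <- function(scores) {
  if (inherits(scores, "metric_table")) return(scores$am)
  colSums(as.matrix(scores))
}

#' @export
print.metric_table <- function(x, digits = 3, ...) {
  disp <- matrix(sprintf(paste0("%.", digits, "f (%g)"), x$scores, x$raw),
                 nrow = nrow(x$raw), dimnames = dimnames(x$raw))
  print(disp, quote = FALSE)
  cat("AM score:\n")
  print(round_half_up(x$am, 2))
  invisible(x)
}

#' Example benchmark table: five tools on a human direct-RNA (RNA004) run
#'
#' A published-style example of the benchmark layout: raw metric values and
#' printed 3-decimal scores for the basecaller move table (Dorado) and four
#' dedicated segmentation tools on one human RNA004 dataset, covering
#' segmentation quality, read statistics and downstream-tool metrics. Used
#' in the worked examples and to verify the score arithmetic; shipped as a
#' plain TSV under `inst/extdata`.
#'
#' @return A list: `raw` (metric x tool matrix), `printed_scores` (same
#'   shape, the 3-decimal published scores), `directions`, and
#'   `printed_am` (2-decimal published AM per tool). Note the downstream
#'   rows' raw values are printed rounded (e.g. coverage to 1 decimal), so
#'   recomputing their scores from these raws does not reproduce the
#'   printed scores exactly; the segmentation and read-statistic rows do.
#' @export
example_benchmark <- function() {
  path <- system.file("extdata", "rna004_human_benchmark.tsv",
                      package = "squigseg", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tools <- c("dorado", "f5c_resquiggle", "f5c_eventalign", "uncalled4",
             "dynamont")
  raw <- as.matrix(tab[, paste0("raw_", tools)])
  printed <- as.matrix(tab[, paste0("score_", tools)])
  colnames(raw) <- colnames(printed) <- tools
  rownames(raw) <- rownames(printed) <- tab$metric
  am_row <- tab$metric == "am_score"
  list(raw = raw[!am_row, , drop = FALSE],
       printed_scores = printed[!am_row, , drop = FALSE],
       directions = tab$direction[!am_row],
       printed_am = stats::setNames(printed[am_row, ], tools))
}
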