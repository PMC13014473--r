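#' End-to-end segmentation of signal/read pairs
#'
#' The segmenter pairs raw signals with their basecalled reads by read_id,
#' normalizes each signal, runs the forward-backward HMM and writes one
#' segmentation table per dataset. Reads the topology cannot segment (fewer
#' than two signal samples per k-mer) are reported as structured
#' infeasibility records, never silently dropped.
#'
#' @name segmenter
NULL

#' Run configuration for the segmenter
#'
#' @param model a [kmer_model] (or a path to a model TSV, loaded on the fly).
#' @param orientation `"dna_5to3"` or `"rna_3to5"`.
#' @param normalization `"median_mad"` or `"none"`.
#' @param band_width nonnegative integer or `"full"`; default 100 k-mer
#'   positions around the diagonal.
#' @param params a [transition_params].
#' @return A `run_config` object.
#' @export
run_config <- function(model,
                       orientation = c("dna_5to3", "rna_3to5"),
                       normalization = c("median_mad", "none"),
                       band_width = 100,
                       params = transition_params()) {
  if (is.character(model)) model <- load_kmer_model(model)
  stopifnot(inherits(model, "kmer_model"), inherits(params, "transition_params"))
  structure(list(model = model,
                 orientation = match.arg(orientation),
                 normalization = match.arg(normalization),
                 band_width = band_width,
                 params = params),
            class = "run_config")
}

#' Segment one read
#'
#' Normalizes the signal, maps the sequence to k-mer indices, runs the full
#' forward-backward pass and extracts the MAP segmentation. Returns either a
#' `segmentation` or a structured infeasibility record (class
#' `infeasible_read`, with a `reason` code such as `"signal_too_short"`).
#'
#' @param signal a [signal_read].
#' @param read the matching [basecalled_read].
#' @param config a [run_config].
#' @return A `segmentation` or an `infeasible_read` record.
#' @export
segment_read <- function(signal, read, config) {
  stopifnot(inherits(signal, "signal_read"), inherits(read, "basecalled_read"),
            inherits(config, "run_config"))
  if (signal$read_id != read$read_id) {
    squigseg_error("squigseg_pairing_error",
      sprintf("read_id mismatch: signal %s vs basecall %s",
              signal$read_id, read$read_id))
  }
  n_seq <- nchar(read$sequence)
  k <- config$model$k
  infeasible <- function(reason) {
    structure(list(read_id = signal$read_id, reason = reason,
                   n_samples = length(signal$samples), n_bases = n_seq),
              class = "infeasible_read")
  }
  if (n_seq < k) return(infeasible("sequence_shorter_than_k"))
  kmers <- sequence_to_kmers(read, config$model, config$orientation)
  if (length(signal$samples) < MIN_SEGMENT_LEN * length(kmers)) {
    return(infeasible("signal_too_short"))
  }
  sig <- if (signal$normalized) signal else
    normalize_signal(signal, config$normalization, config$model)
  band <- make_band(length(sig$samples), length(kmers), config$band_width)
  ali <- align_read(sig, kmers, config$params, config$model, band)
  map_segmentation(posterior(ali), config$params, config$model)
}

## Central-base index (0-based, in the original read's coordinates) for
## k-mer window j (0-based). For even k the base left of center is used.
## For 3'-5' RNA the windows were taken over the reversed sequence, so the
## window offset is mapped back to original coordinates.
central_base_position <- function(kmer_index, k, n_bases, orientation) {
  central <- (k - 1L) %/% 2L                 # offset within the window
  if (orientation == "rna_3to5") {
    (n_bases - 1L) - (kmer_index + central)
  } else {
    kmer_index + central
  }
}

#' Write segmentations as a TSV table
#'
#' One row per segment, columns `read_id`, `signal_start`, `signal_end`
#' (0-based half-open sample interval), `base_position` (0-based index of
#' the k-mer's central base in the read; left-of-center for even k), `kmer`,
#' `posterior`, `border_prob`. Floats are written with 6 decimals.
#'
#' @param segs a list of `segmentation` objects (infeasible records are
#'   skipped).
#' @param path output path.
#' @param config the [run_config] used (supplies k and orientation for the
#'   base_position column); `NULL` leaves base_position = kmer_index.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(segs, path, config = NULL) {
  if (inherits(segs, "segmentation")) segs <- list(segs)
  segs <- Filter(function(s) inherits(s, "segmentation"), segs)
  header <- c("read_id", "signal_start", "signal_end", "base_position",
              "kmer", "posterior", "border_prob")
  rows <- lapply(segs, function(s) {
    d <- s$segments
    base_pos <- if (is.null(config)) d$kmer_index else
      central_base_position(d$kmer_index, config$model$k,
                            nchar_of_read(d, config), config$orientation)
    data.frame(read_id = s$read_id,
               signal_start = d$signal_start,
               signal_end = d$signal_end,
               base_position = base_pos,
               kmer = d$kmer,
               posterior = sprintf("%.6f", d$posterior),
               border_prob = sprintf("%.6f", d$border_prob),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(header))), header)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Number of bases of the read a segment table belongs to (for RNA
## coordinate flipping): recovered from the k-mer count.
nchar_of_read <- function(d, config) {
  nrow(d) + config$model$k - 1L
}

#' Read a segmentation TSV written by [write_segmentation()]
#'
#' @param path path to the TSV.
#' @return A data.frame with one row per segment.
#' @export
read_segmentation <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character"))
}

#' Read/write the portable signal table format
#'
#' The portable fixture format for raw signals: a two-column TSV with header
#' `read_id` and `samples`, samples comma-joined. Real datasets arrive as
#' pod5; this plain-text format carries the same per-read content and keeps
#' every module testable without binary inputs.
#'
#' @param path path to the TSV.
#' @return For `read_signals_tsv`, a named list of [signal_read]s.
#' @export
read_signals_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(read_id = "character"))
  if (!all(c("read_id", "samples") %in% names(tab))) {
    squigseg_error("squigseg_format_error",
                   "signal table needs columns read_id, samples")
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    signal_read(tab$read_id[i],
                as.numeric(strsplit(tab$samples[i], ",", fixed = TRUE)[[1]]))
  })
  stats::setNames(out, tab$read_id)
}

#' @param signals a list of [signal_read]s.
#' @rdname read_signals_tsv
#' @export
write_signals_tsv <- function(signals, path) {
  df <- data.frame(
    read_id = vapply(signals, function(s) s$read_id, character(1)),
    samples = vapply(signals, function(s)
      paste(sprintf("%.17g", s$samples), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read basecalled reads from FASTQ, FASTA or unaligned BAM/SAM
#'
#' Only read_id and sequence are consumed. FASTQ/FASTA are read with
#' Biostrings; BAM/SAM require the Rsamtools package.
#'
#' @param path path to a `.fastq`, `.fq`, `.fasta`, `.fa`, `.sam` or `.bam`
#'   file.
#' @return A named list of [basecalled_read]s.
#' @export
read_basecalls <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bam", "sam")) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      squigseg_error("squigseg_io_error",
                     "reading BAM/SAM requires the Rsamtools package")
    }
    if (ext == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
    } else bam <- path
    res <- Rsamtools::scanBam(bam,
      param = Rsamtools::ScanBamParam(what = c("qname", "seq")))[[1]]
    ids <- res$qname
    seqs <- as.character(res$seq)
  } else {
    fmt <- if (ext %in% c("fastq", "fq")) "fastq" else "fasta"
    ## BStringSet: tolerant of U in direct-RNA reads
    set <- Biostrings::readBStringSet(path, format = fmt)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  }
  out <- Map(basecalled_read, ids, seqs)
  stats::setNames(out, ids)
}

#' Segment a whole dataset
#'
#' Pairs signals and basecalled reads by read_id, segments each pair in
#' read_id order and (optionally) writes one segmentation table. Reads
#' present in only one source are counted as unpaired, infeasible reads are
#' counted and carried in the summary, and unexpected per-read errors are
#' caught and counted as failed: segmented + infeasible + failed equals the
#' number of paired reads, always.
#'
#' @param signals a named list of [signal_read]s, or a path to a signal TSV.
#' @param reads a named list of [basecalled_read]s, or a path to
#'   FASTQ/FASTA/BAM.
#' @param config a [run_config].
#' @param out optional output TSV path.
#' @return A `run_summary`: counts (`n_input_pairs`, `segmented`,
#'   `infeasible`, `failed`, `unpaired_signals`, `unpaired_reads`), the list
#'   of `segmentations`, the `infeasible` records and failure messages.
#' @export
run_dataset <- function(signals, reads, config, out = NULL) {
  if (is.character(signals)) signals <- read_signals_tsv(signals)
  if (is.character(reads)) reads <- read_basecalls(reads)
  sig_ids <- vapply(signals, function(s) s$read_id, character(1))
  read_ids <- vapply(reads, function(r) r$read_id, character(1))
  names(signals) <- sig_ids
  names(reads) <- read_ids
  shared <- sort(intersect(sig_ids, read_ids))

  segmentations <- list()
  infeasibles <- list()
  failures <- character(0)
  for (id in shared) {
    res <- tryCatch(
      segment_read(signals[[id]], reads[[id]], config),
      squigseg_error = function(e) e
    )
    if (inherits(res, "segmentation")) {
      segmentations[[id]] <- res
    } else if (inherits(res, "infeasible_read")) {
      infeasibles[[id]] <- res
    } else {
      failures[id] <- conditionMessage(res)
    }
  }
  if (!is.null(out)) write_segmentation(segmentations, out, config)
  structure(list(
    n_input_pairs = length(shared),
    segmented = length(segmentations),
    infeasible = length(infeasibles),
    failed = length(failures),
    unpaired_signals = length(setdiff(sig_ids, read_ids)),
    unpaired_reads = length(setdiff(read_ids, sig_ids)),
    segmentations = segmentations,
    infeasible_records = infeasibles,
    failures = failures
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(paste0("run summary: %d paired reads -> %d segmented, ",
                     "%d infeasible, %d failed\n"),
              x$n_input_pairs, x$segmented, x$infeasible, x$failed))
  if (x$unpaired_signals + x$unpaired_reads > 0) {
    cat(sprintf("  unpaired: %d signals, %d basecalled reads\n",
                x$unpaired_signals, x$unpaired_reads))
  }
  invisible(x)
}
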