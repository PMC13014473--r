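#' k-mer pore models and signal/read containers
#'
#' A k-mer pore model is the lookup table giving, for every k-nucleotide
#' context in the pore, the expected current level mean and spread. These
#' per-k-mer Gaussians are the emission distributions of the segmentation
#' HMM. Models are stored canonically over the DNA alphabet ACGT (U is
#' mapped to T at load time so one model serves both nucleic acids) in
#' lexicographic k-mer order.
#'
#' @name pore_model
NULL

MODEL_ALPHABET <- c("A", "C", "G", "T")

## All 4^k k-mers in lexicographic order.
all_kmers <- function(k) {
  stopifnot(k >= 1)
  grid <- expand.grid(rep(list(MODEL_ALPHABET), k), stringsAsFactors = FALSE)
  ## expand.grid varies the first factor fastest; reverse for lexicographic
  kmers <- do.call(paste0, rev(grid))
  sort(kmers)
}

## Uppercase and canonicalize U -> T; validate alphabet.
canonicalize_sequence <- function(x, what = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl(sprintf("[^%s]", paste(MODEL_ALPHABET, collapse = "")), x)
  if (any(bad)) {
    squigseg_error("squigseg_alphabet_error",
      sprintf("%s contains non-ACGT/U characters (first offender: %s)",
              what, x[which(bad)[1]]))
  }
  x
}

#' Construct a k-mer pore model
#'
#' @param kmers character vector of k-mer strings (U accepted, stored as T).
#' @param level_mean numeric vector of expected current levels, one per k-mer.
#' @param level_stdv numeric vector of positive current spreads, one per k-mer.
#'
#' @return An object of class `kmer_model`: a list with elements `k`,
#'   `kmers` (lexicographic), `level_mean`, `level_stdv`.
#'
#' @details The model must be complete: exactly one entry for each of the
#'   4^k k-mers over ACGT. k = 5 and k = 9 (the usual ONT R9/R10 model
#'   sizes) are accepted silently; any other k >= 1 is accepted with a
#'   notice.
#' @export
kmer_model <- function(kmers, level_mean, level_stdv) {
  if (length(kmers) == 0) {
    squigseg_error("squigseg_format_error", "empty k-mer model")
  }
  kmers <- canonicalize_sequence(as.character(kmers), "k-mer")
  lens <- nchar(kmers)
  k <- lens[1]
  if (any(lens != k)) {
    squigseg_error("squigseg_format_error",
      sprintf("ragged k-mer lengths in model: saw %s",
              paste(sort(unique(lens)), collapse = ", ")))
  }
  if (length(level_mean) != length(kmers) || length(level_stdv) != length(kmers)) {
    squigseg_error("squigseg_format_error",
                   "level_mean/level_stdv length does not match k-mer count")
  }
  expected <- all_kmers(k)
  missing <- setdiff(expected, kmers)
  if (length(missing) > 0) {
    shown <- utils::head(missing, 10)
    squigseg_error("squigseg_completeness_error",
      sprintf("incomplete k-mer model: %d of %d k-mers absent (e.g. %s)",
              length(missing), length(expected), paste(shown, collapse = ", ")))
  }
  if (anyDuplicated(kmers)) {
    squigseg_error("squigseg_completeness_error",
      sprintf("duplicated k-mers in model (e.g. %s)",
              kmers[which(duplicated(kmers))[1]]))
  }
  level_mean <- as.numeric(level_mean)
  level_stdv <- as.numeric(level_stdv)
  if (any(!is.finite(level_mean))) {
    squigseg_error("squigseg_validation_error",
      sprintf("non-finite level_mean for k-mer %s",
              kmers[which(!is.finite(level_mean))[1]]))
  }
  bad <- !is.finite(level_stdv) | level_stdv <= 0
  if (any(bad)) {
    squigseg_error("squigseg_validation_error",
      sprintf("non-positive level_stdv for k-mer %s", kmers[which(bad)[1]]))
  }
  ord <- order(kmers)
  if (!(k %in% c(5L, 9L))) {
    message(sprintf("note: k-mer model with unusual k = %d accepted", k))
  }
  structure(
    list(k = as.integer(k), kmers = kmers[ord],
         level_mean = level_mean[ord], level_stdv = level_stdv[ord]),
    class = "kmer_model"
  )
}

#' @export
print.kmer_model <- function(x, ...) {
  cat(sprintf("k-mer pore model: k = %d, %d k-mers\n", x$k, length(x$kmers)))
  cat(sprintf("  level_mean range: [%.3f, %.3f]\n",
              min(x$level_mean), max(x$level_mean)))
  cat(sprintf("  level_stdv range: [%.3f, %.3f]\n",
              min(x$level_stdv), max(x$level_stdv)))
  invisible(x)
}

#' Read a k-mer pore model from a tab-separated table
#'
#' Reads the de-facto ONT model table layout: tab-separated with a header
#' naming at least `kmer`, `level_mean` and `level_stdv`; extra columns are
#' ignored. k is inferred from the k-mer strings; U is canonicalized to T.
#'
#' @param path path to the TSV file.
#' @return A [kmer_model].
#' @export
load_kmer_model <- function(path) {
  if (!file.exists(path)) {
    squigseg_error("squigseg_io_error", sprintf("model file not found: %s", path))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("kmer", "level_mean", "level_stdv")
  absent <- setdiff(need, names(tab))
  if (length(absent) > 0) {
    squigseg_error("squigseg_format_error",
      sprintf("model table lacks column(s): %s", paste(absent, collapse = ", ")))
  }
  kmer_model(tab$kmer, tab$level_mean, tab$level_stdv)
}

#' Write a k-mer pore model as a tab-separated table
#'
#' Inverse of [load_kmer_model()]; numeric fields round-trip bit-identically
#' (written with full precision).
#'
#' @param model a [kmer_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_model"))
  df <- data.frame(kmer = model$kmers,
                   level_mean = sprintf("%.17g", model$level_mean),
                   level_stdv = sprintf("%.17g", model$level_stdv),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Index of each k-mer string in the model's lexicographic order (1-based).
kmer_to_index <- function(model, kmers) {
  idx <- match(kmers, model$kmers)
  if (anyNA(idx)) {
    squigseg_error("squigseg_validation_error",
      sprintf("k-mer %s absent from model", kmers[which(is.na(idx))[1]]))
  }
  idx
}

## Global location/spread of the model's level means, used to place
## normalized signals in model space.
model_global_mean <- function(model) mean(model$level_mean)
model_global_spread <- function(model) stats::sd(model$level_mean)

#' Signal and basecalled-read containers
#'
#' `signal_read()` wraps one raw current trace (the squiggle): an ordered
#' series of finite current samples for one read. `basecalled_read()` wraps
#' the basecaller's nucleotide sequence for the same read. Both are light
#' S3 records keyed by `read_id`.
#'
#' @param read_id read identifier.
#' @param samples numeric vector of current measurements, length >= 2.
#' @param normalized logical flag: are the samples already in model space?
#' @return A `signal_read` / `basecalled_read` object.
#' @export
signal_read <- function(read_id, samples, normalized = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    squigseg_error("squigseg_validation_error",
      sprintf("read %s: signal must have >= 2 samples", read_id))
  }
  if (any(!is.finite(samples))) {
    squigseg_error("squigseg_validation_error",
      sprintf("read %s: non-finite signal samples", read_id))
  }
  structure(list(read_id = as.character(read_id), samples = samples,
                 normalized = isTRUE(normalized)),
            class = "signal_read")
}

#' @param sequence nucleotide string (ACGT/U, case-insensitive).
#' @rdname signal_read
#' @export
basecalled_read <- function(read_id, sequence) {
  sequence <- canonicalize_sequence(as.character(sequence),
                                    sprintf("read %s", read_id))
  if (length(sequence) != 1 || nchar(sequence) < 1) {
    squigseg_error("squigseg_validation_error",
                   sprintf("read %s: empty sequence", read_id))
  }
  structure(list(read_id = as.character(read_id), sequence = sequence),
            class = "basecalled_read")
}

#' Map a basecalled sequence to the model's k-mer index series
#'
#' Slides a k-wide window over the sequence and returns the model index of
#' each k-mer, ordered to match signal time. For direct RNA
#' (`orientation = "rna_3to5"`) the pore reads the molecule 3'-to-5', so the
#' sequence is reversed before windowing to put the k-mers in signal time
#' order.
#'
#' @param read a [basecalled_read] (or a plain sequence string).
#' @param model a [kmer_model].
#' @param orientation `"dna_5to3"` (default) or `"rna_3to5"`.
#' @return Integer vector of length `nchar(sequence) - k + 1`: 1-based
#'   indices into `model$kmers`, with the k-mer strings as names.
#' @export
sequence_to_kmers <- function(read, model,
                              orientation = c("dna_5to3", "rna_3to5")) {
  orientation <- match.arg(orientation)
  seq <- if (inherits(read, "basecalled_read")) read$sequence else
    canonicalize_sequence(as.character(read))
  k <- model$k
  n <- nchar(seq)
  if (n < k) {
    squigseg_error("squigseg_infeasible_read",
      sprintf("sequence length %d < k = %d", n, k))
  }
  if (orientation == "rna_3to5") {
    seq <- paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
  }
  starts <- seq_len(n - k + 1)
  kmers <- substring(seq, starts, starts + k - 1)
  idx <- kmer_to_index(model, kmers)
  names(idx) <- kmers
  idx
}

#' Normalize a raw signal into model space
#'
#' `method = "median_mad"` standardizes the trace by its median and raw
#' median absolute deviation (no 1.4826 consistency factor), then rescales
#' affinely into model space using the model's global level mean and spread,
#' so the output median equals the model's global level mean exactly.
#' `method = "none"` passes samples through unchanged. Either way the output
#' is flagged `normalized`.
#'
#' @param read a [signal_read].
#' @param method `"median_mad"` or `"none"`.
#' @param model a [kmer_model] (required for `"median_mad"`).
#' @return A [signal_read] with `normalized = TRUE`.
#' @export
normalize_signal <- function(read, method = c("median_mad", "none"),
                             model = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(read, "signal_read"))
  if (method == "none") {
    read$normalized <- TRUE
    return(read)
  }
  stopifnot(inherits(model, "kmer_model"))
  x <- read$samples
  med <- stats::median(x)
  mad <- raw_mad(x)
  if (mad <= 0) {
    squigseg_error("squigseg_degenerate_signal",
      sprintf("read %s: MAD of signal is 0; cannot normalize", read$read_id))
  }
  z <- (x - med) / mad
  read$samples <- z * model_global_spread(model) + model_global_mean(model)
  read$normalized <- TRUE
  read
}

#' Build a synthetic k-mer pore model
#'
#' Constructs a complete toy model whose level means are evenly spaced in
#' lexicographic k-mer order, so that distinct k-mers always have distinct
#' expected levels. Useful for simulation and testing; not a real pore
#' calibration.
#'
#' @param k k-mer length.
#' @param level_min,level_max range over which level means are spread.
#' @param level_stdv common level spread (all k-mers).
#' @return A [kmer_model].
#' @export
synthetic_kmer_model <- function(k = 5, level_min = 60, level_max = 140,
                                 level_stdv = 1) {
  kmers <- all_kmers(k)
  n <- length(kmers)
  kmer_model(kmers,
             level_mean = seq(level_min, level_max, length.out = n),
             level_stdv = rep(level_stdv, n))
}
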