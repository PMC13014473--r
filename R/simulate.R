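#' Synthetic squiggle simulation with ground-truth segments
#'
#' The simulator shares its generative story with the segmentation HMM: per
#' k-mer, the molecule dwells in the pore for `2 + Geometric(a1)` signal
#' samples (support >= 2, mean `1 + 1/a1`, matching the align/extend
#' topology where one A cell is followed by a geometric number of E cells),
#' and each sample is drawn from the k-mer's pore-model Gaussian with its
#' spread scaled by `noise_scale`. Ground-truth segments are recorded in the
#' same 0-based half-open convention used everywhere else, so recovery can
#' be scored exactly.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' @param model a [kmer_model] supplying emission parameters.
#' @param a1 segment-opening probability controlling dwell geometry,
#'   in (0, 1); mean dwell is `1 + 1/a1` samples.
#' @param noise_scale multiplier on each k-mer's level_stdv; 0 gives
#'   noise-free signals at the level means.
#' @param fixed_dwell optional integer >= 2: use this constant dwell for
#'   every segment instead of the geometric draw.
#' @param orientation passed through to [sequence_to_kmers()].
#' @param n_reads number of reads for [simulate_dataset()].
#' @param len_min,len_max sequence length range (uniform) for random reads.
#' @param seed RNG seed used by the dataset generator.
#' @return A `sim_config` object.
#' @export
sim_config <- function(model, a1 = 0.1, noise_scale = 1, fixed_dwell = NULL,
                       orientation = "dna_5to3", n_reads = 10,
                       len_min = 30, len_max = 60, seed = 1) {
  stopifnot(inherits(model, "kmer_model"), a1 > 0, a1 < 1, noise_scale >= 0)
  if (!is.null(fixed_dwell)) {
    stopifnot(fixed_dwell >= MIN_SEGMENT_LEN)
    fixed_dwell <- as.integer(fixed_dwell)
  }
  stopifnot(len_min >= model$k, len_max >= len_min)
  structure(list(model = model, a1 = a1, noise_scale = noise_scale,
                 fixed_dwell = fixed_dwell, orientation = orientation,
                 n_reads = as.integer(n_reads), len_min = as.integer(len_min),
                 len_max = as.integer(len_max), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one read's squiggle with ground truth
#'
#' Draws a dwell per k-mer (constant `fixed_dwell`, or `2 + Geometric(a1)`)
#' and emits `Normal(mu_k, noise_scale * sigma_k)` samples for each. Uses
#' the current RNG state; seed management belongs to the caller (or to
#' [simulate_dataset()]).
#'
#' @param sequence nucleotide string of length >= k.
#' @param config a [sim_config].
#' @param read_id identifier for the generated read.
#' @return A list: `signal` ([signal_read], flagged normalized since samples
#'   are in model space), `read` ([basecalled_read]), and `truth` (a
#'   `segmentation` with the generating segments; posterior columns NA).
#' @export
simulate_read <- function(sequence, config, read_id = "sim_read") {
  stopifnot(inherits(config, "sim_config"))
  model <- config$model
  kmers <- sequence_to_kmers(sequence, model, config$orientation)
  n <- length(kmers)
  dwell <- if (!is.null(config$fixed_dwell)) {
    rep(config$fixed_dwell, n)
  } else {
    ## 1 A sample + (1 + failures-before-success) E samples
    2L + stats::rgeom(n, prob = config$a1)
  }
  mu <- model$level_mean[kmers]
  sd <- config$noise_scale * model$level_stdv[kmers]
  samples <- stats::rnorm(sum(dwell), mean = rep(mu, dwell), sd = rep(sd, dwell))
  ends <- cumsum(dwell)                       # 1-based inclusive
  starts <- c(0L, ends[-n])                   # 0-based
  truth <- structure(list(
    read_id = read_id,
    segments = data.frame(
      kmer_index = seq_len(n) - 1L,
      kmer = model$kmers[kmers],
      signal_start = starts,
      signal_end = ends,
      posterior = NA_real_,
      border_prob = NA_real_,
      stringsAsFactors = FALSE
    )
  ), class = "segmentation")
  list(signal = signal_read(read_id, samples, normalized = TRUE),
       read = basecalled_read(read_id, sequence),
       truth = truth)
}

## Random ACGT sequence of given length.
random_sequence <- function(len) {
  paste(sample(MODEL_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Simulate a dataset of reads, optionally writing fixture files
#'
#' Generates `n_reads` reads with random sequences (lengths uniform in
#' `[len_min, len_max]`) under `config$seed`; the same seed reproduces the
#' dataset byte-identically. With `out_prefix`, writes `<prefix>.signal.tsv`
#' (portable signal table), `<prefix>.fastq` and `<prefix>.truth.tsv`, all
#' cross-consistent by read_id.
#'
#' @param config a [sim_config].
#' @param out_prefix optional path prefix for fixture files.
#' @return A list with `signals`, `reads`, `truths` (named by read_id) and
#'   the file paths if written.
#' @export
simulate_dataset <- function(config, out_prefix = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sprintf("simread_%04d", seq_len(config$n_reads))
  lens <- sample(config$len_min:config$len_max, config$n_reads, replace = TRUE)
  sims <- lapply(seq_len(config$n_reads), function(i) {
    simulate_read(random_sequence(lens[i]), config, read_id = ids[i])
  })
  out <- list(signals = stats::setNames(lapply(sims, `[[`, "signal"), ids),
              reads = stats::setNames(lapply(sims, `[[`, "read"), ids),
              truths = stats::setNames(lapply(sims, `[[`, "truth"), ids))
  if (!is.null(out_prefix)) {
    sig_path <- paste0(out_prefix, ".signal.tsv")
    fq_path <- paste0(out_prefix, ".fastq")
    truth_path <- paste0(out_prefix, ".truth.tsv")
    write_signals_tsv(out$signals, sig_path)
    seqs <- Biostrings::BStringSet(
      vapply(out$reads, function(r) r$sequence, character(1)))
    names(seqs) <- ids
    Biostrings::writeXStringSet(seqs, fq_path, format = "fastq")
    write_segmentation(out$truths, truth_path)
    out$files <- c(signals = sig_path, reads = fq_path, truth = truth_path)
  }
  out
}

#' Boundary recovery accuracy
#'
#' Fraction of true internal segment boundaries matched by a predicted
#' boundary within a tolerance of `d` samples, for each `d` in `within`.
#' Boundaries are the `signal_start` values of segments 2..n (read ends are
#' shared by construction and not scored).
#'
#' @param truth,predicted `segmentation` objects (or their `segments`
#'   data.frames) for the same read.
#' @param within integer tolerances in samples.
#' @return Named numeric vector: fraction of true boundaries recovered at
#'   each tolerance.
#' @export
boundary_accuracy <- function(truth, predicted, within = c(0, 1, 2, 5)) {
  get_borders <- function(x) {
    d <- if (inherits(x, "segmentation")) x$segments else x
    d$signal_start[-1]
  }
  tb <- get_borders(truth)
  pb <- get_borders(predicted)
  if (length(tb) == 0) {
    return(stats::setNames(rep(NA_real_, length(within)), paste0("d", within)))
  }
  frac <- vapply(within, function(d) {
    mean(vapply(tb, function(b) any(abs(pb - b) <= d), logical(1)))
  }, numeric(1))
  stats::setNames(frac, paste0("d", within))
}
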