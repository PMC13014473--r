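#' The two-state align/extend segmentation HMM
#'
#' The signal-to-sequence alignment is a pair HMM over two states. State A
#' ("align") consumes one signal sample and advances to the next k-mer,
#' opening a new segment; state E ("extend") consumes one signal sample while
#' halting on the current k-mer, extending the open segment. A is reachable
#' only from E (transition probability `a1`), E is reachable from A (first
#' extension, probability `e1`, structurally 1) and from itself (continued
#' extension, probability `e2 = 1 - a1`). Because every segment consists of
#' one A cell followed by at least one E cell, the topology itself enforces a
#' minimum segment length of two signal samples. Emissions are the per-k-mer
#' Gaussians of the pore model; all computation is in natural-log space.
#'
#' @name hmm_core
NULL

MIN_SEGMENT_LEN <- 2L

#' Transition parameters of the align/extend HMM
#'
#' @param a1 probability of opening a new segment from E, in (0, 1].
#' @param e1 probability of the first extension out of A; structurally 1
#'   (A has a single outgoing edge) unless training overrides it.
#' @param e2 probability of continued extension from E; must satisfy
#'   `a1 + e2 = 1`.
#' @return An object of class `transition_params`.
#' @export
transition_params <- function(a1 = 0.1, e1 = 1, e2 = 1 - a1) {
  stopifnot(is.numeric(a1), is.numeric(e1), is.numeric(e2))
  if (a1 <= 0 || a1 > 1 || e1 <= 0 || e1 > 1 || e2 < 0 || e2 > 1) {
    squigseg_error("squigseg_validation_error",
                   "transition probabilities must lie in (0, 1]")
  }
  if (abs(a1 + e2 - 1) > 1e-12) {
    squigseg_error("squigseg_validation_error",
                   sprintf("a1 + e2 must equal 1 (got %.15g)", a1 + e2))
  }
  structure(list(a1 = a1, e1 = e1, e2 = e2), class = "transition_params")
}

#' @export
print.transition_params <- function(x, ...) {
  cat(sprintf("transition params: a1 = %.6g, e1 = %.6g, e2 = %.6g\n",
              x$a1, x$e1, x$e2))
  invisible(x)
}

#' Gaussian emission log-density
#'
#' Log of the Gaussian probability density of observing current `sample`
#' from the pore model's distribution for one k-mer:
#' `ln phi(t; mu_k, sigma_k)`.
#'
#' @param sample numeric current value(s), finite.
#' @param kmer_index 1-based index into `model$kmers` (recycled against
#'   `sample`).
#' @param model a [kmer_model].
#' @return Numeric log-density vector.
#' @export
emission_logpdf <- function(sample, kmer_index, model) {
  if (any(!is.finite(sample))) {
    squigseg_error("squigseg_validation_error", "non-finite signal sample")
  }
  stopifnot(all(kmer_index >= 1), all(kmer_index <= length(model$kmers)))
  stats::dnorm(sample, mean = model$level_mean[kmer_index],
               sd = model$level_stdv[kmer_index], log = TRUE)
}

## n_kmers x n_samples matrix of emission log-densities for one read.
emission_matrix <- function(samples, kmers, model) {
  n <- length(kmers)
  t_len <- length(samples)
  matrix(stats::dnorm(rep(samples, each = n),
                      mean = model$level_mean[kmers],
                      sd = model$level_stdv[kmers], log = TRUE),
         nrow = n, ncol = t_len)
}

#' Diagonal band for the dynamic programming matrices
#'
#' Restricts, for each signal index i, the k-mer indices j that the DP may
#' visit to a rectangle of half-width `band_width` around the rounded
#' diagonal `j = round(i * (n_kmers - 1) / (n_samples - 1))` (0-based;
#' half-up rounding), clamped to the valid range. The origin and terminal
#' cells always lie on the diagonal, so they are always inside the band.
#' `band_width = "full"` (or any width >= n_kmers) allows every cell.
#'
#' @param n_samples signal length (>= 2).
#' @param n_kmers number of k-mers (>= 1).
#' @param band_width nonnegative integer half-width, or `"full"`.
#' @return An object of class `squigseg_band`: list with integer vectors
#'   `lo` and `hi` (1-based inclusive j-range per signal index) and the
#'   `width` used.
#' @export
make_band <- function(n_samples, n_kmers, band_width = 100) {
  stopifnot(n_samples >= 2, n_kmers >= 1)
  full <- identical(band_width, "full") ||
    (is.numeric(band_width) && band_width >= n_kmers)
  if (full) {
    band <- list(lo = rep(1L, n_samples), hi = rep(as.integer(n_kmers), n_samples),
                 width = "full")
    class(band) <- "squigseg_band"
    return(band)
  }
  w <- as.integer(band_width)
  if (w < 0) {
    squigseg_error("squigseg_validation_error", "band_width must be >= 0")
  }
  i0 <- seq_len(n_samples) - 1               # 0-based signal index
  center <- floor(i0 * (n_kmers - 1) / (n_samples - 1) + 0.5)
  lo <- pmax(0, center - w)
  hi <- pmin(n_kmers - 1, center + w)
  band <- list(lo = as.integer(lo) + 1L, hi = as.integer(hi) + 1L, width = w)
  class(band) <- "squigseg_band"
  band
}

## Shared feasibility gate: each of the n_kmers segments needs >= 2 samples.
check_feasible <- function(n_samples, n_kmers, read_id = "?") {
  if (n_samples < MIN_SEGMENT_LEN * n_kmers) {
    squigseg_error("squigseg_infeasible_read",
      sprintf(paste0("read %s: signal length %d < %d = 2 x %d k-mers; ",
                     "the topology cannot place minimum-length segments"),
              read_id, n_samples, MIN_SEGMENT_LEN * n_kmers, n_kmers),
      reason = "signal_too_short")
  }
  invisible(TRUE)
}

check_band <- function(band, n_samples, n_kmers) {
  stopifnot(inherits(band, "squigseg_band"))
  if (length(band$lo) != n_samples || length(band$hi) != n_samples) {
    squigseg_error("squigseg_band_error", "band length does not match signal")
  }
  if (band$lo[1] > 1 || band$hi[n_samples] < n_kmers) {
    squigseg_error("squigseg_band_error",
                   "band excludes the origin or terminal cell")
  }
  invisible(TRUE)
}

#' Forward pass of the align/extend HMM
#'
#' Fills the banded log-space forward matrices alpha_A and alpha_E. Cell
#' (j, i) of either matrix holds the log-probability of all legal paths that
#' align signal prefix `t[0..i]` to k-mer prefix `k[0..j]` and end in that
#' state at that cell; the recursion is
#' `A[j,i] = E[j-1,i-1] + ln a1 + em(j,i)` and
#' `E[j,i] = logsumexp(A[j,i-1] + ln e1, E[j,i-1] + ln e2) + em(j,i)`,
#' with origin `A[0,0] = em(0,0)`. The total alignment score is read at the
#' terminal extend cell: `log_Z = E[n_kmers-1, n_samples-1]`.
#'
#' @param signal a [signal_read] (samples in model space).
#' @param kmers k-mer index series from [sequence_to_kmers()].
#' @param params a [transition_params].
#' @param model a [kmer_model].
#' @param band a `squigseg_band`, or `NULL` for the full band.
#' @param emissions optional precomputed emission matrix (internal reuse).
#' @return A list of class `squigseg_forward`: `log_forward_A`,
#'   `log_forward_E` (n_kmers x n_samples, -Inf outside the band), `log_Z`,
#'   plus the band and the inputs needed downstream.
#' @export
forward_pass <- function(signal, kmers, params, model, band = NULL,
                         emissions = NULL) {
  stopifnot(inherits(signal, "signal_read"))
  x <- signal$samples
  t_len <- length(x)
  n <- length(kmers)
  check_feasible(t_len, n, signal$read_id)
  if (is.null(band)) band <- make_band(t_len, n, "full")
  check_band(band, t_len, n)
  em <- emissions %||% emission_matrix(x, kmers, model)
  la1 <- log(params$a1); le1 <- log(params$e1); le2 <- log(params$e2)

  A <- matrix(-Inf, n, t_len)
  E <- matrix(-Inf, n, t_len)
  if (band$lo[1] == 1) A[1, 1] <- em[1, 1]
  for (i in 2:t_len) {
    jr <- band$lo[i]:band$hi[i]
    jA <- jr[jr >= 2L]
    if (length(jA) > 0) {
      A[jA, i] <- E[jA - 1L, i - 1L] + la1 + em[jA, i]
    }
    E[jr, i] <- logaddexp(A[jr, i - 1L] + le1, E[jr, i - 1L] + le2) + em[jr, i]
  }
  structure(list(log_forward_A = A, log_forward_E = E,
                 log_Z = E[n, t_len], band = band, emissions = em,
                 kmers = kmers, read_id = signal$read_id),
            class = "squigseg_forward")
}

#' Backward pass of the align/extend HMM
#'
#' Fills the banded log-space backward matrices beta_A and beta_E: cell
#' (j, i) holds the log-probability of all legal path continuations from
#' that state to the terminal extend cell, excluding the emission at (j, i)
#' itself. The terminal condition is `beta_E[n_kmers-1, n_samples-1] = 0`;
#' the backward total `log_Z_star = beta_A[0,0] + em(0,0)` must agree with
#' the forward `log_Z`.
#'
#' @inheritParams forward_pass
#' @return A list of class `squigseg_backward`: `log_backward_A`,
#'   `log_backward_E`, `log_Z_star`, band.
#' @export
backward_pass <- function(signal, kmers, params, model, band = NULL,
                          emissions = NULL) {
  stopifnot(inherits(signal, "signal_read"))
  x <- signal$samples
  t_len <- length(x)
  n <- length(kmers)
  check_feasible(t_len, n, signal$read_id)
  if (is.null(band)) band <- make_band(t_len, n, "full")
  check_band(band, t_len, n)
  em <- emissions %||% emission_matrix(x, kmers, model)
  la1 <- log(params$a1); le1 <- log(params$e1); le2 <- log(params$e2)

  bA <- matrix(-Inf, n, t_len)
  bE <- matrix(-Inf, n, t_len)
  bE[n, t_len] <- 0
  for (i in (t_len - 1L):1L) {
    jr <- band$lo[i]:band$hi[i]
    ## A -> E (first extension): consumes t[i+1] on the same k-mer
    bA[jr, i] <- le1 + em[jr, i + 1L] + bE[jr, i + 1L]
    ## E -> A (new segment, next k-mer) or E -> E (continued extension)
    go_a <- rep(-Inf, length(jr))
    jn <- jr < n
    if (any(jn)) {
      go_a[jn] <- la1 + em[jr[jn] + 1L, i + 1L] + bA[jr[jn] + 1L, i + 1L]
    }
    go_e <- le2 + em[jr, i + 1L] + bE[jr, i + 1L]
    bE[jr, i] <- logaddexp(go_a, go_e)
  }
  structure(list(log_backward_A = bA, log_backward_E = bE,
                 log_Z_star = bA[1, 1] + em[1, 1], band = band,
                 kmers = kmers, read_id = signal$read_id),
            class = "squigseg_backward")
}

#' Full forward-backward alignment of one read
#'
#' Convenience wrapper running [forward_pass()] and [backward_pass()] on a
#' shared emission matrix and checking that the two terminal scores agree.
#'
#' @inheritParams forward_pass
#' @param tol maximum tolerated `|log_Z - log_Z_star|`.
#' @return An `alignment_result`: forward and backward matrices, `log_Z`,
#'   `log_Z_star`, band, emissions, kmers, read_id.
#' @export
align_read <- function(signal, kmers, params, model, band = NULL,
                       tol = 1e-6) {
  em <- emission_matrix(signal$samples, kmers, model)
  fwd <- forward_pass(signal, kmers, params, model, band, emissions = em)
  bwd <- backward_pass(signal, kmers, params, model, fwd$band, emissions = em)
  if (!is.finite(fwd$log_Z)) {
    squigseg_error("squigseg_band_error",
      sprintf("read %s: no legal path inside the band", signal$read_id))
  }
  drift <- abs(fwd$log_Z - bwd$log_Z_star)
  if (drift > tol * max(1, abs(fwd$log_Z))) {
    squigseg_error("squigseg_numeric_error",
      sprintf("read %s: forward/backward scores disagree by %.3g",
              signal$read_id, drift))
  }
  structure(list(log_forward_A = fwd$log_forward_A,
                 log_forward_E = fwd$log_forward_E,
                 log_backward_A = bwd$log_backward_A,
                 log_backward_E = bwd$log_backward_E,
                 log_Z = fwd$log_Z, log_Z_star = bwd$log_Z_star,
                 band = fwd$band, emissions = em,
                 kmers = kmers, read_id = signal$read_id),
            class = "alignment_result")
}

#' Posterior state probabilities
#'
#' Combines forward and backward matrices into per-cell posterior
#' probabilities `P(state at (j, i) | signal) = exp(alpha + beta - log_Z)`.
#' Each signal index is visited by exactly one state of the path, so the
#' posteriors over states and k-mers sum to one per signal column, and the
#' A-state posteriors sum to the number of k-mers overall.
#'
#' @param ali an `alignment_result` from [align_read()].
#' @param drift_tol posteriors may exceed 1 by at most this much before the
#'   computation is declared numerically inconsistent; smaller overshoots
#'   (<= 1e-9) are clipped to 1.
#' @return A `posterior_matrices` object: `post_A`, `post_E`, plus band,
#'   kmers, read_id, log_Z.
#' @export
posterior <- function(ali, drift_tol = 1e-6) {
  stopifnot(inherits(ali, "alignment_result"))
  pA <- exp(ali$log_forward_A + ali$log_backward_A - ali$log_Z)
  pE <- exp(ali$log_forward_E + ali$log_backward_E - ali$log_Z)
  over <- max(pA, pE) - 1
  if (is.finite(over) && over > drift_tol) {
    squigseg_error("squigseg_numeric_error",
      sprintf("posterior exceeds 1 by %.3g", over))
  }
  pA <- pmin(pA, 1)
  pE <- pmin(pE, 1)
  structure(list(post_A = pA, post_E = pE, band = ali$band,
                 kmers = ali$kmers, read_id = ali$read_id,
                 log_Z = ali$log_Z),
            class = "posterior_matrices")
}

#' MAP segmentation by posterior-Viterbi decoding
#'
#' Runs the Viterbi algorithm over the log posterior probabilities,
#' restricted to the legal moves of the HMM (A reachable from the diagonal
#' E cell of the previous k-mer; E from A or E of the same k-mer one sample
#' earlier), and extracts the maximum a posteriori path as contiguous
#' segments covering the whole signal. Ties prefer extension over opening a
#' new segment, favouring longer segments deterministically.
#'
#' @param post a `posterior_matrices` object.
#' @param params a [transition_params] (kept for interface symmetry; the
#'   decoder scores posteriors only).
#' @param model optional [kmer_model]; if supplied, segments carry k-mer
#'   strings.
#' @return A `segmentation` object: the read_id and a data.frame `segments`
#'   with columns `kmer_index` (0-based), `kmer`, `signal_start`,
#'   `signal_end` (0-based, half-open), `posterior` (mean posterior over the
#'   segment's path cells) and `border_prob` (total A-state posterior at the
#'   segment's first signal column).
#' @export
map_segmentation <- function(post, params = NULL, model = NULL) {
  stopifnot(inherits(post, "posterior_matrices"))
  lpA <- log(post$post_A)
  lpE <- log(post$post_E)
  n <- nrow(lpA)
  t_len <- ncol(lpA)

  vA <- matrix(-Inf, n, t_len)
  vE <- matrix(-Inf, n, t_len)
  from_A <- matrix(FALSE, n, t_len)   # predecessor of E[j,i]: A (TRUE) or E
  vA[1, 1] <- lpA[1, 1]
  for (i in 2:t_len) {
    jr <- post$band$lo[i]:post$band$hi[i]
    jA <- jr[jr >= 2L]
    if (length(jA) > 0) {
      vA[jA, i] <- vE[jA - 1L, i - 1L] + lpA[jA, i]
    }
    cand_A <- vA[jr, i - 1L]
    cand_E <- vE[jr, i - 1L]
    take_A <- cand_A > cand_E        # tie -> extend (E)
    from_A[jr, i] <- take_A
    vE[jr, i] <- pmax(cand_A, cand_E) + lpE[jr, i]
  }
  if (!is.finite(vE[n, t_len])) {
    squigseg_error("squigseg_band_error",
      sprintf("read %s: no legal path inside the band", post$read_id))
  }

  ## Traceback from the terminal E cell; record the A (segment-start) cells.
  starts <- integer(n)
  j <- n; i <- t_len; state <- "E"
  while (!(state == "A" && j == 1L && i == 1L)) {
    if (state == "E") {
      state <- if (from_A[j, i]) "A" else "E"
      i <- i - 1L
    } else {            # A[j,i]: segment j starts at i
      starts[j] <- i
      j <- j - 1L
      i <- i - 1L
      state <- "E"
    }
  }
  starts[1] <- 1L

  ends <- c(starts[-1] - 1L, t_len)            # 1-based inclusive
  border_prob <- colSums(post$post_A)[starts]
  seg_post <- vapply(seq_len(n), function(jj) {
    cells <- c(post$post_A[jj, starts[jj]],
               post$post_E[jj, (starts[jj] + 1L):ends[jj]])
    mean(cells)
  }, numeric(1))

  kmer_str <- names(post$kmers) %||% rep(NA_character_, n)
  if (!is.null(model)) kmer_str <- model$kmers[post$kmers]

  segs <- data.frame(
    kmer_index = seq_len(n) - 1L,
    kmer = kmer_str,
    signal_start = starts - 1L,               # 0-based half-open
    signal_end = ends,
    posterior = seg_post,
    border_prob = border_prob,
    stringsAsFactors = FALSE
  )
  structure(list(read_id = post$read_id, segments = segs),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation of read %s: %d segments over %d samples\n",
              x$read_id, nrow(x$segments), max(x$segments$signal_end)))
  print(utils::head(x$segments, 10), ...)
  if (nrow(x$segments) > 10) cat(sprintf("  ... %d more\n", nrow(x$segments) - 10))
  invisible(x)
}
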