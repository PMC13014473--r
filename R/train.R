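#' Baum-Welch training of transition and emission parameters
#'
#' Standard expectation-maximization for the align/extend topology:
#' the E-step accumulates expected transition uses (segment openings `a1`
#' vs. continued extensions `e2`) and posterior-weighted signal moments per
#' k-mer from the forward-backward matrices; the M-step renormalizes the
#' transition expectations and refits each k-mer's Gaussian from its
#' weighted moments. `e1` is structurally 1 (single edge out of A) and is
#' not trained. Total log Z is non-decreasing across iterations, up to
#' numerical slack.
#'
#' @name train
NULL

#' E-step sufficient statistics for one read
#'
#' Expected transition counts are summed transition posteriors:
#' `xi_a1(j, i) = exp(alpha_E[j,i] + ln a1 + em(j+1,i+1) + beta_A[j+1,i+1]
#' - log_Z)` for openings and the analogous expression with `e2` and
#' `beta_E` for extensions. Emission statistics are the posterior-weighted
#' sums, squared sums and total occupancy per model k-mer, where a cell's
#' weight is `post_A + post_E` (each signal column distributes exactly
#' weight 1 over k-mers).
#'
#' @param post `posterior_matrices` from [posterior()].
#' @param ali the matching `alignment_result` from [align_read()].
#' @param params the [transition_params] the matrices were computed under.
#' @param model the [kmer_model] (defines the statistics' index space).
#' @param signal the [signal_read] that was aligned.
#' @return A `bw_stats` list: `exp_a1`, `exp_e2` (expected transition uses),
#'   and per-model-k-mer vectors `occ`, `wsum`, `wsum2`; plus `log_Z` and
#'   `n_reads = 1`. Statistics are additive across reads via [add_stats()].
#' @export
expected_counts <- function(post, ali, params, model, signal) {
  stopifnot(inherits(post, "posterior_matrices"),
            inherits(ali, "alignment_result"))
  n <- nrow(post$post_A)
  t_len <- ncol(post$post_A)
  em <- ali$emissions
  la1 <- log(params$a1); le2 <- log(params$e2)
  aE <- ali$log_forward_E
  bA <- ali$log_backward_A
  bE <- ali$log_backward_E

  ## Transition posteriors, summed over all cells (vectorized over j blocks).
  i_from <- 1:(t_len - 1L)
  exp_a1 <- 0
  if (n >= 2) {
    x <- aE[1:(n - 1L), i_from, drop = FALSE] + la1 +
      em[2:n, i_from + 1L, drop = FALSE] + bA[2:n, i_from + 1L, drop = FALSE] -
      ali$log_Z
    exp_a1 <- sum(exp(x))
  }
  y <- aE[, i_from, drop = FALSE] + le2 +
    em[, i_from + 1L, drop = FALSE] + bE[, i_from + 1L, drop = FALSE] -
    ali$log_Z
  exp_e2 <- sum(exp(y))

  ## Emission statistics: per-cell weight = P(A) + P(E), mapped to model
  ## k-mer indices (several sequence positions may share a k-mer).
  w <- post$post_A + post$post_E              # n x t_len
  row_occ <- rowSums(w)
  row_wsum <- as.numeric(w %*% signal$samples)
  row_wsum2 <- as.numeric(w %*% (signal$samples^2))
  n_model <- length(model$kmers)
  occ <- wsum <- wsum2 <- numeric(n_model)
  for (j in seq_len(n)) {
    kj <- post$kmers[j]
    occ[kj] <- occ[kj] + row_occ[j]
    wsum[kj] <- wsum[kj] + row_wsum[j]
    wsum2[kj] <- wsum2[kj] + row_wsum2[j]
  }
  structure(list(exp_a1 = exp_a1, exp_e2 = exp_e2, occ = occ, wsum = wsum,
                 wsum2 = wsum2, log_Z = ali$log_Z, n_reads = 1L),
            class = "bw_stats")
}

#' @param a,b two `bw_stats` objects.
#' @rdname expected_counts
#' @export
add_stats <- function(a, b) {
  if (is.null(a)) return(b)
  structure(list(exp_a1 = a$exp_a1 + b$exp_a1, exp_e2 = a$exp_e2 + b$exp_e2,
                 occ = a$occ + b$occ, wsum = a$wsum + b$wsum,
                 wsum2 = a$wsum2 + b$wsum2, log_Z = a$log_Z + b$log_Z,
                 n_reads = a$n_reads + b$n_reads),
            class = "bw_stats")
}

#' M-step: re-estimate parameters from accumulated statistics
#'
#' `a1 = E[openings] / (E[openings] + E[extensions])`, `e2 = 1 - a1` (the
#' exact EM update for the tied transition pair, which makes the total log Z
#' non-decreasing). Per k-mer, `mu` is the posterior-weighted mean and
#' `sigma` the posterior-weighted standard deviation, floored at
#' `sigma_min`; k-mers with occupancy below `min_occ` keep their prior
#' parameters.
#'
#' @param stats accumulated `bw_stats`.
#' @param prior_model the current [kmer_model] (source of prior parameters).
#' @param sigma_min floor on fitted level_stdv, in model units.
#' @param min_occ minimum expected occupancy to re-estimate a k-mer.
#' @return A list: `params` ([transition_params]) and `model`
#'   ([kmer_model]).
#' @export
m_step <- function(stats, prior_model, sigma_min = 0.01, min_occ = 1e-8) {
  stopifnot(inherits(stats, "bw_stats"))
  denom <- stats$exp_a1 + stats$exp_e2
  a1 <- if (denom > 0) stats$exp_a1 / denom else NA_real_
  ## keep a1 strictly inside (0, 1): an all-minimal-dwell corpus drives the
  ## extension expectation to 0
  eps <- 1e-9
  a1 <- min(max(a1, eps), 1 - eps)
  params <- transition_params(a1 = a1)

  mu <- prior_model$level_mean
  sd <- prior_model$level_stdv
  est <- stats$occ >= min_occ
  mu[est] <- stats$wsum[est] / stats$occ[est]
  var <- stats$wsum2[est] / stats$occ[est] - mu[est]^2
  sd[est] <- pmax(sqrt(pmax(var, 0)), sigma_min)
  n_kept <- sum(!est)
  if (n_kept > 0) {
    message(sprintf("m_step: %d k-mer(s) with zero occupancy keep prior parameters",
                    n_kept))
  }
  ## prior model is already validated; swap parameters in place
  model <- prior_model
  model$level_mean <- mu
  model$level_stdv <- sd
  list(params = params, model = model)
}

#' Fit transition and emission parameters by Baum-Welch EM
#'
#' Iterates forward-backward E-steps over all reads and M-step updates until
#' the total log Z improves by less than `tol` or `max_iter` is reached.
#'
#' @param signals named list of [signal_read]s (already in model space, or
#'   raw with `normalization` set).
#' @param reads named list of [basecalled_read]s.
#' @param init_model starting [kmer_model].
#' @param init_params starting [transition_params]; the default `a1 = 0.1`
#'   corresponds to a mean dwell of 11 samples, matching typical
#'   samples-per-base at nanopore translocation speeds.
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the change in total log Z.
#' @param orientation passed to [sequence_to_kmers()].
#' @param band_width band half-width for the forward-backward passes.
#' @param normalization `"none"` if signals are already in model space.
#' @param train_emissions logical: refit the k-mer Gaussians as well as the
#'   transitions.
#' @param verbose print the log Z trajectory.
#' @return A `train_state`: final `params` and `model`, `iterations`,
#'   `log_Z_trajectory` (one total per completed E-step) and `converged`.
#' @export
fit_baum_welch <- function(signals, reads, init_model,
                           init_params = transition_params(a1 = 0.1),
                           max_iter = 20, tol = 1e-3,
                           orientation = "dna_5to3", band_width = "full",
                           normalization = c("none", "median_mad"),
                           train_emissions = TRUE, verbose = FALSE) {
  normalization <- match.arg(normalization)
  ids <- intersect(names(signals), names(reads))
  if (length(ids) == 0) {
    squigseg_error("squigseg_pairing_error", "no paired reads to train on")
  }
  params <- init_params
  model <- init_model
  traj <- numeric(0)
  converged <- FALSE

  prepped <- lapply(ids, function(id) {
    sig <- signals[[id]]
    if (!sig$normalized && normalization == "median_mad") {
      sig <- normalize_signal(sig, "median_mad", model)
    }
    sig
  })
  names(prepped) <- ids

  e_step <- function() {
    stats <- NULL
    for (id in ids) {
      sig <- prepped[[id]]
      kmers <- sequence_to_kmers(reads[[id]], model, orientation)
      band <- make_band(length(sig$samples), length(kmers), band_width)
      ali <- align_read(sig, kmers, params, model, band)
      post <- posterior(ali)
      stats <- add_stats(stats, expected_counts(post, ali, params, model, sig))
    }
    stats
  }

  n_updates <- 0L
  ## One EM iteration = one E-step + one M-step; an extra closing E-step
  ## evaluates the improvement of the last update.
  for (pass in seq_len(max_iter + 1L)) {
    stats <- e_step()
    traj <- c(traj, stats$log_Z)
    if (verbose) {
      message(sprintf("pass %d: total log Z = %.4f, a1 = %.4f",
                      pass, stats$log_Z, params$a1))
    }
    if (pass >= 2 && (traj[pass] - traj[pass - 1]) < tol) {
      converged <- TRUE
      break
    }
    if (pass > max_iter) break
    upd <- m_step(stats, model)
    params <- upd$params
    if (train_emissions) model <- upd$model
    n_updates <- n_updates + 1L
  }
  structure(list(params = params, model = model, iterations = n_updates,
                 log_Z_trajectory = traj, converged = converged),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("Baum-Welch fit: %d iteration(s), %sconverged\n",
              x$iterations, if (x$converged) "" else "NOT "))
  cat(sprintf("  a1 = %.4f (mean dwell %.1f samples)\n",
              x$params$a1, 1 + 1 / x$params$a1))
  cat(sprintf("  total log Z: %s\n",
              paste(sprintf("%.2f", x$log_Z_trajectory), collapse = " -> ")))
  invisible(x)
}
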