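test_that("emission_logpdf matches the Gaussian log-density closed forms", {
  model <- tiny_model()
  # at the mode with unit sigma: -0.5 * ln(2*pi)
  expect_equal(emission_logpdf(0, 1, model), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # one sigma from the mode: mode value - 0.5
  expect_equal(emission_logpdf(1, 1, model),
               -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)
  # t = 0, mu = 2, sigma = 2, substituted by hand
  m2 <- quiet_model(c("A", "C", "G", "T"), c(2, 10, 20, 30), c(2, 1, 1, 1))
  expect_equal(emission_logpdf(0, 1, m2), -0.5 - log(2 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_error(emission_logpdf(NaN, 1, model),
               class = "squigseg_validation_error")
})

test_that("forward pass reproduces the single-path closed form", {
  model <- tiny_model()
  sig <- signal_read("r", c(0, 0), normalized = TRUE)
  kmers <- sequence_to_kmers("A", model)
  fwd <- forward_pass(sig, kmers, transition_params(a1 = 0.5), model)
  # unique path A,E with e1 = 1: two emissions at the mode
  expect_equal(fwd$log_Z, -log(2 * pi), tolerance = 1e-9)
})

test_that("infeasible signal/sequence shapes are rejected before the DP", {
  model <- tiny_model()
  sig <- signal_read("r", c(0, 0, 0), normalized = TRUE)
  kmers <- sequence_to_kmers("AC", model)
  expect_error(forward_pass(sig, kmers, transition_params(), model),
               class = "squigseg_infeasible_read")
  expect_error(backward_pass(sig, kmers, transition_params(), model),
               class = "squigseg_infeasible_read")
})

test_that("DP log Z matches exhaustive path enumeration on small instances", {
  model <- tiny_model()
  params <- transition_params(a1 = 0.5)
  set.seed(101)
  for (n in 1:3) {
    for (t_len in (2 * n):8) {
      inst <- random_instance(n, t_len, model)
      orc <- oracle_enumerate(inst$signal$samples, inst$kmers, model, 0.5)
      ali <- align_read(inst$signal, inst$kmers, params, model)
      expect_equal(ali$log_Z, orc$log_Z, tolerance = 1e-9,
                   label = sprintf("log_Z (n=%d, T=%d)", n, t_len))
      # posterior matrices agree with path-weighted enumeration
      po <- posterior(ali)
      expect_equal(po$post_A, orc$post_A, tolerance = 1e-9)
      expect_equal(po$post_E, orc$post_E, tolerance = 1e-9)
      # MAP path equals the enumeration argmax over posterior path scores
      seg <- map_segmentation(po, params, model)
      dwell_dp <- seg$segments$signal_end - seg$segments$signal_start
      expect_identical(as.integer(dwell_dp),
                       as.integer(oracle_map_dwells(orc)),
                       label = sprintf("MAP dwells (n=%d, T=%d)", n, t_len))
    }
  }
})

test_that("the hand-built two-k-mer instance behaves exactly as derived", {
  model <- tiny_model()
  params <- transition_params(a1 = 0.5)
  sig <- signal_read("r", c(0, 0, 10, 10), normalized = TRUE)
  kmers <- sequence_to_kmers("AC", model)
  ali <- align_read(sig, kmers, params, model)
  # only legal dwell composition of 4 into 2 segments is (2, 2):
  # 4 emissions at the mode plus one a1 transition
  expect_equal(ali$log_Z, 4 * dnorm(0, log = TRUE) + log(0.5),
               tolerance = 1e-12)
  po <- posterior(ali)
  # single path: on-path posteriors 1, off-path 0
  expect_equal(po$post_A[1, 1], 1, tolerance = 1e-9)
  expect_equal(po$post_A[2, 3], 1, tolerance = 1e-9)
  expect_equal(sum(po$post_A) + sum(po$post_E), 4, tolerance = 1e-9)
  seg <- map_segmentation(po, params, model)
  expect_identical(seg$segments$signal_start, c(0L, 2L))
  expect_identical(seg$segments$signal_end, c(2L, 4L))
})

test_that("forward-backward consistency and posterior normalization hold", {
  model <- tiny_model()
  params <- transition_params(a1 = 0.2)
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    t_len <- sample((2 * n):(2 * n + 15), 1)
    inst <- random_instance(n, t_len, model)
    ali <- align_read(inst$signal, inst$kmers, params, model)
    expect_lt(abs(ali$log_Z - ali$log_Z_star), 1e-6)
    po <- posterior(ali)
    expect_equal(unname(colSums(po$post_A + po$post_E)), rep(1, t_len),
                 tolerance = 1e-6)
    # every path visits A exactly once per k-mer
    expect_equal(sum(po$post_A), n, tolerance = 1e-6)
    expect_true(all(po$post_A >= 0 & po$post_A <= 1 + 1e-9))
    expect_true(all(po$post_E >= 0 & po$post_E <= 1 + 1e-9))
  }
})

test_that("MAP segmentations are contiguous with minimum segment length 2", {
  model <- tiny_model()
  params <- transition_params(a1 = 0.3)
  set.seed(303)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    t_len <- sample((2 * n):(2 * n + 12), 1)
    inst <- random_instance(n, t_len, model)
    seg <- map_segmentation(
      posterior(align_read(inst$signal, inst$kmers, params, model)),
      params, model)
    d <- seg$segments
    expect_identical(nrow(d), n)
    expect_true(all(d$signal_end - d$signal_start >= 2))
    expect_identical(d$signal_start[1], 0L)
    expect_identical(d$signal_end[n], t_len)
    if (n > 1) expect_identical(d$signal_start[-1], d$signal_end[-n])
  }
})

test_that("a single k-mer is forced into one whole-signal segment", {
  model <- tiny_model()
  params <- transition_params()
  sig <- signal_read("r", rep(0, 5), normalized = TRUE)
  seg <- map_segmentation(
    posterior(align_read(sig, sequence_to_kmers("A", model), params, model)),
    params, model)
  expect_identical(seg$segments$signal_start, 0L)
  expect_identical(seg$segments$signal_end, 5L)
})

test_that("make_band follows the rounded diagonal and clamps correctly", {
  # full band: every cell allowed
  b <- make_band(10, 5, "full")
  expect_true(all(b$lo == 1) && all(b$hi == 5))
  # w = 0: 0-based centers hand-rounded for T=10, n=5
  b0 <- make_band(10, 5, 0)
  hand <- c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4)
  expect_identical(b0$lo, as.integer(hand + 1))
  expect_identical(b0$hi, as.integer(hand + 1))
  # w >= n_kmers collapses to the full band
  b_wide <- make_band(10, 5, 7)
  expect_identical(b_wide$lo, b$lo)
  expect_identical(b_wide$hi, b$hi)
})

test_that("cells outside the band stay -Inf and log Z is monotone in width", {
  model <- tiny_model()
  params <- transition_params(a1 = 0.3)
  set.seed(404)
  inst <- random_instance(4, 20, model)
  zs <- numeric(0)
  for (w in 0:4) {
    band <- make_band(20, 4, w)
    fwd <- forward_pass(inst$signal, inst$kmers, params, model, band)
    outside <- which(outer(seq_len(4), seq_len(20),
                           function(j, i) j < band$lo[i] | j > band$hi[i]))
    expect_true(all(fwd$log_forward_A[outside] == -Inf))
    expect_true(all(fwd$log_forward_E[outside] == -Inf))
    zs <- c(zs, fwd$log_Z)
  }
  expect_true(all(diff(zs) >= -1e-12))
  # full band reproduces the unbanded result bit-for-bit
  f_full <- forward_pass(inst$signal, inst$kmers, params, model,
                         make_band(20, 4, "full"))
  f_wide <- forward_pass(inst$signal, inst$kmers, params, model,
                         make_band(20, 4, 100))
  expect_identical(f_full$log_forward_E, f_wide$log_forward_E)
  expect_identical(f_full$log_Z, f_wide$log_Z)
})

test_that("a band excluding origin or terminal is rejected", {
  model <- tiny_model()
  sig <- signal_read("r", rep(0, 8), normalized = TRUE)
  kmers <- sequence_to_kmers("AC", model)
  band <- make_band(8, 2, "full")
  band$lo[1] <- 2L   # origin excluded
  expect_error(forward_pass(sig, kmers, transition_params(), model, band),
               class = "squigseg_band_error")
})

test_that("transition parameters enforce a1 + e2 = 1", {
  expect_error(transition_params(a1 = 0.3, e2 = 0.6),
               class = "squigseg_validation_error")
  expect_error(transition_params(a1 = 0), class = "squigseg_validation_error")
  p <- transition_params(a1 = 0.25)
  expect_equal(p$e2, 0.75)
  expect_equal(p$e1, 1)
})
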