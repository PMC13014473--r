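# Shared fixtures: tiny models and instances used across test files.

# Complete k = 1 model over ACGT with well-separated levels; the workhorse
# for hand-checkable DP instances.
tiny_model <- function(means = c(0, 10, 20, 30), sds = rep(1, 4)) {
  suppressMessages(kmer_model(c("A", "C", "G", "T"), means, sds))
}

quiet_model <- function(...) suppressMessages(kmer_model(...))

quiet_synth <- function(...) suppressMessages(synthetic_kmer_model(...))

# Random feasible instance on the k = 1 model: n k-mers, signal length T.
random_instance <- function(n_kmers, t_len, model = tiny_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), n_kmers, replace = TRUE),
               collapse = "")
  kmers <- sequence_to_kmers(seq, model)
  samples <- model$level_mean[rep(kmers, length.out = t_len)] +
    rnorm(t_len, sd = 2)
  list(signal = signal_read("rand", samples, normalized = TRUE),
       kmers = kmers, model = model, sequence = seq)
}
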