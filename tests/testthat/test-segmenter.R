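seg_model <- function() quiet_synth(5, level_stdv = 0.01)

seg_config <- function(model = seg_model(), ...) {
  run_config(model, normalization = "none", band_width = "full",
             params = transition_params(a1 = 0.2), ...)
}

test_that("zero-noise simulated reads are recovered exactly end to end", {
  model <- seg_model()
  cfg <- sim_config(model, noise_scale = 0, fixed_dwell = 4,
                    n_reads = 5, len_min = 15, len_max = 25, seed = 21)
  ds <- simulate_dataset(cfg)
  rc <- seg_config(model)
  for (id in names(ds$signals)) {
    seg <- segment_read(ds$signals[[id]], ds$reads[[id]], rc)
    expect_s3_class(seg, "segmentation")
    expect_identical(seg$segments$signal_start,
                     ds$truths[[id]]$segments$signal_start)
    expect_identical(seg$segments$signal_end,
                     ds$truths[[id]]$segments$signal_end)
  }
})

test_that("a read of exactly k bases becomes one whole-signal segment", {
  rc <- seg_config()
  sig <- signal_read("r1", rep(60, 7), normalized = TRUE)
  seg <- segment_read(sig, basecalled_read("r1", "AAAAA"), rc)
  expect_identical(nrow(seg$segments), 1L)
  expect_identical(seg$segments$signal_start, 0L)
  expect_identical(seg$segments$signal_end, 7L)
})

test_that("too-short signals yield a structured infeasibility record", {
  rc <- seg_config()
  # 6-nt read against k = 5 gives 2 k-mers, needing >= 4 samples
  sig <- signal_read("r1", c(60, 60, 60), normalized = TRUE)
  res <- segment_read(sig, basecalled_read("r1", "ACGTAC"), rc)
  expect_s3_class(res, "infeasible_read")
  expect_identical(res$reason, "signal_too_short")
  # sequence shorter than k is its own reason code
  res2 <- segment_read(signal_read("r1", c(60, 60), normalized = TRUE),
                       basecalled_read("r1", "ACG"), rc)
  expect_s3_class(res2, "infeasible_read")
  expect_identical(res2$reason, "sequence_shorter_than_k")
})

test_that("mismatched read_ids raise a pairing error", {
  rc <- seg_config()
  expect_error(
    segment_read(signal_read("a", c(1, 2), normalized = TRUE),
                 basecalled_read("b", "ACGTA"), rc),
    class = "squigseg_pairing_error"
  )
})

test_that("segmentation tables round-trip through TSV", {
  model <- seg_model()
  cfg <- sim_config(model, noise_scale = 0, fixed_dwell = 3,
                    n_reads = 2, len_min = 10, len_max = 14, seed = 5)
  ds <- simulate_dataset(cfg)
  rc <- seg_config(model)
  segs <- lapply(names(ds$signals), function(id)
    segment_read(ds$signals[[id]], ds$reads[[id]], rc))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segmentation(segs, path, rc)
  tab <- read_segmentation(path)
  expect_named(tab, c("read_id", "signal_start", "signal_end",
                      "base_position", "kmer", "posterior", "border_prob"))
  expect_identical(nrow(tab), sum(vapply(segs, function(s)
    nrow(s$segments), integer(1))))
  # starts strictly increasing within each read
  for (id in unique(tab$read_id)) {
    expect_true(all(diff(tab$signal_start[tab$read_id == id]) > 0))
  }
  # round-trip preserves coordinates and 6-decimal floats
  s1 <- segs[[1]]$segments
  t1 <- tab[tab$read_id == segs[[1]]$read_id, ]
  expect_identical(t1$signal_start, s1$signal_start)
  expect_identical(t1$signal_end, s1$signal_end)
  expect_identical(t1$kmer, s1$kmer)
  expect_equal(t1$posterior, round(s1$posterior, 6), tolerance = 1e-9)
  # base_position is the central base of the k-mer (k = 5 -> offset 2)
  expect_identical(t1$base_position, s1$kmer_index + 2L)
})

test_that("an empty segmentation list writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segmentation(list(), path)
  tab <- read_segmentation(path)
  expect_identical(nrow(tab), 0L)
  expect_named(tab, c("read_id", "signal_start", "signal_end",
                      "base_position", "kmer", "posterior", "border_prob"))
})

test_that("run_dataset conserves read counts and reports unpaired reads", {
  model <- seg_model()
  cfg <- sim_config(model, noise_scale = 0, fixed_dwell = 3,
                    n_reads = 6, len_min = 10, len_max = 16, seed = 9)
  ds <- simulate_dataset(cfg)
  # sabotage one read: truncate its signal below feasibility
  short_id <- names(ds$signals)[3]
  ds$signals[[short_id]] <- signal_read(short_id, c(60, 61), normalized = TRUE)
  # add one unpaired signal
  ds$signals[["orphan"]] <- signal_read("orphan", rnorm(20, 60),
                                        normalized = TRUE)
  rc <- seg_config(model)
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- run_dataset(ds$signals, ds$reads, rc, out = out)
  expect_identical(res$n_input_pairs, 6L)
  expect_identical(res$segmented + res$infeasible + res$failed, 6L)
  expect_identical(res$infeasible, 1L)
  expect_identical(res$unpaired_signals, 1L)
  expect_identical(res$infeasible_records[[short_id]]$reason,
                   "signal_too_short")
  # rerun is byte-identical (no RNG in the decode path)
  out2 <- withr::local_tempfile(fileext = ".tsv")
  run_dataset(ds$signals, ds$reads, rc, out = out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("basecalls load from FASTQ and from SAM/BAM", {
  model <- seg_model()
  cfg <- sim_config(model, n_reads = 3, len_min = 10, len_max = 12, seed = 13)
  prefix <- withr::local_tempfile()
  ds <- simulate_dataset(cfg, out_prefix = prefix)
  reads <- read_basecalls(ds$files[["reads"]])
  expect_length(reads, 3)
  expect_identical(reads[[1]]$sequence, ds$reads[[1]]$sequence)

  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    vapply(ds$reads, function(r)
      sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", r$read_id, r$sequence),
      character(1))
  ), sam)
  reads_sam <- read_basecalls(sam)
  expect_length(reads_sam, 3)
  expect_identical(reads_sam[[ds$reads[[2]]$read_id]]$sequence,
                   ds$reads[[2]]$sequence)
})

test_that("RNA orientation flips both k-mer order and base positions", {
  model <- tiny_model()
  rc <- run_config(model, orientation = "rna_3to5", normalization = "none",
                   band_width = "full", params = transition_params(0.3))
  # sequence ACGT read 3'->5': signal time order is T,G,C,A
  sig <- signal_read("r", c(30, 30, 20, 20, 10, 10, 0, 0), normalized = TRUE)
  seg <- segment_read(sig, basecalled_read("r", "ACGT"), rc)
  expect_identical(seg$segments$kmer, c("T", "G", "C", "A"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segmentation(seg, path, rc)
  tab <- read_segmentation(path)
  # first segment (time order) is the 3' end: last base of the read
  expect_identical(tab$base_position, c(3L, 2L, 1L, 0L))
})
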