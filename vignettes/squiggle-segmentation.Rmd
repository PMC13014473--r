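---
title: "Segmenting nanopore squiggles with a two-state forward-backward HMM"
author: "squigseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting nanopore squiggles with a two-state forward-backward HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigseg)
```

## The problem

A nanopore sequencer reports a time series of ionic current measurements
(the "squiggle") as a DNA or RNA molecule translocates the pore. Basecallers
turn that series into a nucleotide sequence, but many downstream analyses --
modification detection, error diagnosis, signal visualization -- need the
inverse map: which contiguous stretch of current samples was produced while
each k-mer of the read occupied the pore. Producing that map is
*segmentation* (also called resquiggling). Most existing tools presegment
the signal with a sliding-window event detector and then align events with
a forward-only pass; squigseg instead aligns every raw sample directly with
a full forward-backward HMM, which yields posterior confidence for every
segment and avoids committing early to event boundaries.

## The model

Let $T = (t_0, \dots, t_{\mathcal{T}-1})$ be the signal and
$N = (n_0, \dots, n_{\mathcal{N}-1})$ the basecalled read, windowed into
$\mathcal{N} - k + 1$ overlapping k-mers. The pore model supplies, for each
k-mer, a Gaussian $\phi(t;\mu_k,\sigma_k)$ for the current it produces;
these are the emission distributions of both HMM states.

The HMM has two states. **A** ("align") consumes one signal sample and
advances one k-mer, opening a new segment; **E** ("extend") consumes one
signal sample while halting on the current k-mer. A is reachable only from
E, with probability $a_1$; E is reachable from A (first extension,
probability $e_1 = 1$, since A has a single outgoing edge) and from itself
(continued extension, probability $e_2 = 1 - a_1$). Every segment therefore
consists of one A sample followed by at least one E sample: **the topology
itself enforces a minimum segment length of two signal samples**, and dwell
times are geometric with mean $1 + 1/a_1$ samples.

In log space the recursions are

$$A[j,i] = E[j{-}1,i{-}1] + \ln a_1 + \ln\phi(t_i),\qquad
E[j,i] = \mathrm{LSE}\!\big(A[j,i{-}1] + \ln e_1,\; E[j,i{-}1] + \ln e_2\big) + \ln\phi(t_i),$$

with origin $A[0,0] = \ln\phi(t_0)$ and total score
$\log Z = E[\mathcal{N}-k,\ \mathcal{T}-1]$. The backward pass mirrors this
from the terminal cell; its origin total $\log Z^\ast$ must agree with
$\log Z$, which `align_read()` checks to $10^{-6}$. Cell posteriors are
$P = \exp(\alpha + \beta - \log Z)$; each signal column's posteriors sum to
1 and the A posteriors sum to the number of k-mers (both are tested
properties). The MAP segmentation is extracted by running Viterbi over the
*log posteriors* restricted to the legal move set ("posterior-Viterbi"),
with ties broken toward extension so output is deterministic and favors
longer segments. The per-segment `border_prob` column is the total A-state
posterior at the segment's first signal column -- the model's confidence
that *some* segment starts there.

### Why posterior-Viterbi, and other open choices

Three places in the procedure were genuinely open and are fixed here as
package design choices:

* **Decoding target.** The MAP path is the argmax over legal paths of the
  summed log cell posteriors, not of raw likelihood-times-transition
  weights. Tests verify the decoder against an exhaustive enumeration
  oracle that scores paths the same way.
* **Border probability.** No closed form is prescribed for a per-border
  confidence trace; we define it as the column sum of A posteriors at the
  border's signal index.
* **Band geometry.** Banding follows a fixed rectangular corridor of
  half-width $w$ (default 100 k-mer positions) around the rounded diagonal
  through the $(i, j)$ rectangle, clamped to the valid range; the origin and
  terminal cells lie on the diagonal, so they are always inside. The full
  band reproduces unbanded results bit-for-bit and $\log Z$ is
  non-decreasing in $w$ (tested). Adaptive band shapes are out of scope.

### Feasibility

A read with $\mathcal{T} < 2(\mathcal{N} - k + 1)$ cannot host
minimum-length segments for all its k-mers. The gate runs before the DP and
such reads are returned as structured infeasibility records (reason
`signal_too_short`), never dropped silently: the package's philosophy is to
attempt every read, including the very short ones that event-detection
tools filter, and let the user decide using the posterior confidence.

## Normalization

Raw current is shifted and scaled per read: `median_mad` standardizes by
the signal median and raw median absolute deviation (no 1.4826 consistency
factor -- the same raw MAD convention used by the metrics), then rescales
affinely so the signal median lands on the model's global level mean with
the model's level spread. This is a pragmatic default in the tradition of
median/MAD resquiggling, not a claim about any particular tool's internal
normalization; signals simulated in model space use `none`. The MAD factor
choice is documented and held consistent everywhere.

## Training

`fit_baum_welch()` is standard EM for this topology. The E-step accumulates
expected transition uses ($a_1$ openings versus $e_2$ extensions, as summed
transition posteriors) and posterior-weighted signal moments per k-mer; the
M-step sets $a_1 = E[\text{openings}]/(E[\text{openings}] +
E[\text{extensions}])$ -- the exact EM update for the tied pair, which keeps
the total $\log Z$ monotone (tested) -- and refits each k-mer's Gaussian
from its weighted moments. Numerical safeguards: $\sigma$ floored at 0.01
model units, $a_1$ clamped inside $(0,1)$, k-mers with negligible expected
occupancy keep their prior parameters (logged). $e_1$ is structurally 1 and
not trained. The default initialization $a_1 = 0.1$ corresponds to a mean
dwell of 11 samples, a typical samples-per-base at nanopore translocation
speeds (~400 b/s at 4-5 kHz for DNA, slower for direct RNA).

## The simulator: what a green test does and does not establish

`simulate_read()` shares the model's generative story: dwell $= 2 +
\mathrm{Geometric}(a_1)$ samples per k-mer (support $\ge 2$, mean $1 +
1/a_1$) and samples drawn $\mathcal{N}(\mu_k,\ \text{noise\_scale}\cdot
\sigma_k)$, with ground-truth segments recorded in the same 0-based
half-open convention. Because simulation and inference share the story,
parameter-recovery tests are well-posed: with 200 simulated reads at $a_1 =
0.2$ and unit noise, training recovers $a_1$ within $\pm 0.05$ and level
means shifted by $+2$ within $\pm 0.2$ model units; with zero noise and
distinct level means, segmentation recovers true boundaries exactly.

The simulator deliberately omits low-pass filtering, baseline drift, stall
artifacts, adapter/poly-A signal and modification-shifted levels. A green
recovery test therefore establishes the *inference machinery* is correct
under the model's own assumptions -- not that real pore data satisfies those
assumptions.

Defaults were chosen once as a realistic desk-scale world: sequence lengths
30-60 nt (small-RNA-like, keeps exhaustive checks tractable), $a_1 = 0.1$
dwell geometry as above, unit noise scale. The zero-noise recovery fixture
uses a synthetic k = 5 model with evenly spaced, well-separated level means
(`synthetic_kmer_model(5, level_stdv = 0.01)`) so that boundary recovery is
determined by emissions rather than tie-breaking.

## Metrics and scores

For benchmarking segmentations (from this package or external tools, read
from the same TSV layout):

* **Border contrast** (`border_deltas`): at each internal border, the
  absolute difference between the medians (or raw MADs) of the 6 samples on
  either side; higher is better. Borders without a full 6-sample window on
  either side are skipped, not padded -- padding would fabricate signal.
  Window width 6 matches the smallest segment emitted by common basecaller
  move tables.
* **Homogeneity** (`homogeneity`): the standard deviation of the inner 80%
  of each segment spanning at least 10 samples
  ($\lceil 0.1\,\ell\rceil$ dropped from each end); lower is better.
* **Read statistics** (`read_stats`): segmented and truncated read counts
  and min/N50/max segmented base span. Truncation is strict -- any
  uncovered basecalled nucleotide counts -- since no tolerance is
  prescribed; the criterion is documented and lives in one place.

Per metric and dataset, raw values across tools are normalized linearly
against the maximum: higher-better $x/\max$, lower-better $1 - x/\max$
(so a raw 0 maps to 1.0 and the maximum to 0.0); all-zero raws default to
the direction's best value, logged. The **AM score** is each tool's column
sum of *unrounded* scores; rounding (half away from zero, 2 decimals)
happens only at presentation. The shipped example table
(`example_benchmark()`) exercises exactly this arithmetic; note its
downstream-tool rows print rounded raw values, so only the segmentation and
read-statistic rows reproduce their printed scores from the printed raws.

## Numerical choices

* All DP in natural-log space with an `-Inf`-safe log-sum-exp; cells
  outside the band are $-\infty$.
* Posterior overshoot above 1 up to $10^{-9}$ is clipped; beyond
  $10^{-6}$ it is an error, not a warning.
* Coordinates are 0-based half-open `[start, end)` sample intervals in all
  tables; internal R matrices are 1-based and converted at the boundary.
* The `base_position` column reports the k-mer's central base (left of
  center for even k), mapped back to the original read's coordinates for
  3'-to-5' RNA.
* Orientation is an explicit flag (`dna_5to3` / `rna_3to5`), never
  autodetected.

## Known limitations

Pure-R DP: throughput is roughly hundreds of thousands of DP cells per
second, ample for desk-scale studies and testing but not for whole
flowcells. pod5 input is not parsed directly; convert to the portable
signal TSV (`read_id`, comma-joined samples). The resquiggle/error-correction
mode and adaptive banding of full-scale tools are out of scope, as are
basecalling and running external segmentation tools -- although their
tabular outputs can be scored by the generic metric normalizer.
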