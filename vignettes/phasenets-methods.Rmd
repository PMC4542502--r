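---
title: "Methods: time-resolved network topology from multichannel phase synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved network topology from multichannel phase synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phasenets` follows the topology of functional brain networks through days of
multichannel electrophysiological recording. This vignette is the package's
own account of the method: the estimators, the conventions chosen where a
convention had to be chosen, what the synthetic generator does and does not
emulate, and the numerical decisions a maintainer would want written down.

## From signals to networks

**Filtering.** Each channel is bandpass filtered (default 1–45 Hz) with a
4th-order Butterworth applied forward and backward. Zero net phase response
is not a nicety here: any phase distortion would bias every downstream
phase-synchrony estimate. The filter is realised as cascaded second-order
sections with the gain distributed evenly across sections; a transfer-function
realisation of the full 8th-order bandpass is numerically fragile when the
low edge sits at 1/100 of the sampling rate. Forward–backward passes use
odd-reflection padding (up to 512 samples) and steady-state initial
conditions per section. A sharp 1 Hz low edge still leaves an intrinsic edge
transient — the reference `scipy.signal.sosfiltfilt` behaves identically —
which is why amplitude checks in the tests discard one second at each edge.
Each contiguous segment of a record is filtered independently, so no filter
state leaks across recording gaps.

**Windowing.** Records are cut into consecutive, non-overlapping windows of
`n_samples = 4096` points (20.48 s at 200 Hz). Windows never span a gap: the
grid restarts at each post-gap segment, and trailing remainders shorter than
one window are discarded. All epoch logic is keyed to the absolute wall-clock
start time of each window.

**Instantaneous phase.** Per window and channel, the phase is the argument of
the analytic signal $x + i\,H[x]$, with the Hilbert transform evaluated by
FFT over the window, no tapering. The channel mean is removed first — a DC
offset moves the analytic signal off the origin and corrupts the phase; the
windowed estimation accepts edge effects, which the temporal average of the
coherence estimator damps. A constant (all-zero) channel has no defined
phase: it is marked `NA` with a warning and excluded downstream.

**Mean phase coherence.** Pairwise synchrony is
$$R_{nm} = \Bigl|\, N^{-1} \sum_{j=0}^{N-1}
  e^{\,i(\Phi_n(j) - \Phi_m(j))} \Bigr| \in [0, 1],$$
the modulus of the time-averaged unit phasor of the phase difference: 1 for
phase-locked pairs (any constant offset), near 0 for uniformly scattered
differences. The per-window matrix is computed for all unordered pairs; the
diagonal is 0 by convention.

**Thresholding to fixed link density.** Each synchrony matrix becomes a
binary undirected network with predefined link density
$\rho = \bar{k}/(N_{rs} - 1)$ (default 0.1): the
$L = \mathrm{round}(\rho M_{rs})$ largest lower-triangular entries become
links, $M_{rs} = (N_{rs}^2 - N_{rs})/2$. Three conventions were fixed here:

* $L$ uses half-up rounding — "the $(\rho M_{rs} - 1)$-largest entry"
  presumes $\rho M_{rs}$ is an integer; rounding gives the closest
  achievable density when it is not.
* Rank selection guarantees an exact link count even with ties at the
  threshold $\Theta$ (reported as the smallest retained entry); exact density
  was preferred over a literal "exceeds $\Theta$" rule because fixed density
  is the stated goal of the construction.
* Ties at $\Theta$ break deterministically by ascending (row, column) index;
  random tie-breaking would violate the package's determinism contract.

Rank selection also makes the construction invariant under monotone
transforms of the synchrony values.

## Network measures

**Assortativity.** Degree–degree correlation in the degree-sum form
$$a = \frac{2 F_1 \sum_{n>m} A_{nm} k_n k_m - F_2^2}{F_1 F_3 - F_2^2},
\qquad F_u = \sum_n k_n^u,$$
equal to the Pearson correlation between the degrees at the two ends of
links ($a > 0$ assortative, $a < 0$ dissortative). For regular graphs
(including the empty graph) the denominator vanishes and $a$ is undefined;
the package returns `NA` and excludes such windows from time averages,
medians and histograms rather than imputing a value. The original analysis
never discusses this case; an explicit undefined flag is the only choice
that cannot silently bias a median.

**Clustering.** The local coefficient
$C_n = [k_n(k_n-1)]^{-1} \sum_{m,l} A_{nl} A_{nm} A_{ml}$ for $k_n > 1$ and
$C_n = 0$ for $k_n \in \{0, 1\}$; the network coefficient $C$ is the mean
over all nodes, zeros included.

**Erdős–Rényi baseline.** Finite networks show nonzero assortativity even
when degree–degree uncorrelated by construction. The baseline ensemble
(default 20 realizations) uses the fixed-link-count model $G(N, L)$ with
exactly $L = \mathrm{round}(\rho M_{rs})$ links placed uniformly — not
$G(N, p)$ — because the functional networks have exactly $L$ links by
construction and the point of the baseline is "the same number of nodes and
the same link density". Whether the original used $G(N,p)$ or $G(N,L)$ is
unstated; at these sizes the difference is far below the ensemble spread.
The ensemble standard deviation uses the sample ($n-1$) denominator. The
baseline is computed once per recording (fixed $N_{rs}$, $\rho$), not per
window. A value is flagged *genuine* when it deviates from the ensemble mean
by strictly more than one ensemble standard deviation; the strict inequality
carries a $10^{-9}$ relative guard so the boundary convention is stable
under floating-point rounding.

## Temporal analysis

**Smoothing is display-only.** The centered moving average (default 30
windows = 10.24 min) never bridges a gap: averaging restarts at each
contiguous run, and run edges average over the available points. Every
statistic — medians, correlations, periodograms — is computed on unsmoothed
values.

**Periodicity.** The normalized Lomb–Scargle periodogram (classical
$\tau$-shifted form, equivalent to per-frequency least-squares sinusoid
fitting) is evaluated on the demeaned, unsmoothed metric series at the
window start times in hours. Uneven sampling from recording gaps needs no
special handling — that is the point of the estimator. The grid runs from
one cycle per record span to the pseudo-Nyquist of the window cadence
(0.5 / median spacing), oversampled 4-fold; only the algorithm, not the
grid, is prescribed by the source analysis. Times are hours, so frequencies
read directly in cycles/hour. One caveat a user should know: if gaps are
strictly periodic (say, exactly one burst per hour), a 24 h rhythm is
genuinely ambiguous with 1/h-harmonic aliases — an artifact of the sampling
comb, not the estimator. Irregular gap placement (as in real drop-outs)
suppresses these aliases.

**Epoch labels.** Day is [06:00, 22:00) and night [22:00, 06:00) by
wall-clock window start. Seizure-relative states, with precedence
ictal > pre-ictal > post-exclusion:

* *ictal* — the window interval overlaps a seizure annotation;
* *pre-ictal* — window start within the 4 h before a seizure onset;
* *post-exclusion* — window start within 30 min after a seizure **end**
  (the annotations provide ends; anchoring at the end is the conservative
  reading of "after a seizure");
* *inter-ictal* — everything else.

When a window falls both shortly after one seizure and within 4 h of the
next, pre-ictal wins: the inter-ictal reference must exclude both
categories, and pre-ictal data are the scarce class of interest. Membership
is decided by window start time throughout — simple and deterministic.

**Comparisons.** Group contrasts are medians of unsmoothed defined values
with relative changes $(\bar{a}_{night} - \bar{a}_{day})/\bar{a}_{day}$ and
$(\bar{a}_{pre} - \bar{a}_{inter})/\bar{a}_{inter}$. An empty group (a
recording without seizures) yields no result for that axis rather than a
placeholder. The assortativity–clustering relation is summarised by the
Pearson correlation over paired defined windows plus a 2-D histogram
normalized to its maximum bin count; 50 × 50 bins over the observed ranges
(bin counts are not prescribed by the source analysis).

## The synthetic generator: a stated world

Clinical multi-day intracranial recordings are not publicly available, so
every downstream stage is validated against a generator with known
structure: Kuramoto-type phase oscillators
$$\dot\Phi_n = 2\pi f_n + K(t) \sum_m W_{nm}(t) \sin(\Phi_m - \Phi_n),$$
integrated by fixed-step Euler at the sampling rate (adequate for phase
dynamics at 200 Hz and dependency-free), observed as $\sin\Phi_n$ plus
Gaussian noise. Defaults: 200 Hz; per-channel base frequencies spread over
9–11 Hz (alpha-range rhythms); coupling gain 20 rad/s at the daytime peak
and 2 at night (a gain of this size locks oscillators a few Hz apart;
0 decouples them); observation noise SD 0.1 of the unit signal amplitude.
$W(t)$ cross-fades sinusoidally — smooth, differentiable, one parameter —
between a *day* and a *night* topology on a 24 h wall-clock cycle (peak
14:00); $K(t)$ is raised by a factor (default 3) during annotated seizures.
Gaps are implemented by sample deletion, so downstream timestamps become
non-uniform exactly as recording drop-outs make them.

Two stylised topologies are built in: *hub-dominated* (a few cores wired to
everyone) and *modular* (fully connected blocks of deliberately unequal
size). A subtlety documented up front: the sign of the *functional*
(thresholded-coherence) network's assortativity is not inherited from the
*coupling* graph. A modular coupling graph with unequal blocks yields
near-clique functional networks whose links join equal-degree nodes —
strongly assortative — while a hub-driven system synchronises leaf pairs
through their common drive, producing dissortative-to-uncorrelated
functional networks. Ground truth for recovery tests is therefore computed
numerically at generation time, by running short pure-day and pure-night
snippets through the canonical analysis, never read off the coupling graph.
Both day/night regimes (higher-day or higher-night assortativity) are
reachable by assigning topologies to the two phases; the
lower-night-assortativity regime used in the tests is day-modular /
night-hub.

What the generator does **not** emulate: 1/f spectra, epileptiform spikes or
any waveform morphology, sleep architecture, re-referencing of electrode
contacts, and medication effects. A green recovery test therefore
establishes that the pipeline recovers planted periodicity, day/night
contrast and epoch structure from signals with controlled phase synchrony —
not that it would detect any particular clinical effect.

## Reproducibility and scale

Everything is deterministic under a fixed seed: the generator (noise,
initial phases), the null ensemble, and the pipeline as a whole; reruns are
byte-identical. Test-suite recovery runs at a reduced scale the source
analysis's runtime note anticipates: 16 channels, 3 simulated days, one
jittered 128 s kept segment per hour (~3.6% duty cycle, 432 windows), which
keeps the end-to-end suite within a couple of minutes while leaving ≥ 3
modulation periods for the periodogram.

## Known limitations

* Euler integration at the sampling rate slightly biases oscillator
  trajectories for strong coupling; recovery tests operate at the coherence
  level, where this is immaterial.
* The per-window analytic signal has edge effects; they are accepted by
  design and damped by the temporal average in the coherence.
* Records are processed in memory; multi-day full-duty recordings at 200 Hz
  should be processed in segments (the gap machinery makes this natural).
* The CLI-style entry point is the function surface
  (`pipeline_config()` + `run_pipeline()`); there is no shell executable.
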