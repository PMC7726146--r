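---
title: "Analysing modular neuronal networks on MEAs with meamod"
author: "meamod authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing modular neuronal networks on MEAs with meamod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meamod)
```

## The analysis problem

Patterned MEA cultures confine neurons to small network modules (a few
electrodes each) whose mutual connections can be created, severed, or
reversibly silenced. Three complementary measurements characterize the
functional coupling between modules:

1. **Rate correlation.** Spike trains are binned into firing-rate
   histograms, smoothed, and correlated pairwise. The mean coefficient
   within a module (intra-CC) measures local synchrony; the mean across
   modules (inter-CC) measures global synchrony. Disconnected modules have
   inter-CC near zero while intra-CC stays high.
2. **Synchronized-event structure.** Bursts that overlap across electrodes
   form synchronized events; events spanning several modules reveal which
   module leads (propagation direction) and how much of each electrode's
   activity is engaged (association degree).
3. **Perturbation.** Silencing one module and measuring the partner's rate
   change gives a directed, causal influence estimate that spontaneous
   correlation alone cannot provide.

`meamod` implements all three, plus the spike detection that precedes them
and a generative simulator that provides ground truth for validation.

## Models and procedures

### Spike detection

Spikes are negative threshold crossings at $-k\sigma$ with $k = 6$ by
default. The noise level $\sigma$ is estimated as
$\mathrm{median}(|x - \mathrm{median}(x)|)/0.6745$ — the MAD scaled to the
SD of a Gaussian. A robust estimator matters because the spikes themselves
inflate a naive SD; with 1% large spikes in the trace the global SD
overestimates $\sigma$ noticeably while the MAD barely moves (the global
estimator is retained as an option for comparison). A spike is timestamped
at the first sample of the sub-threshold excursion, the simplest
deterministic rule; a 1 ms dead time prevents one waveform from being
counted more than once. Only the negative threshold is applied. Because
many acquisition chains band-pass in hardware (150–4000 Hz in the systems
this package targets), software filtering is optional; `bandpassFilter()`
provides an effective fourth-order zero-phase Butterworth (second-order
design applied forward and backward so spike times are not shifted).

Stimulation artifacts are handled by deterministic blanking: every
detection within 2 ms after a stimulus is discarded. This replaces
sorting-based artifact rejection, which would introduce a stochastic,
parameter-heavy step into an otherwise exactly testable chain; the package
deliberately performs no unit isolation and analyses multi-unit activity
per electrode.

### Rates and correlation

Rate histograms use half-open 100 ms bins, $[a, a+w)$, so boundary spikes
are never double counted; the unsmoothed bin value is count/width (Hz).
Smoothing uses a 5-bin discrete Gaussian. The kernel's SD is a free
parameter of any "5-bin Gaussian filter" description; the package uses
$\sigma = 1.25$ bins so the support covers $\pm 2\sigma$, and exposes it as
a configuration field. At the histogram edges the kernel is renormalized
over the in-range bins rather than zero-padded, so every input bin
redistributes exactly its own count and the total spike count is conserved
to floating-point precision (the test suite requires $10^{-9}$ relative
error).

Electrodes enter correlation analyses only when their session mean rate
strictly exceeds 0.05 Hz: an electrode with exactly 30 spikes in 600 s is
excluded. Pearson coefficients are computed on the smoothed histograms (a
switch allows raw histograms), over the full session by default — a window
option (`cropSession()`) supports sub-window analyses such as before/after
comparisons within one recording. Zero-variance channels yield undefined
coefficients; these are reported as `NA` and *excluded* from intra/inter
means rather than set to zero, which would bias inter-CC toward zero.
Pairs involving control electrodes are summarized separately and never
enter intra- or inter-CC.

### Bursts and synchronized events

A burst is a maximal run of spikes whose successive gaps are at most
200 ms; the quoted threshold is on the gap, so a gap exactly at 200 ms
stays within the burst (the half-open convention applies to bins, not
gaps). A minimum of 3 spikes per burst is required by default: the
two-spike floor implied by "successive spikes" would let isolated spike
pairs seed events; 3 is the conventional floor and the parameter is
configurable.

Synchronized bursting events are connected components of the burst-window
overlap graph, using closed intervals (touching endpoints count as
simultaneous) and transitive merging — a chain of pairwise-overlapping
bursts becomes one event, matching the treatment of events as single
windows. For intervals, these components are exactly the maximal merged
runs of a sweep over sorted windows, which is how the implementation
computes them; the test suite checks equivalence against a literal
$O(n^2)$ overlap-graph-plus-components oracle on randomized instances. A
component must span two or more *electrodes* to be an SBE and two or more
non-control *modules* to be an SE. The optional single-spike rule promotes
a single-module SBE to an SE when any other-module electrode fires at
least once inside the window; it is off by default and intended for
two-electrode-per-module layouts where burst overlap is a high bar. A
shaded 100 ms visualization window sometimes drawn around synchronized
activity in raster figures is treated as display only; detection uses the
200 ms burst rule throughout.

Association degree divides each electrode's spikes inside the union of SE
windows by its total spike count; windows are merged before counting so
the union is well defined, and zero-spike electrodes are flagged `NA`.
Because it is sometimes reported per electrode and sometimes as module
means, `moduleAssociation()` provides the per-module aggregation
alongside the per-electrode table.

Propagation direction orders the participating modules of an SE by their
first spike inside the (closed) event window, where a module's first spike
is the minimum over its participating electrodes. If any two adjacent
modules in the ordering differ by less than the tie tolerance (1 ms by
default, well below the 15–35 ms delays typical of inter-module
propagation) the event is flagged ambiguous and excluded from direction
tallies. Proportions are normalized over unambiguous labels only.

### Suppression and influence

A modulation epoch is a window $[on, off)$ during which one module is
illuminated at a given power density (carried as opaque metadata; no
photothermal dose model is implemented — suppression strength enters only
through the measured rate change). The baseline window immediately
precedes the epoch and defaults to the epoch's own length; raster figures
of such experiments show pre/during/post segments without stating
durations, so the length is configurable. Module rates pool the member
electrodes' spikes over the window (robust when electrodes have
heterogeneous rates; a per-electrode variant is returned alongside), and
the percent change is $100\,(r_{during} - r_{base})/r_{base}$, undefined
when the baseline is zero. Recovery-window changes are computed and
reported for reversibility checks but do not enter the influence
statistic.

The influence of A on B is the magnitude of B's mean change at A's
maximum-suppression power, defined only when A's own change there reaches
the full-suppression criterion (≤ −90%, configurable): "maximum
suppression" is operationalized as the highest power level with an
explicit suppression check, since the definition is only meaningful when
the modulated network is actually silenced. Trials are paired by index
across source and target.

Significance against control electrodes uses an exact two-sided
Mann–Whitney test: all $\binom{n_1+n_2}{n_1}$ assignments of the mid-ranks
are enumerated and the smaller tail is doubled (capped at 1). With five
trials per group the attainable minimum is $2/252 \approx 0.0079$, which
is why p-values near 0.008 recur in such experiments; a printed value of
0.0075 is not attainable from this exact distribution at $n=5$ versus
$n=5$, so the package documents its enumeration rather than attempting to
match it. Above 20 total observations the normal approximation with tie
correction is used.

### Evoked responses

PSTHs re-reference spikes to the nearest preceding stimulus and count them
in half-open bins over $[0, 50)$ ms, normalized to counts/(trials × bin
width). Stimulus spacing must exceed the analysis window so trial windows
never overlap. Bins falling inside the 2 ms artifact blank are reported as
masked rather than zero, so downstream consumers can distinguish "no
response" from "not measurable". Stimulated electrodes are excluded from
array-level mean PSTHs. The early/late split summarizes response mass
below 10 ms (direct/antidromic activation of the stimulated network) and
within 15–35 ms (synaptic propagation from another network); bin edges
must align with those boundaries. Response probability is the fraction of
trials with at least one spike in the response window; pooling across
several stimulation electrodes is done by concatenating their stimulus
times, and is left to the caller because published counts do not always
state the pooling.

## The simulator

The generator models activity at the burst-event level rather than with
biophysical neurons: the analyses only see spike times, and event-level
generation gives exact, controllable ground truth for propagation and
influence recovery.

- Each module emits intrinsic burst events as a Poisson process at
  `burstRate × (1 − drivenFraction)`.
- Each burst of a source module triggers a burst in a coupled target with
  probability $p$ after a Gaussian delay truncated to positive values
  (mean 30 ms, SD 8 ms by default — truncated Gaussian rather than
  exponential because observed inter-module latencies concentrate in a
  narrow 15–35 ms window). Triggering is recursive, so reciprocal
  couplings produce reverberating cascades; these terminate almost surely
  while the loop gain (product of coupling probabilities around a cycle)
  stays below one, and the generator aborts with an error if a cascade
  fails to terminate.
- Within a burst, each electrode of the module participates with
  probability 0.9 and fires a Poisson(15) number of spikes uniformly over
  the 250 ms burst duration; independent Poisson background spikes
  (0.2 Hz per electrode) are added.
- Suppression epochs delete the targeted module's bursts with probability
  $1 - \mathrm{factor}$ (the configured rate scaling for the epoch's
  power) and, through the recorded parent–child provenance, every burst
  downstream of a deleted one — so silencing a driver also silences what
  it would have driven. Background spikes in the epoch are thinned by the
  same factor. Thinning was chosen as the simplest mechanism that produces
  graded, power-dependent rate changes.
- Evoked responses give each stimulus, per responding module, a Bernoulli
  response; a responding trial places one spike per electrode at the
  trial's truncated-Gaussian latency plus small per-electrode jitter.
- Raw traces are Gaussian noise plus a 1 ms negative-leading biphasic
  template (60% negative lobe at the full amplitude, 40% positive lobe at
  0.35× — an arbitrary but documented shape) inserted at each spike time;
  overlapping injections superimpose additively and are counted.

A single integer seed fixes all randomness; identical configurations and
seeds reproduce sessions and serialized reports byte for byte.

### Preset study conditions

Two presets encode the study conditions used throughout the tests.
`presetCoupledPair(p)` is a pair of four-electrode modules bursting at
10 events/min with an optional one-way coupling of probability `p` and an
unconnected control module; with `p = 0` it provides the null condition
(inter-CC within ±0.05 of zero at 600 s, intra-CC above 0.5), and the
coupling can be restricted to a time window to emulate a mid-session
structural disconnection. `presetAsymmetricPair()` realizes a one-sided
dependency: N1 has no intrinsic bursts and is driven entirely by N2
($p = 1$), while N2 is driven back with $p = 0.6$, so at stationarity 60%
of N2's bursts trace back to N1 and suppressing N1 removes about 60% of
N2's activity while suppressing N2 silences N1. Both modules burst at
40 events/min — the regime of a strongly synchronized mature culture —
with suppression trials of 60 s. These sizes keep the burst-count
(Poisson) noise of a per-trial percent change small: with roughly 40
baseline bursts per trial window, a five-trial mean change carries an SD
of a few percentage points, so the influence statistic is determined by
the network structure rather than by counting noise.

### What the simulator does not emulate

Passing these tests shows the analysis chain is correct and sensitive
under the generator's assumptions, not that real recordings satisfy them.
The generator omits, among other things: burst-internal temporal structure
(rate envelopes, within-burst propagation between electrodes of one
module), development and plasticity (synchronization emerging over days is
biology, not an algorithm, and is emulated only as a coupling switched on
or off), electrode-specific amplitudes and noise spectra, non-stationary
background rates, true photothermal dose–response (suppression factors are
specified per power, not derived from physics), and spike waveform
diversity (no sorting is attempted, so none is simulated).

## Numerical choices and degenerate inputs

- Time is in seconds (double precision) starting at 0 unless declared;
  bins and analysis windows are half-open, burst and event windows closed.
- Delimited spike tables are comma-separated, dot-decimal, UTF-8, one
  header line, timestamps at 9 decimals (1 ns); HDF5 round trips are
  bit-identical. Silent electrodes survive round trips via a roster
  header.
- The PSTH binning adds a $10^{-9}$-bin relative guard before the floor so
  a latency nominally on a bin edge is assigned to the right-hand bin
  despite floating-point subtraction error.
- Validation rejects every constructed invariant violation: unsorted or
  duplicated timestamps (naming the electrode), spikes outside
  $[t_{start}, t_{stop})$, mismatched train intervals, electrodes in two
  modules, maps with no non-control module, non-positive sampling rates.
  Constant traces are a degenerate-signal error in noise estimation, and
  zero-baseline rate changes, zero-spike association degrees and
  zero-variance correlations are `NA` with flags, never silent zeros.
- Electrode exclusion beyond the activity filter is supported through an
  explicit exclusion list in the module map, since no further criterion is
  standard.
- The −6 SD threshold is recomputed per recording (per call); whether to
  fix it per channel across days is a protocol decision left to the
  caller.

## Problem sizes used in the test suite

The oracle-equivalence tests run 100 randomized small instances per
operation against literal brute-force implementations. The statistical
properties use: 10 seeds of 600 s uncoupled sessions for the null
correlation bounds; 10 seeds of the asymmetric pair (1850 s suppression
sessions with 2 power levels × 5 trials of 60 s, plus 360 s spontaneous
sessions for propagation); 3 seeds of 600 s for the mid-session
disconnection contrast; and 10 rendered 60 s traces at 25 kHz with
10σ spikes for detection recall (≥ 0.96 required) and false positives
(≤ 2/min). Influence bands (I ≥ 90% and I in [45, 75]%) are asserted on
the across-seed mean, the per-seed spread being dominated by five-trial
sampling noise; the dominant propagation direction (≥ 80% of labeled SEs)
and the detection bounds hold per seed. The whole suite runs in well under
a minute on one CPU.

## Limitations

The package analyses multi-unit, per-electrode activity only; it provides
no spike sorting, no lagged or spectral correlation measures (zero-lag
Pearson only), no burst-shape metrics beyond what the analyses require,
and no biophysical or photothermal modeling. Influence estimates inherit
the usual caveats of perturbation measures: they are defined only at full
suppression of the source, pool whatever pathway (direct or indirect)
links the modules, and assume stationarity across the trial blocks.
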