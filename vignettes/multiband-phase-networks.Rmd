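---
title: "Multiband phase-locking networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband phase-locking networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(plvnet)
library(dplyr)
```

plvnet builds and compares EEG functional networks organized around a single
primitive, the phase-locking value (PLV), at four levels: static within-band
networks (low- and high-order), sliding-window dynamic networks with
integration/segregation state entropy, between-frequency networks summarized
by a supra-adjacency matrix, and FDR-controlled group statistics. This
vignette explains the models behind each stage, the parameters that matter,
and the design decisions taken where the methodology leaves choices open.

## The connectivity model

### Instantaneous phase

Each recording is band-limited into the four canonical rhythms — delta
(1–4 Hz), theta (4–8 Hz), alpha (8–13 Hz), beta (13–30 Hz) — with a
4th-order Butterworth band-pass applied forward–backward
(`signal::filtfilt`). The forward–backward pass has zero phase response,
which matters because phase is the quantity under study; the effective
magnitude roll-off is that of an 8th-order filter. The instantaneous phase
is the four-quadrant angle of the analytic signal,
$\varphi(t) = \arg\left(x(t) + i\,\mathcal{H}[x](t)\right)$, computed by
frequency-domain Hilbert transform. (A single-argument arctangent of
$\mathcal{H}[x]/x$ would wrap into two quadrants and cannot produce a
continuous phase ramp even for a pure sinusoid; the four-quadrant convention
is the only self-consistent one.)

Both the filter and the Hilbert transform distort the ends of a finite
record, so `band_phases()` marks the first and last `trim_s` seconds
(default 1 s) invalid; all downstream PLV estimates use only the valid
range.

### Low-order networks

For channels $u, v$ the phase-locking value is

$$\mathrm{PLV} = \left|\frac{1}{N}\sum_{j=0}^{N-1}
  e^{\,i(\varphi_u(j\Delta t) - \varphi_v(j\Delta t))}\right|,$$

the modulus of the time-averaged unit phasor of the phase difference: 1 for
a constant phase relation, approximately $\sqrt{\pi/4N}$ for independent
phases. `lofc()` evaluates this for all channel pairs over the full valid
range (the static network); the matrix is symmetric with entries in
$[0, 1]$.

### High-order networks

The high-order network asks a different question: not "are these two
channels synchronized?" but "do these two channels synchronize with the
rest of the brain in the same way?". Edge $(i, j)$ is the Pearson
correlation between columns $i$ and $j$ of the low-order matrix after (a)
deleting rows $i$ and $j$ from both columns (the self-connection terms,
which would otherwise inject the trivial correlation of a channel with
itself), and (b) Fisher z-transforming each column entry
($z = \operatorname{atanh} r$), which maps the bounded PLVs onto an
unbounded, approximately variance-stabilized scale. Entries are clipped to
$1 - 10^{-12}$ in magnitude before `atanh` so z stays finite when a PLV is
exactly 1; the clip is far below any meaningful resolution. If a reduced
column has zero variance the correlation is undefined; the package sets
that edge to 0 and raises a degenerate-edge warning rather than emitting
NaN, so graph metrics downstream always see finite weights. High-order
entries are signed, in $[-1, 1]$, with a zero diagonal.

### Between-frequency networks and the supra-adjacency matrix

For a band pair $(a, b)$, `cross_band_lofc()` computes the PLV between the
phase of band $a$ on channel $i$ and band $b$ on channel $j$, for all
ordered pairs including $i = j$ (the same-channel cross-frequency case).
The default is the literal 1:1 phase difference. Because two rhythms with
different center frequencies precess against each other, 1:1 locking
between distinct bands is non-stationary by construction; the package
therefore also offers an n:m mode,
$|\,\mathrm{mean}\, e^{i(n\varphi_a - m\varphi_b)}|$, with the ratio
defaulting to the rounded band-center ratio. The 1:1 default reflects the
canonical analysis; n:m is the appropriate instrument when harmonically
linked rhythms are the hypothesis (and is what the planted-linkage
recovery analysis uses).

Band-pair matrices are not symmetrized — entry $(i, j)$ genuinely differs
from $(j, i)$ since the bands attach to different channels. The
supra-adjacency matrix $S$ places the four within-band matrices on the
diagonal blocks and each band-pair matrix in its off-diagonal block, with
the transpose in the mirrored block, so $S$ is symmetric of size
$(B \cdot C)^2$ — 32 × 32 at the defaults (4 bands × 8 channels). The
cross-band global metric is the arithmetic mean of a band pair's block (and
overall, of all off-diagonal-block entries); it scales linearly with the
block weights and reduces to the block constant for constant blocks. The
same assembly applies verbatim to high-order blocks.

## Graph metrics

All four metrics operate on weighted networks directly — no thresholding
or binarization, avoiding the arbitrary-threshold bias — after
`prepare_weights()` zeroes the diagonal and rectifies high-order negatives
(clipped to 0 by default; `absolute` mode is available because the
treatment of negative correlation weights is a genuinely open choice; the
default discards anti-correlation rather than conflating it with positive
coupling). Connection lengths are inverse weights, $\ell = 1/w$, the
conventional choice for PLV-type weights where strong coupling means short
functional distance ($-\log w$ is available for audit).

* **Clustering coefficient**: mean over nodes of geometric-mean triangle
  intensity, $\mathrm{CC}_i = \sum_{j,h}(w_{ij} w_{ih} w_{jh})^{1/3} /
  [k_i(k_i - 1)]$ with $k_i$ the binary degree. Nodes with fewer than two
  neighbors contribute 0.
* **Characteristic path length**: mean shortest-path distance over ordered
  pairs. Disconnected pairs make it $+\infty$; the mean over finite pairs
  is reported alongside, and group comparisons use that finite-subnetwork
  mean (identical to CPL whenever the network is connected).
* **Global efficiency**: mean of $1/d_{ij}$ with $1/\infty = 0$ — defined
  natively on disconnected graphs.
* **Local efficiency**: mean over nodes of
  $\sum_{j \ne h \in N_i} (w_{ij} w_{ih} / d_{jh}(N_i))^{1/3} /
  [k_i(k_i-1)]$, where $d_{jh}(N_i)$ is the shortest path between
  neighbors inside the subgraph induced by $N_i$. The cube root is applied
  to the whole product, with distances computed on plain inverse-weight
  lengths; this follows the printed formulation in which the $1/3$ exponent
  covers the $d^{-1}$ term. (An alternative convention computes distances
  on cube-rooted lengths; on dense 8-node PLV networks, where most
  neighbor pairs are directly connected, the two agree closely.)

Every metric is checked against independent brute-force oracles (explicit
triplet enumeration, Floyd–Warshall path search, neighborhood extraction)
on hundreds of random weighted graphs, to $10^{-10}$.

## Dynamics: states and entropy

Six window lengths (0.5, 1, 2, 4, 6, 8 s) at 20% overlap span sub-second
fluctuations through slow network reconfiguration. The step is rounded to
integer samples and the last partial window is dropped, so all windows
carry equal-length PLV estimates. At 300 s and 1000 Hz this yields 749
windows at 0.5 s down to 46 at 8 s. Note that a 0.5 s window contains
fewer than two delta cycles; delta-band estimates at the shortest windows
are intrinsically unstable, which is a property of the analysis scale, not
a software artifact.

Each window's network yields a participation-coefficient vector,
$\mathrm{PC}_i = 1 - \sum_s (\kappa_{is}/k_i)^2$, over a module partition
(default: the anatomical left/right pairs frontal {F3, F4}, central
{C3, C4}, temporal {T3, T4}, occipital {O1, O2}). High PC means strength
spread across modules — integration; low PC means strength concentrated
within the node's module — segregation. K-means with $k = 2$, best of 50
seeded restarts by within-cluster sum of squares, classifies windows; the
cluster with higher mean network PC is labeled 1 (integration). The
feature is the per-node PC *vector* by default (richer than the scalar
network mean, which is available via `state_features = "mean"`).

The state entropy of the resulting binary sequence is the normalized
Shannon entropy of the four consecutive-window pair types (00, 01, 10, 11):

$$\mathrm{SE} = -\frac{1}{\log 4}\sum_{i=1}^{4} p_i \log p_i,$$

with natural logarithms (the normalization makes the base irrelevant) and
$0 \log 0 = 0$. SE is 0 iff exactly one pair type occurs, 1 for the uniform
pair distribution, and invariant to the global relabeling $0
\leftrightarrow 1$. A strictly alternating 8-label sequence gives
$-(\tfrac{4}{7}\log\tfrac{4}{7} + \tfrac{3}{7}\log\tfrac{3}{7})/\log 4
\approx 0.4926$.

One caveat worth knowing when interpreting PC-based states on dense PLV
networks: background synchronization spreads strength evenly across
modules, which *raises* PC. Segregation is only visible when within-module
weights genuinely dominate the noise floor of the window-level PLV
estimate, and that floor grows as windows shorten (roughly
$\sqrt{\pi/4N_{\mathrm{eff}}}$ with $N_{\mathrm{eff}}$ the number of
independent phase-difference samples per window).

## Group statistics

Every between-group analysis reduces to the same engine: an independent
two-sample t-test per item (pooled variance by default — the conventional
reading of "independent-sample t-tests" — Welch by flag), Benjamini–
Hochberg FDR within the analysis family, and the sign of the group
difference. Families are band × order for the 28 within-band edges, band
pair × order for the 64 between-frequency edges, band × order for the four
metrics and for the six window lengths of SE, and order for the six
cross-band global metrics. BH rather than BY is the default because PLV
edges are positively dependent, the standard regime for BH. Raw and
adjusted p-values are always reported together so any alternative
correction scope (e.g. joint across bands) can be audited from the output;
the package does not guess which scope an external study used.

## The synthetic cohort generator

No public EEG cohort accompanies this methodology, so the package ships a
generator whose ground truth is *exactly* the quantity the pipeline
measures: phase coupling. Per band, each channel is a noisy Kuramoto phase
oscillator

$$d\varphi_i = 2\pi f_b\, dt + \sum_j K_{ij}\sin(\varphi_j - \varphi_i)\,
  dt + \sigma\, dW_i,$$

integrated by Euler–Maruyama at the recording sampling rate (step
$1/f_s$; at 1000 Hz the step-size bias is negligible relative to the phase
noise, but the integrator is not meant for $f_s$ below ~10× the highest
band edge). The coupling matrix $K$ (rad/s, symmetric, nonnegative) is
group-specific, giving direct, continuous control of PLV; empirical PLV is
monotone in $K_{ij}$ and spans ~0.05 (uncoupled, long recordings) to >0.99
(strong coupling). The observed signal is
$\sum_b A_b \cos\varphi^b_i(t)$ plus $1/f^\beta$ Gaussian background noise
(spectral shaping of white noise, $\beta = 1$ by default, amplitude 0.5
relative to unit oscillation amplitude).

Cross-band linkages overwrite a target channel's phase in one band with
$\frac{n}{m}\varphi_{\text{source}} + (1 - s)\,\xi(t)$, where $\xi$ is an
independent phase random walk and $s \in [0, 1]$ the linkage strength —
at $s = 1$ a perfect n:m harmonic, at $s = 0$ an independent phase. The
n:m ratio should be chosen so the slaved phase's instantaneous frequency
lands inside the target band (e.g. theta at 6 Hz slaved 2:1 into alpha at
12 Hz).

Defaults mirror a resting-state pediatric protocol: 8 channels of the
10–20 montage, 1000 Hz, 300 s, two groups of 36. Everything is seeded:
subject seeds derive deterministically from the base seed, group index and
subject index, so a truth object reproduces its cohort bit-for-bit.

What the generator does *not* emulate: volume conduction and reference
effects (a linear mixing stage is deliberately absent by default, because
mixing inflates zero-lag PLV and would blur the planted ground truth),
eye-blink/EMG artifacts, and nonstationary amplitude dynamics. Passing
recovery tests on these cohorts therefore demonstrates that the pipeline
measures planted phase coupling correctly — not that it is robust to the
artifact structure of real scalp EEG.

## Problem sizes and calibration conditions

The calibration and recovery analyses are run at desk scale: null
calibration uses 20 cohorts of 36 + 36 subjects, one band, 20 s at 128 Hz;
planted-effect recovery uses 5 cohorts of 36 + 36, two bands, 40 s at
200 Hz, with coupling 3 rad/s on three planted edges per band (subject-level
standardized effect far above 1); linkage recovery uses 12 + 12 subjects,
30 s at 128 Hz, four 2:1 theta→alpha linkages. Group sizes and replicate
counts match the canonical study conditions; durations and sampling rates
are reduced because PLV estimator variance, not recording length, is the
quantity under test, and the planted effects are defined at subject level.

## Open choices and how the package resolves them

A few points are genuinely underdetermined in this kind of analysis; the
package picks a default and keeps the alternative reachable:

* **Re-referencing.** Synthetic data need none, so the common-average
  re-reference in `preprocess()` is off by default; real recordings
  referenced to a single site can switch it on. PLV is not
  reference-invariant, so the choice should be reported with any result.
* **Same-channel cross-band edges.** The between-frequency matrices
  include the i = j entries (a channel's own cross-rhythm coupling); they
  participate in the block means and edge families. Excluding them is a
  one-line filter on the tidy edge table.
* **States from low- or high-order windows.** `dynamics_orders` in the
  pipeline config runs the participation/state/entropy chain on either or
  both network orders; both are first-class.
* **Negative high-order weights.** Clipped to zero by default, absolute
  value by option (`weight_mode = "absolute"`); both modes flow through
  the whole metric pipeline.

## Numerical choices and degenerate inputs

* PLV clipping: tiny floating-point excursions above 1 from the vectorized
  phasor products are clipped back to 1.
* `atanh` guard: $|r| \le 1 - 10^{-12}$ before Fisher z.
* HOFC degenerate columns: edge set to 0 with a warning (never NaN).
* Zero-variance t-tests: equal means give $t = 0, p = 1$; unequal means
  give signed infinite $t$, $p = 0$.
* Disconnected networks: CPL is $+\infty$ with a flag and a
  finite-subnetwork mean; GE and LE are defined natively.
* K-means on identical feature vectors raises a degenerate-clustering
  error (state entropy would be meaningless).
* Window steps round to integer samples; partial trailing windows are
  dropped, never padded.
* Constant (zero-variance) signals have no phase and raise an error.

## Worked example

A miniature two-group cohort with alpha-band coupling planted in one group:

```{r example}
bands <- list(theta = band_spec("theta", 4, 8),
              alpha = band_spec("alpha", 8, 13))
truth <- synthetic_truth(
  bands = bands, groups = c(TD = 4L, ASD = 4L),
  coupling = list(TD = list(alpha = coupling_matrix(
    8, rbind(c(1, 2), c(3, 4)), 6))),
  fs = 128, dur_s = 20, n_channels = 8L, seed = 7)
cohort <- simulate_cohort(truth)
cfg <- pipeline_config(bands = bands,
                       schemes = list(w2 = window_scheme(2, 0.2)),
                       kmeans_replicates = 10L, seed = 1L)
bundle <- run_pipeline(cohort, cfg)
bundle
glance(bundle$comparisons[["edges:alpha:low"]])
head(tidy(bundle$comparisons[["edges:alpha:low"]]) |>
       arrange(p) |> select(item, mean_a, mean_b, t, p, q, direction))
```

The planted F3–F4 and T3–C3 edges surface with TD > ASD direction. The
same bundle carries the graph metrics, state entropies and cross-band
global metrics for every subject:

```{r example2}
head(bundle$metrics)
head(bundle$entropy)
head(bundle$crossband_global)
```

## Known limitations

* Eight sensors span a coarse subnetwork; the metrics describe that
  subnetwork, not the full cortical topology.
* 1:1 between-frequency PLV on genuinely different rhythms is dominated by
  precession; treat its absolute level as a relative, not physical,
  coupling measure (use n:m mode for harmonic hypotheses).
* The state classifier is limited to two states by design; richer state
  spaces (HMMs, k > 2) are out of scope.
* The generator's Euler–Maruyama step ties integration accuracy to the
  sampling rate; very low sampling rates with strong coupling are outside
  its intended regime.
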