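---
title: "Methods: sensor fusion and age regression for rice wines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor fusion and age regression for rice wines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavorfuse)
```

`flavorfuse` implements a complete feature-level fusion workflow for two
flavor-sensing instruments — a pulse-voltammetric electronic tongue and a
12-sensor MOS electronic nose — ending in a regression of rice-wine marked
age. This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic
generator can demonstrate.

## The measurement model behind the synthetic generator

The original measurement campaign this workflow targets is five marked-age
classes (3, 5, 8, 10, 20 years) with 40 replicate wine samples each, every
sample measured by both instruments. Raw instrument data of that kind are
rarely shareable, so the package ships a seeded generator whose output has
the temporal and statistical structure the downstream analysis relies on.

**E-nose traces.** Each MOS sensor's response to a headspace sample rises
quickly during exposure, holds a plateau, and decays when the chamber is
flushed with clean dry air. We model the value at time $t$ (seconds) as

$$v(t) = \begin{cases}
  b + A\,\dfrac{1 - e^{-t/\tau_r}}{1 - e^{-t_p/\tau_r}} & 0 \le t \le t_p \\
  b + A & t_p < t \le t_c \\
  b + A\, e^{-(t - t_c)/\tau_d} & t > t_c
\end{cases}$$

with plateau amplitude $A$, baseline $b = 0$, rise constant $\tau_r = 3$ s,
decay constant $\tau_d = 40$ s, plateau onset $t_p = 10$ s and cleaning onset
$t_c = 50$ s. The rise term is normalised so the plateau is reached *exactly*
at $t_p$; a plain $1 - e^{-t/\tau_r}$ rise with $\tau_r = 3$ s would still be
3.6 % short of $A$ at 10 s, which contradicts the observed flat plateau
between the 10th and 50th second. Traces span 0–230 s. No sampling rate is
dictated by the hardware narrative beyond second-level resolution, so the
generator samples at 1 Hz (231 points) — a deliberate, configurable choice.
Values are clipped to the instrument range 0–3500 mV.

**E-tongue traces.** The two excitation waveforms are multi-frequency
rectangle pulse voltammetry (MRPV: 1 Hz for 11 s, 10 Hz for 1.1 s, 100 Hz
for 0.11 s; 12.21 s total) and the staircase variant MSPV (7 s / 0.7 s /
0.07 s; 7.77 s total). Within each potential step the current follows a
capacitive-decay transient

$$i(t) = I_{ss} + (I_{peak} - I_{ss})\, e^{-t/\tau}, \qquad
  I_{peak} = a \cdot V_{step}, \quad I_{ss} = 0.35\, I_{peak},$$

with $\tau = 0.05$ s and $a$ the class's analyte-level sensitivity for that
electrode (the three electrodes respond to tyrosine, ascorbic acid and
glucose, whose concentrations track aging). The default sampling interval is
**0.002 s**: it is the value consistent with the instrument's raw data
counts, $12.21/0.002 \times 3 = 18315$ points per sample for MRPV and
$7.77/0.002 \times 3 = 11655$ for MSPV, both exact integers. Trace length per
electrode is $\lfloor \text{duration}/\Delta t \rfloor$. Coarser intervals
are supported (0.02 s gives $\lfloor 610.5 \rfloor = 610$ points), but beware
of aliasing: sampling a 100 Hz pulse train at 0.02 s locks onto a fixed phase
of the step cycle, which can flatten the fastest phase's features.

**Noise and correlation structure.** One `noise_sd` parameter (default 0.05,
i.e. 5 % relative noise) drives (a) a multiplicative Gaussian factor on each
trace's amplitude, (b) a smaller additive white noise on individual samples,
and (c) a per-sample factor *shared by all channels of the same device*.
The shared factor is what makes features from the same sensor or electrode
more correlated than features across devices — the multicollinearity that
motivates the VIF step. The age→amplitude map is monotone for all channels
except one e-nose sensor (S11), which dips at 10 years: real score plots show
the 10-year class breaking the otherwise monotone ordering, and a generator
in which every channel orders the classes identically would make the
discrimination task unrealistically easy.

**What the generator does not emulate:** sensor drift and hysteresis,
inter-session batch effects, temperature/humidity confounds, heteroscedastic
saturation near the range limits, and any true electrochemical kinetics.
Passing tests on synthetic data therefore demonstrate the *pipeline's*
correctness and its behaviour under the assumed signal structure — not
instrument-level performance on real wines.

## Area features

Every trace is reduced by the area method: trapezoidal integrals over
defined windows (exact for piecewise-linear signals, and additive across
windows that share a boundary — the reason the boundary sample at 50 s
belongs to both windows without double-counting any area).

* E-tongue: one area per frequency phase (windows at the cumulative phase
  durations, in the order 1 Hz, 10 Hz, 100 Hz) per waveform per electrode:
  $3 \times 2 \times 3 = 18$ features `E{e}{w}{f}`. A `collapse_phases`
  option yields the 6 whole-waveform areas instead; the 18-feature form is
  the default because the fused table's arithmetic ($18 + 24 = 42$) requires
  it.
* E-nose: per sensor, the exposure-window area (0–50 s, "taste") and the
  cleaning-window area (50–230 s, "aftertaste"): $12 \times 2 = 24$ features
  `S{k}a{1,2}`.

## Fusion and the 16/9 weight

Both blocks are z-scored before fusing (population standard deviation;
"normalisation" is otherwise underspecified, and the choice is configurable).
Direct fusion concatenates the standardized blocks. Weighted fusion first
multiplies the e-tongue block by

$$W = \frac{w_{taste}}{w_{aroma}} \times \frac{n_{enose}}{n_{etongue}}
    = \frac{0.40}{0.30} \times \frac{24}{18} = \frac{16}{9},$$

compensating both the sensory panel's higher weight on taste than aroma
(GB/T 13662-2008 factor weights) and the e-nose's larger feature count. The
published factor is stated without derivation; the formula above is this
package's reconstruction and reproduces 16/9 exactly from those printed
quantities. An explicit `weight` can be supplied instead.

Correlation is scale-invariant, so the direct and weighted tables have
identical Pearson matrices and identical VIF elimination sequences — the
package asserts both properties in its tests. VIF elimination recomputes
$\mathrm{VIF}_j = 1/(1 - R^2_j)$ for every remaining feature at every step
(ordinary least squares of feature $j$ on all others, via QR), removes the
arg-max, and stops when all values are below the threshold (default 10).
Exact collinearity gives $R^2_j = 1$ and is treated as $\mathrm{VIF} =
+\infty$, removed first; ties break toward the larger column index so runs
are deterministic. When fewer samples than features remain, every VIF is
infinite and elimination proceeds until the system is overdetermined — the
audit trail records each removal with its VIF.

## Projections

**PCA** uses the SVD of the centered matrix (numerically preferable to an
eigendecomposition of the covariance; the tests bridge the two routes).
**LPP** builds a symmetric k-nearest-neighbour graph (edge if either point
names the other; `k_neighbors = 5` by default), weights edges with a heat
kernel $w_{ij} = e^{-\lVert x_i - x_j\rVert^2 / t}$ whose bandwidth $t$
defaults to the mean squared pairwise distance (a scale-free choice; a
simple-minded 0/1 mode exists too), and solves
$X^\top L X\, a = \lambda X^\top D X\, a$ with $L = D - W$. The embedding
directions are the eigenvectors of the smallest eigenvalues, computed by
Cholesky-whitening the constraint matrix. A PCA pre-projection onto the
numerical rank is always applied first, so the highly collinear fused tables
never produce a singular $X^\top D X$. Disconnected neighbour graphs (common
when tight classes sit far apart) trigger a warning and proceed per
component. Every component's sign is fixed so its largest-magnitude loading
is positive, making score plots reproducible across runs and platforms.

## Regression protocol

A stratified, seeded split takes 25 training and 15 testing samples per
class (125/75 overall). Three regressors predict marked age in years:

* **PLSR** — univariate NIPALS with deflation; prediction is linear via
  $B = W(P^\top W)^{-1} q$. Components default to $\min(10, \mathrm{rank}\,X)$
  (no component count is prescribed by the protocol; cross-validated
  selection is deliberately out of scope). At full rank NIPALS reproduces
  ordinary least squares, which the tests exploit as an oracle.
* **ELM** — input weights and biases from a seeded uniform $(-1, 1)$,
  hidden layer $H = g(XW + b)$ with sigmoid activation by default (tanh and
  ReLU available; the protocol names only the width, $n = 27$), output
  weights $\hat\beta = H^{+} y$ (SVD pseudoinverse, minimum-norm least
  squares).
* **SVR** — $\varepsilon$-insensitive support vector regression with RBF
  kernel at the protocol's cost and width ($c = 1024$, $g = 0.0313$),
  solved by LIBSVM (package e1071). $\varepsilon$ defaults to 0.1, the
  LIBSVM convention, as no tube width is published. The fitted dual
  coefficients, support vectors and dual objective are exposed so the
  optimizer can be cross-checked against an independent QP solver — the
  test suite does exactly that with a projected-gradient method on a
  10-sample problem.

**Evaluation.** $R^2$ is the *squared Pearson correlation* between observed
and predicted ages — the convention of the LIBSVM toolchain this protocol
comes from; the coefficient of determination $1 - SS_{res}/SS_{tot}$ is
reported alongside for completeness, and a constant prediction vector yields
$R^2 = 0$ with a warning rather than `NA`. MSE is the mean squared residual
in (years)².

All randomness flows from three named seeds (dataset, split, ELM); two runs
of `run_pipeline()` with the same configuration produce byte-identical
artifacts and manifest checksums.

## Problem sizes and numerical tolerances in the test suite

Unit tests run the generator at reduced replicate counts (1–8 per class) and,
where trace shape does not matter, a coarse 0.02 s e-tongue interval, so the
suite exercises every code path quickly; study-scale properties (200
samples, default programs) are checked in the acceptance tests. Oracle
comparisons use 1e-8 for direct linear-algebra equivalences (PCA/LPP/PLSR/
ELM), 1e-4 for the SVR dual objective (two iterative optimizers), and 1 %
for integration against a 10×-finer Riemann sum. On noiseless synthetic
weighted-fusion data all three regressors reach test $R^2 \ge 0.99$ and
MSE $\le 0.1$; at the default 5 % noise the nonlinear models' headline
numbers are necessarily below the near-perfect values attainable on real
instrument data with its stronger class signal — the package reports its own
synthetic-run metrics and makes no claim to reproduce instrument-level
accuracy.

## Known limitations

* The synthetic amplitude maps are stylised; absolute feature values carry
  no chemical meaning.
* LPP offers no out-of-sample guarantee beyond its linearity; scores for new
  data reuse the training graph's projection.
* The VIF-pruned sets lose information by construction; on well-separated
  synthetic data the unpruned weighted set usually discriminates best, and
  the pipeline treats pruning as a diagnostic variant, not a default.
* PLSR component selection and SVR/ELM hyperparameter search are out of
  scope; the protocol's final values are taken as given.
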