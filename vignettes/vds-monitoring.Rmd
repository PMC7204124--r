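---
title: "Velocity-distance kernel classification of laryngeal motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-distance kernel classification of laryngeal motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdsmonitor)
```

## The problem

Elderly and terminal patients can accumulate phlegm that obstructs the
airway; without prompt suction this leads to hypoxia or asphyxia. A bedside
camera pointed at the throat offers a non-contact way to catch such episodes:
laryngeal motion during a phlegm-stagnation episode is faster and more
irregular than ordinary throat movement, so a monitoring system can watch
the moving throat region, summarise its motion as a speed time series, and
classify that series — raising an alert for the caregiver when it looks like
an episode.

`vdsmonitor` implements that pipeline end to end:

1. **Detection** — three-frame differencing isolates the moving throat
   marker in each frame.
2. **Features** — the selected region is reduced to its centroid; the
   centroid track becomes a sequence of scalar speeds
   $v = l / t$ with $l$ the Euclidean displacement between consecutive
   detections and $t$ the elapsed time.
3. **Classification** — a support vector machine whose kernel

   $$K(x_i, x_j) = \exp\!\left(-\frac{\alpha\,D(x_i,x_j) +
   (1-\alpha)\,V(x_i,x_j)}{2\sigma^2}\right)$$

   mixes a dynamic-time-warping distance $D$ between the two speed
   sequences with a velocity term $V$, the squared difference of their mean
   speeds. $\alpha \in [0,1]$ interpolates between pure sequence-shape
   similarity and pure overall-speed similarity.
4. **Alerting** — a sliding window classifies segments of the stream and
   fires alerts on positive windows.

Because no patient videos are publicly available, the package ships a
synthetic generator that emulates the recording setup, and every empirical
claim below is made on that generator's output.

## Motion detection

For consecutive frames $f_{k-1}, f_k$ the interframe difference mask is
$R(x,y) = \mathbf{1}\{|f_k(x,y) - f_{k-1}(x,y)| \ge T\}$. The magnitude is
taken as an absolute difference: without it, motion that darkens a pixel
would be invisible. Three-frame differencing computes the masks of
$(f_{k-1}, f_k)$ and $(f_k, f_{k+1})$ and returns their pixelwise AND,
attributed to the central frame $k$. The conjunction removes the "image
tail" — the ghost of the previous position that a single difference leaves
behind — at a cost: for a uniformly colored target only the advancing and
receding edges change between frames, so the conjunction keeps thin edge
bands rather than the full target ("holes").

Numerical choices:

* **Threshold** `threshold = 25` on 8-bit frames by default. Too small
  floods the mask with sensor noise, too large fragments the target. An
  automatic per-pair mode (`threshold = "otsu"`, Otsu's method on the
  difference image) is available for footage whose contrast is unknown.
* **Morphology.** The cleaned mask is produced by a closing with a disc of
  radius `morph_radius = 1`, which fills interior holes. An opening is
  available (`open_radius`) but off by default: on uniform targets the
  legitimate detection *is* a thin structure, and a radius-1 opening erases
  it entirely — we observed exactly this on every synthetic clip. Isolated
  noise specks are rejected by the `min_area` filter (default 9 px)
  instead.
* **Region selection.** Components are labeled with 8-connectivity; the
  largest surviving component is the moving target. Area ties break on the
  smallest bounding-box top-left corner, row before column, so selection is
  deterministic.
* **Coordinates** are 0-based with `x` = column and `y` = row, in every
  exported track and region table.

A consequence of the edge-band behavior worth knowing: when the two edge
bands of the blob come out as separate components, the selected region is
*one* of them, offset from the blob center by roughly one semi-axis. The
centroid still translates with the target, so extracted speeds are
unaffected; tests assert that the selected centroid lies on the target
rather than exactly at its center.

## Velocity features

Frames with no surviving region produce a *gap* in the track, not a zero.
Speeds are computed per consecutive *detected* pair using the true frame
gap: $v = l \cdot f_w / \Delta k$ for displacement $l$ over $\Delta k$
frames at frame rate $f_w$. Treating a missed detection as one frame would
inflate the speed across the gap. Speeds are unsigned scalars — direction
carries no information for this task. An optional normalization by frame
height (`normalize_height`) is provided for cross-camera comparisons but is
off by default.

## DTW distance

The cumulative table follows
$D(i,j) = \min\{D(i,j-1), D(i-1,j), D(i-1,j-1)\} + d(a_i, b_j)$
with the pointwise cost $d$ either $|a_i - b_j|$ (default) or squared. Two
boundary rules are implemented:

* `standard` (default): only the virtual origin has cost zero, so the first
  row and column accumulate cost and $D(a,a) = 0$ with a diagonal path.
* `literal`: every cell with $i < 1$ or $j < 1$ is zero. This permits
  cost-free skipping of a prefix of either sequence, which makes
  self-alignment degenerate; it is retained as an option because some
  formulations state it this way.

An Itakura-style step set `extended_b`
$\{(i{-}1,j{-}1), (i{-}2,j{-}1), (i{-}1,j{-}2)\}$ is available for strictly
advancing alignments; under it some cell pairs admit no path at all, and
the distance is then `Inf` with an empty path. Backtracking prefers the
diagonal predecessor, then vertical, then horizontal, so returned paths are
deterministic. No global band constraint is applied.

Correctness is pinned by an independent oracle: exhaustive enumeration of
all monotone warping paths for sequences up to length 6, which the dynamic
program must match exactly (bit-exact on integer-valued inputs).

## The VDS kernel and classifier

The velocity term is $V = (\bar a - \bar b)^2$, the squared difference of
mean speeds — the simplest symmetric scalar that captures "how fast
overall", making $\alpha$ a true shape-vs-speed dial. Two scaling decisions
keep $D$ and $V$ commensurable:

* $D$ is divided by $M + N$ (the two lengths) by default, so the DTW term
  does not grow linearly with clip duration (`normalize_dtw = FALSE`
  recovers the raw cumulative cost).
* With `normalize_inputs = "zscore_over_training"` (default), all speeds
  are centered and scaled by the pooled mean/sd of the training speeds
  before *both* kernel terms, so the default bandwidth $\sigma = 1$ is on a
  meaningful scale. The statistics are stored in the model and re-applied
  to queries.

Defaults $\alpha = 0.5$, $\sigma = 1$, $C = 10$ were chosen as neutral
midpoints on the normalized scale, not tuned per dataset.

Training precomputes the Gram matrix and solves the soft-margin dual with
an interior-point QP solver. A DTW-based kernel is not guaranteed positive
semidefinite; when the Gram matrix has meaningfully negative eigenvalues
they are clipped to zero before solving (spectrum-clip repair, the standard
recipe for indefinite similarity SVMs) and the model records that this
happened. Out-of-sample kernel rows are used as computed. When no repair
was needed the solved model is identical to solving the raw Gram matrix.
After support-vector truncation the dual coefficients are projected back
onto the equality constraint $\sum_i \alpha_i^* y_i = 0$, which holds to
$10^{-6}$ or better in every fitted model. A decision value of exactly zero
maps to class $+1$.

Two baselines are included for comparison, sharing the same dual solver
and normalization so differences reflect the kernels, not the plumbing:

* **DTW-1NN** — each training sequence is a template; a query takes the
  label of the nearest template (first occurrence on ties).
* **Fixed-vector SVM** — sequences are linearly resampled to a common
  length (the median training length) and fed to a plain Gaussian-kernel
  SVM; this is what one must do to use a standard SVM on variable-length
  sequences, and its accuracy cost is what the mixed kernel is meant to
  recover.

## The synthetic generator

`generate_video()` renders a bright anti-aliased elliptical marker (the
"sticker" a caregiver places on the throat; `marker_contrast` lowers
towards the harder no-sticker condition) moving vertically over a flat
background with additive Gaussian pixel noise, clipped and quantized to
8 bits. The trajectory is

$$y_k = c_y + \text{drift}\cdot(k - \tfrac{n-1}{2}) +
A \sin(2\pi f\, k / f_w) + \varepsilon_k + B_k s_k\, (2.5A),$$

with per-frame jitter $\varepsilon_k \sim N(0, \sigma_j^2)$ and, for the
positive class only, Bernoulli(`burst_probability`) one-frame excursions
$B_k$ of magnitude $2.5 \times$ amplitude with random sign $s_k$ — a spike
of displacement emulating an irregular high-velocity episode. The exact
generated centers are returned as ground truth, and generation is
bit-reproducible under the scene seed. Configurations whose trajectory
would carry the blob outside the frame are rejected.

Two named operating points fix the study conditions:

* `separable_profiles()` — positive: $A = 20$ px at 0.8 Hz, bursts with
  probability 0.2; negative: $A = 5$ px at 0.4 Hz; jitter 0.5 px for both.
  Speed distributions do not overlap; any sound classifier should be
  essentially perfect here.
* `overlapping_profiles()` — both classes share $A = 12$ px, 0.5 Hz and
  3 px jitter; the positive class differs only through bursts with
  probability 0.06 per frame. Clips that happen to contain few or no
  bursts are genuinely ambiguous, which is the regime used for comparing
  classifiers.

These kinematic profiles are stand-ins: the real kinematics of phlegm
stagnation are not quantitatively characterised anywhere we know of, so
the parameters are exposed rather than hard-coded, and nothing about them
is clinically validated. What passing tests show is that the *pipeline*
recovers planted class structure of this kind — not that the planted
structure matches real episodes. The generator also does not emulate
illumination changes, camera shake, occlusions, skin-texture variation, or
multiple moving structures; real footage will be harder.

`generate_sequences()` evaluates the same kinematic model but skips
rendering and detection, returning labeled speed sequences directly. The
classifier-scale experiments below use it so that hundreds of training
sets remain cheap; the rendered path is exercised end-to-end at smaller
sizes.

## Experiment sizes and what the package reports

The built-in comparison (`replicate_evaluation()`) uses, per replicate, a
fresh test set of 50 sequences per class shared by every method and
training size, with training sets of 25, 50 and 75 per class and 10
replicates — sizes chosen so the whole sweep runs in a few minutes on one
core while keeping the Monte-Carlo error of a mean detection rate near one
point. Scoring all methods on identical test samples makes the paired
comparison sharper than splitting each training pool. Detection rate is
reported per class (fraction of that class's test samples labeled
correctly), the field's convention for this task.

On these conditions VDS is consistently at or above both baselines and
improves with training-set size; the acceptance script
(`scripts/acceptance.R`) recomputes the numbers from scratch on each run.

## Monitoring and alerting

Continuous footage has no natural "action" boundaries, so `run_monitor()`
cuts the stream into windows of `window_length = 30` frames advancing by
`window_stride = 15` (3 s windows at 10 fps, half overlap — long enough to
contain a burst, short enough to localise it). Windows without at least
two detections are reported as `no_motion`, never classified. Two alert
policies exist: `any_positive` fires on every positive window (the
immediate-alarm reading), while the default `k_of_m` (2 of 3) requires a
second positive among the last three windows, damping single-window flips
at the cost of one window of latency. Alerts carry frame indices and
seconds (`frame / f_w`).

## Known limitations

* The synthetic-to-clinical gap described above: all quantitative claims
  are about planted structure.
* Single-target assumption: the largest moving region wins; a second
  moving object (a hand, a shadow) would be selected if larger.
* The edge-band detection geometry means centroids can sit on the target's
  edge rather than its center; speeds are unaffected but positions should
  not be over-interpreted.
* The literal DTW boundary and the extended step set are provided for
  completeness but are not the defaults; the extended set can return
  infinite distances for incompatible lengths.
* Sex-stratified training (the manifest accepts extra columns) is not
  modeled separately; one model serves all inputs.
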