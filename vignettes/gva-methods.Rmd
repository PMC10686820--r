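---
title: "Methods: estimating CFU concentrations from colony positions in a cone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating CFU concentrations from colony positions in a cone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gva)
```

## The model

A sample is mixed into liquid gel and drawn into a conical vessel — in
the standard protocol a 200 µL pipette tip holding 150 µL of 0.5%
agarose, with the sample diluted 1:100 into the gel. Each viable cell
founds a colony where it happens to sit. Under uniform volumetric
seeding, the probability that a colony lands within axial distance $x$
of the apex is proportional to the volume of the sub-cone of height
$x$, so its axial position has density and distribution

$$\mathrm{pdf}(x) = \frac{3x^2}{h^3}, \qquad
  \mathrm{cdf}(x) = \left(\frac{x}{h}\right)^3, \qquad 0 \le x \le h,$$

where $h$ is the axial length. The same law holds for any axially
symmetric cone or pyramid, because only the $x^2$ scaling of the
cross-section enters; `ConeGeometry` also implements a cylinder
(uniform, $1/h$) and a wedge ($2x/h^2$) for comparing dynamic range.
Radial position carries no information and is ignored by everything
except the image renderer.

Two modelling choices deserve emphasis:

* **Length and volume are independent parameters.** A real pipette tip
  is not an exact cone, and the protocol's $h = 36$ mm, $V = 150$ µL
  are not mutually consistent with one. The axial law uses only $h$;
  the concentration arithmetic uses only $V$. We never derive one from
  the other, and no base radius enters the estimator (the renderer uses
  a nominal 2.7 mm purely for drawing).
* **Colony counts are Poisson.** The number of colonies in a cone at
  in-gel density $\rho$ is $N \sim \mathrm{Poisson}(\rho V)$, and
  positions are i.i.d. from the cubic law. Replicate simulations
  resample $N$; fixing $N$ instead changes the convergence summaries by
  less than their Monte-Carlo noise, so the distinction is immaterial at
  the tolerances we quote.

## The estimator and its counting conventions

With colony positions sorted from the apex, the estimate from the first
$k$ colonies is

$$\widehat{\mathrm{CFU}/\mathrm{mL}}
  = \frac{N}{V \,[\mathrm{cdf}(x_2) - \mathrm{cdf}(x_1)]}
    \times \mathrm{dilution},$$

where $[x_1, x_2)$ is the counted interval and $N$ the number of
colonies inside it. The default **interval** convention takes $x_1$ as
the first colony, $x_2$ as the $k$-th, and counts half-open, so ties at
$x_2$ are excluded and $N = k - 1$ for continuous positions. A second
**tip_anchored** convention anchors the interval at the apex,
$[0, x_k)$, again with $N = k - 1$; in simulation it is slightly less
biased (the interval estimator overshoots by a factor
$(k-1)/(k-2)$ in expectation), but the interval form is the assay's
canonical definition and remains the default. **full_volume** reduces
to the exhaustive count $N/V$ — it is the oracle that any counting
convention must reproduce when $k$ covers the whole cone, and the test
suite asserts that identity exactly.

Degenerate inputs are explicit errors, not silent results: a single
colony cannot span an interval (use `full_volume`); coincident first
and last colonies give a zero-mass interval. An *empty* tip is not an
error — it yields a flagged below-limit-of-detection result carrying
$\mathrm{LOD} = \mathrm{dilution}/V$ (667 CFU/mL for the standard
embedding) as an upper bound rather than a point estimate, mirroring
how dilution floors are reported in practice.

Error is measured multiplicatively throughout:
$\mathrm{factorOff} = |\hat{c} - c|/c + 1 \ge 1$, which treats being
off by a given factor identically across the assay's ~5 decades of
dynamic range. Note its asymmetry: "within a factor of 2" means
$\hat{c} < 2c$, with no lower cutoff other than 0.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `axialLength` | 36 | mm | standard p200 cone |
| `volume` | 150 | µL | gel drawn per tip |
| `dilutionFactor` | 100 | — | 1:100 embedding of the sample |
| `k` | 10 | colonies | ~96% of cones within factor 2; more adds little |
| `mode` | interval | — | the canonical counted-sub-volume definition |

## The simulator

`sampleColonies()` draws $N \sim \mathrm{Poisson}(\rho V)$ and positions
by inverse transform $x = h\,u^{1/3}$, $u \sim U(0,1)$, attaching
radial coordinates uniform over the cross-sectional disc for the
renderer. Each replicate cone runs on an RNG substream derived from the
master seed, so a given replicate is bit-reproducible regardless of how
many replicates are requested, and perturbation experiments can reuse
identical colony sets.

The experiment drivers (`convergenceExperiment()`, `errorSweep()`) never
materialise whole cones: at $10^7$ CFU/mL a cone holds 1.5 million
colonies, of which only the first 10–15 matter. They draw the first $k$
uniform order statistics of $N$ draws directly via the exact recursion
$v_j = 1 - (1 - v_{j-1})\,W^{1/(N-j+1)}$, $W \sim U(0,1)$ — $O(k)$ per
cone and distributionally identical to sorting, which the test suite
verifies against brute force by Kolmogorov–Smirnov comparison and the
exact order-statistic means.

Summaries at $k$ colonies include only replicates holding at least $k$
colonies (a cone cannot contribute to a statistic about its 10th colony
if it has 7), and the conditioning rate is reported as `n_used`.

**What the generator does *not* emulate:** manufacturing asymmetries of
real tips, the meniscus at the gel surface, optical distortion,
colony-size variation, and correlated detection failures (occlusion).
Green simulation tests therefore validate the estimator's mathematics
and the pipeline's plumbing, not the wet-lab assay; the robustness
module exists precisely to probe the failure modes that real data adds
(missed colonies, apex misidentification).

## Robustness experiments

`dropColonies()` removes colonies from the counted set under a policy.
The default is `uniform_random` — which colonies a human misses is not
knowable, so we take the neutral assumption — with `nearest_tip_first`
(worst case: it moves the interval anchor $x_1$) and `farthest_first`
exposed for sensitivity analysis. After removal the estimate is
recomputed from *all* survivors. A subtlety the paired sweep makes
visible: removing colonies while more than $k$ survive can slightly
*improve* the estimate, because the surviving $k$-th colony sits deeper
in the cone and the counted interval carries more mass; the error only
degrades monotonically once the survivor count drops below $k$.

`offsetTip()` shifts every position by a signed offset with $h$ fixed,
clipping to $[0, h]$; positive means the apex was assumed too far from
the colonies. (The alternative reading — shortening $h$ itself —
changes the denominator's normalisation rather than the positions; we
model the positional error, which is the dominant effect of
misreading a tip image, and sweep both signs in `errorSweep()`.) High
densities are hurt more by a fixed offset because their first colonies
sit within a millimetre of the apex, where a 4 mm shift is catastrophic
relative to the interval width.

Replicate technical noise is summarised by `replicateCv()`, the
standard deviation over the mean on the *linear* scale — the
conventional CV definition.

`errorSweep()` is a paired design: the same simulated cones are
re-estimated at every perturbation level, so level-to-level differences
are not washed out by between-cone Poisson noise.

## The ruler

Inverting the expected cumulative count $m \,\mathrm{cdf}(x) = k$ (with
$m = \rho V$ colonies expected in the gel) gives the position where the
$k$-th colony is expected:

$$x_k = h \left(\frac{k}{m}\right)^{1/3}.$$

We interpret "expected $k$-th colony" as this expected-count inversion;
the median-order-statistic alternative (solving
$P(\mathrm{Poisson}(m\,\mathrm{cdf}(x)) \ge k) = \tfrac12$, available
via `method = "order_statistic"`) differs by $O(1/m)$ and the tests
bound the two within 5% in the annotated range. Concentrations whose
expected count falls below $k$ have no $k$-th colony to annotate and
are dropped with a warning naming the minimum annotatable
concentration, $k\,D/V$.

`renderRuler()` writes SVG whose user units *are* millimetres
(`width="70mm" viewBox="0 0 70 60"`), so a 100%-scale print places
ticks with exact physical coordinates against the tip held at the
printed apex crosshair.

## Imaging

`generateTipImage()` rasterises the cone silhouette (optionally tilted)
and stamps each colony as a darkened disc. Colony radius follows
$r = r_0 (1 + \rho/d_0)^{-1/3}$ with $r_0 = 66$ µm and
$d_0 = 10^5$ CFU/mL — a stated rendering rule standing in for the
empirically observed self-limiting colony size whose mechanism is
unknown; it preserves the phenomenology that matters for detection
(colonies shrink with density and rarely merge). A colony rendered
below 2 px radius sets a resolution warning: this is how the
pixel-size-limited dynamic range of a phone camera (13.7 µm pixels)
versus a mirrorless rig (6.6 µm) manifests, and the tests reproduce
exactly that contrast.

`segmentTip()` estimates the axis as the principal axis of the
silhouette mask, identifies the apex end as the narrower one, then
refines both angle and apex by fitting the left/right cone edges in
one-pixel axial bins (with a half-pixel outward correction, since the
extreme pixel centre sits uniformly inside the true edge) and
intersecting them. A trimmed refit discards bins locally widened by
colonies overhanging the silhouette edge. On noise-free renders this
recovers the apex within 2 px and the tilt within 0.5°, verified by
round trip against the renderer's ground truth.

`detectColonies()` inverts the image and searches scale-normalised
Laplacian-of-Gaussian responses over a geometric scale ladder
(σ from ~1.4 px up to a quarter of the base width, steps of √2),
keeping local maxima above a response threshold (default 0.15 in
intensity units, against a colony contrast of ~0.55) that are also
substantially darker than the silhouette median — the intensity gate
that rejects edge artefacts — followed by greedy non-maximum
suppression of overlapping blobs. The five "zoom levels" select the
analysed axial window (the apex-most 1, 1/2, 1/5, 1/10, 1/20 of the
axis; the window fractions between the stated endpoints are a
geometric interpolation of our own choosing), and the narrowest level
caps output at the first 30 colonies. A programmatic curation hook
(`add`/`remove` coordinate lists) mirrors semi-automated use. Physically
overlapping colonies merge into one blob and are counted once — the
exact-recovery guarantee applies to non-overlapping renders, which is
also the regime real colonies occupy thanks to their self-limiting
size.

## Problem sizes and numerical choices

The simulation studies run 1,000 replicate cones per condition
(convergence, missing-colony and offset sweeps at $10^3$–$10^7$ CFU/mL;
dilution series of 8 four-fold steps × 4 replicates), sizes at which
every headline statistic's Monte-Carlo standard error is well inside
the tolerance quoted for it; the whole suite and the acceptance script
each complete in seconds on one CPU. Imaging tests render full-length
p200 tips at 60 µm/px (~620 × 110 px) with proportionally larger
colonies ($r_0$ = 400 µm), preserving every size *ratio* that the
segmentation pipeline depends on while keeping renders small.

Other numerics: the geometry's density normalisation is quadrature-
checked to $10^{-9}$ and cdf/quantile round trips to $10^{-10}$;
position ties are kept in stable order and excluded at $x_2$ by the
half-open rule; unsorted input tables are sorted with a warning, rows
outside $[0, h]$ rejected with a count; all volumes stay in µL until
the final division by mL.

## Known limitations

* No per-tip confidence intervals — replicate CV is the noise currency.
* The imaging loop is validated on synthetic renders only; real tip
  photographs bring glare, meniscus shadows and focus gradients that
  the renderer does not model.
* Colonies are rendered and detected as discs; elongated or merged
  morphologies are out of scope.
* Consumables dish amortisation for the drop assay varies by lab and
  ships unset (NA) rather than guessed.
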