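---
title: "Modelling and measuring visual distortion in CSR: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring visual distortion in CSR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngrid)
```

## The problem

Central serous chorioretinopathy (CSR) lets fluid collect under the retina,
lifting it into a dome-shaped cavity. Photoreceptors riding on the stretched
tissue are displaced from their original positions, so the brain's retinotopic
map no longer matches the stimulus: straight lines look wavy
(metamorphopsia). `ngrid` provides (i) a geometric model of that displacement,
(ii) a generator for straight-line perimetry tests, (iii) a simulator of the
distorted percept and of a patient's good/bad judgements, and (iv) the
reduction of a response log into a heatmap, a scalar distortion percentage
$\eta$, and an estimate of lesion location.

## The cavity model and its radial law

The cavity is idealised as a spherical cap: a sphere of radius $R$ pixels
whose cap has base diameter $D$ ($0 \le D \le 2R$), centred at canvas
position $(x_0, y_0)$. The cap half-angle is

$$\beta = \sin^{-1}\!\left(\frac{D}{2R}\right) \in (0, \pi/2],$$

with $\beta = \pi/2$ the half-sphere special case $D = 2R$.

Sensing points that were uniformly spaced on the flat cap base are assumed to
stay uniformly spaced along the cap's arc after the tissue stretches. A point
originally at flat radius $L_1 \in [0, D/2]$ from the centre therefore sits at
polar angle $\alpha = 2\beta L_1 / D$ on the sphere, whose planar projection
has radius $R\sin\alpha$. The package's *forward map* (stimulus position to
perceived position) is the radial law

$$L_2 = R \sin\!\left(\frac{2\beta L_1}{D}\right), \qquad
  \tan\omega = \frac{y_1 - y_0}{x_1 - x_0} = \frac{y_2 - y_0}{x_2 - x_0},$$

i.e. points move along their ray from the centre ($\omega$ invariant). The
law fixes the centre ($L_1 = 0$) and the support boundary
($L_1 = D/2 \mapsto R\sin\beta = D/2$), is continuous, strictly increasing,
and expansive ($L_2 \ge L_1$, by concavity of $\sin$ on $[0, \beta]$). Every
point at distance $\ge D/2$ from the centre is an exact fixed point: the
model acts only inside the *support disk* of radius $D/2$. For the half
sphere it reduces to $L_2 = R\sin(\pi L_1 / (2R))$, so e.g. $R = 250$,
$L_1 = 250/3$ gives $L_2 = 250\sin(\pi/6) = 125$ exactly.

The inverse map is closed form as well,
$L_1 = \frac{D}{2\beta}\sin^{-1}(L_2/R)$ for $L_2 < D/2$, and round-trips the
forward map to $10^{-9}$ px (tested). The $\sin^{-1}$ argument is clamped to
$[-1, 1]$ within a $10^{-9}$ tolerance window; larger excursions raise an
error rather than being silently absorbed.

Design choices that were genuinely open:

* **Direction of the displacement.** Uniform arc stretching can be read in
  two directions: percepts pushed *outward* ($\sin$, the law above) or pulled
  *inward* (the $\sin^{-1}$ inverse). The two are exact inverses with
  identical displacement magnitudes, so heatmaps, $\eta$, and localisation
  are unaffected; the outward convention is adopted and used consistently.
* **Support radius.** The displacement acts on the cap base disk, radius
  $D/2$ (not $R$): outside the cavity footprint the retina is taken as
  unstretched. For the half sphere the two coincide.
* **Multiple lesions** compose sequentially in list order. For disjoint
  support disks this equals independent application (tested); overlapping
  supports are permitted with a warning, since order then matters and no
  principled composition exists.
* **Coordinates.** Origin at the top-left pixel centre, x rightward,
  y downward, 0-based pixel indices, all lengths in pixels on an
  $m \times n$ canvas (default $800 \times 800$).

### The displacement scale of shallow caps

A consequence worth stating explicitly: for $D \ll 2R$ the cap is shallow and
the stretch is small. At $R = 250$ the supremum of
$|L_2 - L_1|$ over the support is about $0.26$ px for $D = 125$ and
$0.028$ px for $D = 60$ — *sub-pixel* even for the "severe" cavity, whereas
the half sphere ($D = 500$) displaces by up to $\approx 53$ px. Mild CSR
distortion being nearly invisible on a line pattern is thus a prediction of
the geometry, not a numerical artefact. This matters for choosing the
responder threshold below.

## Test patterns

Frames are vector graphics (a restricted SVG 1.1 dialect: `<line>`,
`<polyline>`, `<path>` with absolute `M`/`L`, translate-only transforms; user
units are pixels and the `viewBox` is `0 0 n m`), so a test is independent of
the rendering display. `generate_grid_test(canvas, spacing)` produces the
standard fixture: one full-width horizontal line per offset
$0, s, 2s, \dots$ then one full-height vertical line per offset, giving
$\lceil m/s \rceil + \lceil n/s \rceil$ frames — 160 for the default
$800 \times 800$ canvas at 10 px spacing. (The line spacing, stroke width,
and orientation mix of a clinical test are free design parameters; the 10 px
default makes the localisation resolution one line spacing.) Note that with
offsets anchored at 0 the last line can sit up to $s - 1$ px from the
trailing canvas edge, so pixel coverage is within $s/2$ everywhere except
that residual edge band, where it is still within $s$.

Rasterization (`rasterize_frame`) uses an integer midpoint/DDA traversal with
no anti-aliasing — one pixel per major-axis step, stroke width $w$ drawn as
$w$ parallel traversals — so the frame matrix $F$ is *exactly* binary, which
the collapse step below requires. Geometry outside the canvas is clipped.

## Perception simulation

* **Vector percepts** (`distort_frame`): polyline segments intersecting a
  support disk are resampled so consecutive samples are at most `max_step`
  (default 1 px) apart and pushed through the forward map; segments wholly
  outside every support pass through untouched. At 1 px the chord error of
  the polyline approximation is sub-pixel given the law's bounded curvature.
* **Raster percepts** (`distort_raster`): inverse warping — each output pixel
  is sampled at its inverse-mapped source position (bilinear by default,
  nearest available) — so the percept has no holes, out-of-canvas samples
  clamp to the border, and pixels outside every support disk are copied
  bit-exactly. Locally constant neighbourhoods interpolate bit-exactly, so a
  uniform image is invariant under any lesion.
* **Responses** (`simulate_response`, `run_test`): the synthetic patient
  judges a frame 'bad' (0) when the maximum displacement over the frame's
  sampled pattern points reaches the threshold $\delta$
  (`threshold_delta`). Optional lapse/guess noise can flip or replace the
  deterministic bit; both default to 0, making simulated logs fully
  reproducible, and a seed governs the noise draws otherwise. Timestamps are
  synthetic at $1/r$ intervals from the test's frame rate.

**Choosing $\delta$.** Human metamorphopsia detection has no agreed
psychophysical model, so $\delta$ is a free parameter with two natural
regimes. The default $\delta = 2$ px is a conservative suprathreshold
criterion: on the displacement scale above it is only reached by
near-hemispherical cavities, and shallow caps ($D \le 125$ at $R = 250$)
elicit all-'good' logs — the model's own statement that early CSR is hard to
self-detect on line patterns. For validating the *pipeline* (simulate →
collapse → normalize → estimate) the package's tests use an idealized
observer with $\delta = 0.01$ px, deliberately below the smallest cavity's
displacement scale, so that every stage of the loop is exercised
deterministically. Neither value claims to be a measured human threshold.

## Heatmap reduction

With responses $R_i \in \{0, 1\}$ ($1$ = 'good') and binary frame matrices
$F_i$, the accumulation matrix collects the patterns the patient judged
distorted:

$$C = \sum_{i=1}^{N} (1 - R_i)\, F_i,$$

so each entry of $C$ counts the distorted patterns meeting in that pixel.
Normalization subtracts the matrix mean, clamps negatives to zero, and
divides by the maximum, giving $H \in [0, 1]$ with $\max H = 1$ whenever
anything survives clamping; a z-score's division by the standard deviation
would cancel in the final max-scaling and is omitted. $H$ is invariant under
positive rescaling of $C$, and an all-constant $C$ (including the all-'good'
log) maps to the zero heatmap.

Summary statistics (`distortion_percentage`): the distortion percentage is
$\eta = 100 \cdot N_\text{heat} / M$ with $N_\text{heat}$ the number of
pixels strictly above the heat threshold $\theta$ and $M = m \cdot n$ the
canvas size. $\theta$ defaults to 0 (any positive normalized heat counts);
$\eta$ is non-increasing in $\theta$.

**Lesion localisation** (`estimate_lesion`) returns the $H$-weighted centroid
over heat pixels and an effective radius $\sqrt{N_\text{heat}/\pi}$. For
line-grid tests the localisation threshold $\theta = 0.5$ is the right
choice: after max-scaling, pixels where at least two distorted patterns meet
(the intersections of 'bad' horizontal and 'bad' vertical lines) sit above
$0.5$, while single-line pixels sit near $0.49$; restricting weight to the
intersections places the centroid at the crossing of the two bad-line bands,
i.e. at the lesion. With $\theta = 0$ the full-width bad lines drag the
centroid toward the canvas centre.

**Rendering** (`render_heatmap`): the canvas is tiled into `cell`-pixel
blocks (default 10); each block with positive mean $v$ becomes a circle of
radius $(\text{cell}/2)\,v$ and opacity $v$ at the block centre. `cell = 1`
recovers one circle per pixel, which at $800 \times 800$ is visually and
computationally degenerate — hence the block default.

## What the synthetic closed loop shows — and what it does not

The closed-loop experiments (in the test suite and `scripts/acceptance.R`)
run a grid test (800×800, spacing 10) against a single cap lesion
($R = 250$, $D \in \{60, 125\}$) with the idealized observer, collapse the
log, and estimate the lesion. Under those conditions the centroid lands
within one line spacing (10 px) of the true centre in 18/18 runs over a
3×3 grid of centres (spaced 150 px) for both cavity sizes, and the
distortion percentage orders severity, $\eta(D{=}125) > \eta(D{=}60) >
\eta(D{=}0) = 0$. Problem sizes were chosen so the whole loop runs in
seconds on one CPU: 160 frames, 1 px pattern sampling, $10^6$-point oracle
discretisation, $10^4$-point round-trip checks.

The generator emulates a clean psychophysics session: a deterministic,
attentive observer with stable fixation, exact frame timing, and a lesion
that is exactly a spherical cap. Real data break all of these — fixation
drift, lapses, scotoma (missing regions rather than displaced ones), optical
blur and contrast changes, irregular cavity shapes — so passing the
closed-loop tests demonstrates the *pipeline's* correctness, not clinical
sensitivity or specificity. Clinical $\eta$ values depend on unpublished
patient logs and are not reproducible here; only the qualitative severity
ordering is testable synthetically.

## Numerical choices

* Round-trip tolerance $10^{-9}$ px; arcsin clamp window $10^{-9}$;
  oracle agreement $10^{-3}$ px against a $10^6$-point discrete arc.
* Fixed points (centre, support boundary and beyond) hold *bitwise*, not
  just to tolerance: the maps only touch points strictly inside the support.
* Degenerate inputs: $D = 0$ and the empty lesion list are exact identities
  end to end (identity warps, all-'good' logs, zero $C$, $\eta = 0$).
* Rasterized line pixels are set by rounding the DDA samples; ties follow
  R's `round` (banker's rounding), applied identically on every call, so
  rasterization is deterministic.

## Known limitations

* The cap model displaces but never occludes: scotomata and the
  blur/contrast component of CSR are out of scope.
* The cylindrical-cavity variant is not formulated and not implemented.
* Overlapping lesion supports compose order-dependently.
* The responder threshold $\delta$ is a stand-in, not a fitted psychometric
  function; lapse/guess noise is a two-parameter caricature.
* Heatmap circle radius/opacity proportionality constants are conventions;
  only the per-block means are statistically meaningful.
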