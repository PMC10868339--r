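---
title: "Quantifying biofilm structure from 3D OCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm structure from 3D OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmOCT)
```

## The problem

Optical coherence tomography (OCT) images biofilms at the mesoscale without
staining or sample destruction: back-scattered light is converted to 8-bit
greyscale intensities on a voxel grid, with biomass bright and the bulk
liquid dark. A scan of a biofilm grown on a coupon contains three regions —
the *bottom* (the support, whose surface is the strongest reflector), the
*biofilm* itself, and the *top* (bulk liquid). Structural quantities such as
mean thickness, roughness and porosity require segmenting the volume into
these regions; doing this by hand on volumes of $10^8$ voxels is not
practical, and naive thresholding cannot distinguish attached biomass from
floating flocs or internal pores from open channels.

`biofilmOCT` implements a fully automatic segmentation and characterization
pipeline for such volumes. Throughout, a volume is indexed $(y, z, x)$:
$y$ is the depth (slice) axis, $x$ the horizontal axis within a slice, and
$z$ the vertical axis, increasing *toward* the support. All indices are
1-based.

## Pipeline

### Step 1 — trimming

The biofilm occupies a narrow vertical band; planes far above or below it
carry no information for the structural parameters. `trim_volume(grid,
z_low, z_high)` keeps the inclusive band `[z_low, z_high]`. Bounds are
supplied by the user (a helper, `suggest_trim_bounds()`, proposes a band
from the vertical mean-intensity profile but never applies it silently);
choosing bounds that cut into the biofilm is the one user error the
pipeline cannot detect, although biomass in the uppermost retained plane is
caught later and reported as a trimming problem.

### Step 2 — bottom interface

Within each constant-$y$ slice, the support line is the brightest voxel of
each vertical column; `detect_bottom_slice()` takes the per-column argmax,
breaking ties toward the smallest $z$ (the first strong reflector met from
the liquid side — a deterministic and physically sensible rule). Speckle
and bright flocs occasionally misplace the maximum, so the estimate is
cleaned by *iterated running-median outlier replacement*: entries deviating
from the window-$w$ running median by more than `jump_tol` voxels are
replaced by that median, repeated to a fixpoint (at most 10 passes). The
same operator is applied twice: along $x$ within each slice, and then — the
essential 3D addition — along the depth axis $y$ at each fixed $x$
(`smooth_bottom_depth()`), which flattens spurious points that are locally
plausible within their own slice but inconsistent across slices.

Defaults are `window = 5` and `jump_tol = 5` voxels. A window of 5 is the
smallest that outvotes two adjacent corrupted columns; a tolerance of 5
voxels (≈10 µm at typical OCT resolution) passes genuine support
inclination (which enters the median itself) while rejecting the
order-of-magnitude jumps misdetections produce. Both are exposed because
very rough substrata may need a larger tolerance.

### Step 3 — binarization

The void intensity $i^{\mathrm{void}}$ is the $p$-th percentile (linear
interpolation between order statistics, the `quantile` type-7 convention)
of all intensities in a band of planes above the biofilm — by default the
first 10% of the trimmed volume, pooled over all $y$ and $x$. The threshold
is $i^{\mathrm{thresh}} = i^{\mathrm{void}} \times m$ with $m > 1$, kept as
a real number; a voxel is biomass iff its intensity is *strictly greater*
than the threshold (ties are background, a fixed rule chosen so results are
bit-reproducible). Defaults $p = 95$, $m = 2$ work well on the synthetic
volumes used for validation, but both depend on acquisition settings and
should be tuned per dataset; $i^{\mathrm{void}}$ may also be set manually.

### Steps 4–5 — continuity testing

Biofilm is defined as the biomass forming a *continuous structure attached
to the bottom interface*. Connectivity is 26-neighbour (all voxels within
Chebyshev distance 1), identically for both growth passes. The seed layer
is the set of biomass voxels immediately above the interface,
$(y,\, z^{\mathrm{bot}}(y,x) - 1,\, x)$; `grow_region()` then computes the
breadth-first closure. The engine expands a whole frontier per iteration on
linear indices of a 1-voxel padded copy of the volume: candidate
neighbours are generated in bulk, de-duplicated, and filtered against a
visit state so no voxel is ever processed twice. Floating biomass —
flocs with no voxel path to the support — is never reached and is excluded
from the structure (it remains `unclassified` in the final labelling, the
only label consistent with the region definitions; its count is available
as biomass minus biofilm).

The top region grows from the background voxels of the uppermost plane
through background above the bottom interface. A background voxel adjacent
to at least one biofilm voxel is a *top-interface* voxel; the two
continuity models differ only in how growth treats them:

* **deep** — interface voxels keep expanding, so the top region penetrates
  arbitrarily narrow channels into the structure;
* **shallow** — interface voxels absorb growth (they are marked but never
  expanded from), preserving the external contour.

Interface membership is evaluated against the finalized biofilm in both
modes, so the modes differ in expansion only. One consequence of
26-connectivity deserves note: for a channel one voxel wide, the voxel
directly above the channel mouth is itself diagonally adjacent to the
slab's top face and hence a top-interface voxel. In shallow mode it is
absorbed, so nothing ever expands *into* the mouth — the entire channel,
mouth included, ends up as pore. This is the consistent reading of the
shallow model under 26-connectivity and is what the analytic phantom truths
encode.

`segregate_regions()` completes the labelling: voxels at or below the
bottom interface are `bottom` (the interface row itself belongs to the
bottom region, so thickness counts voxels strictly between the
interfaces); unexplored background above it becomes `biofilm_pore`. The
*biofilm region* is biofilm plus pores; top-interface voxels belong to the
top region.

### Chunked execution

For large volumes the growth passes dominate runtime, so they can be
partitioned: the $(y, x)$ plane is split into `y_bands` × `x_bands`
near-equal chunks ($z$ is never split), each chunk grows independently from
the seeds it contains, chunks are merged along $x$ into bands and growth
continues from region voxels within distance 1 of the previously internal
$x$ edges, then bands are merged along $y$ and growth finishes from the
internal $y$ edges. Because growth is a monotone closure with fixed masks,
each stage runs to a local fixpoint and every region voxel that could still
expand lies within distance 1 of a removed edge, so the staged result
equals the serial closure exactly — the governing contract, asserted
bit-for-bit in the tests for every plan, including a serpentine channel
deliberately crossing every chunk edge. Stages (i) and (ii) may run in
forked worker processes (`parallel::mclapply`); the schedule is
deterministic regardless. Volumes under 64 voxels along $y$ or $x$ fall
back to a single chunk, where scheduling overhead exceeds any gain.

### Step 6 — structural parameters

With $z^{\mathrm{bot}}(y,x)$ the bottom interface and
$z^{\mathrm{top}}(y,x)$ the set of top-interface positions of a column,
thickness is

$$L_F(y,x) = \bigl(z^{\mathrm{bot}}(y,x) - \min z^{\mathrm{top}}(y,x) - 1\bigr)\, vx_{len},$$

the number of voxels strictly between the interfaces times the vertical
voxel length (µm). Columns containing no top-interface voxel and no biofilm
take their top interface immediately above the bottom interface, i.e.
$L_F = 0$; a column with biofilm but no interface voxel is an internal
inconsistency and raises an error. The scalar parameters are

$$\bar{L_F} = \tfrac{1}{N_y N_x}\textstyle\sum_{y,x} L_F, \qquad
R_\alpha = \tfrac{1}{N_y N_x}\textstyle\sum_{y,x} \lvert L_F - \bar{L_F}\rvert, \qquad
R_\alpha^{*} = R_\alpha / \bar{L_F},$$

$$C_p = \frac{\#\{\text{biofilm voxels}\}}{\sum_{y,x} L_F / vx_{len}}, \qquad
\Phi = 1 - \frac{\#\{\text{biofilm voxels}\}}{\#\{\text{biofilm region voxels}\}}.$$

$C_p \in (0, 1]$ measures compaction toward the support (1 = the structure
fills its envelope); $\Phi \in [0, 1)$ is the fraction of background in the
biofilm region and is the only parameter that differs between deep and
shallow modes — shallow excludes more background from the top region, so
$\Phi_{\mathrm{deep}} \le \Phi_{\mathrm{shallow}}$ always. The $L_F /
vx_{len}$ terms are exact integers by construction and no rounding is
applied. Zero-thickness columns contribute 0 to $C_p$'s denominator and are
*not* excluded from any mean. When $\bar{L_F} = 0$ or the region is empty,
the affected parameters are reported as `NA` with a warning rather than as
an arbitrary number. `roi_params()` recomputes everything on a rectangular
$(y, x)$ window, all $z$ retained.

On the phantom family used for validation, both modes also agree exactly on
$\bar{L_F}$, $R_\alpha$, $R_\alpha^{*}$ and $C_p$. This is a property of
geometries whose per-column topmost interface voxel lies on the exterior
contour; a structure with a fully enclosed cavity *above* an overhanging
biofilm ceiling, reachable in deep mode through a channel, could in
principle raise the deep-mode top interface of that column and break the
agreement. No such geometry is generated by the phantom module.

## Phantoms: what they emulate, and what they do not

`make_phantom()` builds volumes whose segmentation is known in closed form:
a dark background, a one-voxel support line at the brightest level (so
argmax detection is exact by construction), and a biomass slab of
intermediate level, optionally carrying enclosed single-voxel pores, a
one-voxel channel leading into an internal cavity, or an inclined support.
All truth counts (biofilm, per-mode region and pore counts, all five
parameters) come from multiplication and list lengths, never from flood
fill, so the phantom truths are an oracle that is independent of the code
they validate. `make_serpentine_phantom()` carves a boustrophedon channel
crossing every chunk boundary, the adversarial case for stitching.
`add_noise()` adds clipped zero-mean Gaussian noise with a fixed seed.

What the phantoms do *not* reproduce: OCT speckle (multiplicative,
spatially correlated), intensity attenuation with depth, partial-volume
voxels at interfaces, curved or rough substrata, and the gradual density
variation of real EPS matrices. Passing the phantom suite therefore
demonstrates that the *algorithms* implement their definitions exactly; it
does not certify parameter accuracy on real scans, which hinges mostly on
the user-tuned threshold ($p$, $m$) and on bottom-interface quality in
noisy data.

Test problem sizes are kept small — volumes of roughly $10^3$–$10^4$ voxels
for exactness checks, $\le 8^3$ for the brute-force closure comparisons
(whose adjacency-matrix oracle is quadratic in voxel count), and a
$20 \times 30 \times 24$ serpentine for stitching — sizes at which every
property asserted is exact, not approximate, and the whole suite runs in
seconds.

## Numerical and design choices

* 1-based $(y, z, x)$ indexing with $z$ increasing toward the support;
  thickness and trim widths are index differences, so no off-by-one
  relative to a 0-based formulation.
* Trim bounds are inclusive on both ends.
* Argmax ties → smallest $z$; threshold ties → background; percentile =
  linear interpolation. All three are conventions fixed for
  reproducibility, not tunables.
* Top growth is seeded from the uppermost plane only; with a clear top
  band (enforced: biomass at $z = 1$ raises an error advising a wider
  trim) this is equivalent to seeding from the whole pre-biofilm band.
* The chunked scheduler communicates only newly labelled voxel indices
  from workers; no shared mutable state, so the result cannot depend on
  worker timing.
* Renders are pure functions of their inputs; re-running a configuration
  writes byte-identical volumes, masks and parameter files.

## Limitations

* The bottom interface is located to whole-voxel precision; no sub-voxel
  refinement or multi-layer substrata.
* Distances are geometric: the vertical voxel length is taken as given and
  no refractive-index correction is applied.
* Trimming is manual by design.
* $p$ and $m$ have no universal defaults; porosity in particular is
  sensitive to thresholding and the deep/shallow choice, and the two modes
  should be read as complementary views rather than competing estimates.
* Floating biomass is excluded from all parameters and reported only as a
  count.
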