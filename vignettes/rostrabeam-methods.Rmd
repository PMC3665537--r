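---
title: "Methods: beam-theory section properties of rostra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beam-theory section properties of rostra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rostrabeam)
```

## The model and its assumptions

The rostrum is idealised as a cantilever beam fixed at the skull: load is
applied at the free (anterior) end, the structure is much longer than wide
or deep, and material properties are uniform along its length. Under these
assumptions, the resistance of a transverse cross-section to bending about
a centroidal axis is proportional to its second moment of area about that
axis, and resistance to torsion about the long axis to the polar moment
J. For a binary bone mask with pixel area ΔA and pixel-centre coordinates
(x, y),

* Ix = Σ (y − ȳ)² ΔA — moment about the mediolateral axis; resists
  dorsoventral bending (biting, pitching),
* Iy = Σ (x − x̄)² ΔA — moment about the dorsoventral axis; resists
  mediolateral bending (sideways sweeps),
* J = Ix + Iy — resists torsion (rolling with gripped prey).

The axes are *anatomical image axes*, not principal axes, because the
dorsoventral/mediolateral dichotomy is the biological question; the product
moment Ixy is deliberately not computed, and no section modulus or
principal-axis rotation is reported. Where compared structures share
material properties, I and J are used directly as stiffness proxies;
`stiffness()` supplies E·I and G·J when moduli matter.

These are proxies, not stress analyses: no finite-element modelling, no
load cases, no failure criteria.

## Numerical conventions

**Pixel-centre point masses.** A pixel contributes its centre coordinate
with weight ΔA; the per-pixel self-moment (the a⁴/12 of a filled square) is
omitted. This is the most literal reading of Σ d²ΔA, and it makes a single
pixel contribute exactly zero moment. Tools that integrate the pixel
rectangle will report very slightly larger moments; on sections of ≥ 200 px
diameter the difference is far below the 1% oracle tolerance used
throughout the tests.

**Rasterization rule.** A pixel belongs to a phantom section iff its centre
lies inside the outer ellipse and outside the cavity — unbiased as
resolution increases, and exactly mirror-symmetric because the in-plane
grid is constructed with an odd column count centred on the mid-sagittal
plane.

**Pooling.** Slices with several bone components (paired bones) are pooled
about the common centroid: the rostrum flexes as one structure. Per-bone
moments about each component's own centroid are available via
`section_properties(per_component = TRUE)`.

**Nearest stored slice.** `extract_profile()` picks the nearest stored
transverse slice for each requested fractional position and records the
position actually used; it refuses silently degenerate requests (two
requested positions landing on one stored slice). There is no interpolation
between slices — the method works from discrete CT slices, and pairing
between specimens is by the *requested* (equivalent) locations.

**J = Ix + Iy is exact** by construction (J is computed as that sum), so
the invariant holds to machine identity on every section, rasterized or
analytic.

## Mask preparation

`threshold_mask()` selects pixels within a closed greyscale window. Real CT
thresholds are scanner- and specimen-specific and remain user input; the
package makes no attempt to choose them. An empty result warns rather than
errors, since on real data it usually means a mis-set window.

`close_section()` fills every background region not connected to the image
border (4-connectivity flood fill from the border). This is the digital
version of removing teeth and levelling their alveoli so each slice is a
closed tube; an open, C-shaped section (e.g. through the external naris) is
left untouched because its "cavity" reaches the border. Whether naris
slices should be treated as open or closed is genuinely undecided in the
comparative literature; both behaviours are reachable (generate the phantom
with or without `naris_gap`; fill or don't), and neither is asserted as
canonical.

`mirror_complete()` reflects the preserved half of a bilaterally symmetric
section about a named sagittal column, unioning at the midline — the
equivalent of cloning an intact maxilla onto the damaged side. The output
canvas is padded so the reflection always fits; moments are translation
invariant, so padding is harmless.

## Slice placement

Two conventions, both "equally spaced", differ in anchoring:

* **Scheme A** (posterior-anchored): position_k = k/count of the measured
  span, k = 1..count. With 25 slices: slice 4 at 16%, slices 2 and 6 at 8%
  and 24%, slice 25 at the posterior end. The first slice is *not* at the
  tip.
* **Scheme B** (tip-anchored): position_k = (k−1)/(count−1) ×
  span_fraction. With 8 slices over 18.5%: first slice at the tip, eighth
  at 18.5% of skull length — the scheme for taxa whose posterior rostrum is
  not preserved.

Whether the published percentage anchors were measured over the rostral
span or total skull length is ambiguous in the source literature; the span
is therefore a parameter (`span_fraction`), not a constant.

## Size correction

With s = L_ref / L, isometry forces area × s² and I, J × s⁴. The default
`"analytic"` mode applies these laws exactly. The `"resample"` mode instead
rescales each slice mask isotropically (nearest-neighbour sampling at pixel
centres, aspect ratio preserved) and recomputes the moments — mimicking
image-space rescaling of scan data. The two modes agree within 2% per slice
at the study's own extreme scale factor s = 86/21.7 ≈ 3.96 provided walls
span ≳ 8 pixels; this cross-validation runs in the acceptance suite.
Analytic is the default because it is exact and resolution-independent;
resample exists to show the image-space shortcut costs only discretization
error.

## The test battery

Slice-matched series of Ix, Iy and J are compared pairwise between taxa.

**Gate.** Each taxon × measure series is screened with Shapiro–Wilk at
α = 0.05 (the standard small-n normality test; the original workflow left
its test unnamed). If *either* member of a pairing fails, the pairing is
tested with the Wilcoxon signed-rank test; if both pass, with a paired
two-tailed t test. The paired t form is used because the series are
slice-matched by design.

**Wilcoxon, normal approximation.** Differences d = a − b; zeros dropped
(classic convention, not Pratt's); |d| ranked with average ranks on ties;
W = rank sum of positive differences; z = |W − m(m+1)/4| /
√(m(m+1)(2m+1)/24), two-sided p from the normal. *No continuity
correction*: back-calculation from the published statistics forces this
convention (with m = 25 and W = 0, 162.5/37.165 = 4.37; a −0.5 term would
give 4.36). This is also why `stats::wilcox.test()` is not used behind the
interface: its `correct = TRUE/FALSE` exact/approximate switching does not
expose precisely this reported-z form. The approximation is accurate at the
m = 8–25 range used here; the acceptance suite checks its empirical type-I
error under an exchangeable null lands in [0.03, 0.07] at nominal 0.05.

**Šidák.** The per-test family-wise threshold is 1 − (1 − α)^(1/n) — the
exact correction from which Bonferroni's α/n is derived, and always less
conservative. The family is *all tests of one treatment in one battery
run*: 9 for three taxa × three measures, 21 for five taxa. This is the only
family definition consistent with a raw p of 0.00685 being significant at
0.05 but not after correction in a family of 9 (threshold 0.005683), and it
is configurable (`family_size`) for batteries that are part of larger
designs. Rows significant raw but not after correction carry an asterisk
flag, mirroring the conventional table markup.

## What the phantoms emulate — and what they don't

`morphotype_preset()` provides three hollow-ellipse morphotypes whose
proportions scale isometrically with skull length:

| preset | emulates | a(z)/L (semi-width) | b(z)/L (semi-height) | wall t(z)/L | span/L |
|---|---|---|---|---|---|
| platyrostral | broad flat (alligator-like) | 0.10 → 0.30 | 0.030 → 0.090 | 0.020 → 0.030 | 0.65 |
| longirostrine | narrow tube (gharial-like) | 0.035 → 0.045 | 0.035 → 0.045 | 0.012 → 0.015 | 0.75 |
| oreinirostral | tall compressed + terminal rosette (spinosaur-like) | 0.040 → 0.070 | 0.080 → 0.160 | 0.018 → 0.025 | 0.60 |

Profiles are piecewise linear between knots (minimal assumption, exactly
integrable per slice); the rosette is a Gaussian multiplicative bulge
(×1.35 at the tip, decaying over 8% of the span); the optional `naris_gap`
removes the dorsal wall over an axial interval, producing open sections.
Proportions were chosen once, from typical adult skull proportions of the
emulated taxa (e.g. a broad crocodilian skull roughly 0.6× as wide as long
at the quadrates versus a tubular snout ~0.08× its skull length wide), and
are not tuned to any test outcome.

These phantoms reproduce the *structure* of the real comparison — taper,
hollowness, bilateral symmetry, aspect-ratio contrasts, fourth-power size
scaling — with analytic ground truth. They do **not** reproduce sutures,
cortical thickness variation, ornamentation, alveoli, scanner noise or
beam hardening, and no tooth modelling is attempted (tooth handling on
real scans is a mask-editing concern: user-supplied exclusion masks plus
`close_section()`). Consequently a green test establishes correctness of
the measurement and inference machinery, and the qualitative
morphotype-ordering result (flat-wide maximal in size-corrected Iy,
tall-narrow in Ix) — it does not establish, and cannot, the absolute
magnitudes of any museum specimen. Those require the original CT scans,
which have no public accessions.

## Degenerate inputs and error policy

* wall thinner than 3 voxels at any axial position → generation error
  naming the position (the rasterized wall would disconnect);
* empty mask → `section_properties()` errors naming the slice; empty
  threshold result → warning only;
* all-zero differences → Wilcoxon error; zero-variance differences →
  paired-t error; constant series → normality-gate error;
* fewer than 5 nonzero differences → Wilcoxon error (the normal
  approximation is meaningless there);
* mismatched slice grids or mixed treatments → battery error.

## Design choices that were genuinely open

* **Image format.** Stacks are numbered PGM slices plus a plain-text
  sidecar. PGM was chosen over TIFF/PNG because it is a standard grayscale
  raster format that can be written and read exactly with no external
  image libraries, and its ASCII variant makes fixtures diffable text.
* **Seeded jitter.** Phantom noise flips only mask-boundary voxels
  (p = 0.15), under a private RNG stream restored afterwards: volumes are
  bit-reproducible per seed and the analytic oracle stays valid to ≤ 1%.
* **Fixture construction for rank configurations.** Reference signed-rank
  statistics are reproduced by *constructing* series whose positive
  differences occupy a prescribed rank set (greedy top-down subset of
  {1..n}, provably exact), then auditing the realised ranks. This tests the
  statistic through the same code path as real data, rather than by
  plugging W into a formula.
* **Supplementary-unit output.** Published supplementary tables use a
  "×10⁻⁷" convention with the power of the metre unit left ambiguous
  (m⁴ presumed for I/J, m² for area); CSVs are SI by default with an
  opt-in `scale_1e7` flag, documented as such.

## Known limitations

Anatomical fidelity of phantoms is deliberately minimal (see above). The
normal-approximation Wilcoxon is used even at m = 8 because that is the
published convention being reproduced; an exact permutation p would differ
(two-sided exact p at m = 8, W = 0 is 0.0078 versus 0.0117 from the
approximation) and is out of scope. The t route assumes slice-matched
pairing; unpaired designs are not supported. Landmark detection is manual:
tip and posterior landmarks are stored metadata, never inferred from the
image.
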