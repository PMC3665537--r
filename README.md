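# rostrabeam

Beam-theory section properties of archosaur rostra.

## The problem

Crocodilians and some theropod dinosaurs evolved strikingly different snout
(rostrum) shapes — broad and flat, narrow and tubular, tall and compressed —
and these shapes are classically read as signatures of feeding ecology.
Treating the rostrum as a cantilever beam makes the comparison quantitative:
at each transverse cross-section, the second moments of area

    Ix = Σ (y − ȳ)² ΔA      (resistance to dorsoventral bending)
    Iy = Σ (x − x̄)² ΔA      (resistance to mediolateral bending)
    J  = Ix + Iy             (polar moment; resistance to torsion)

summarise how bone is distributed about the centroidal (neutral) axes.
Multiplied by the Young's and shear moduli these give flexural (E·Ix, E·Iy)
and torsional (G·J) stiffness; where taxa are assumed to share material
properties, I and J alone carry the comparison. Because I and J scale with
the fourth power of linear size, specimens are compared after isometric
rescaling to a common skull length ("size correction": area × s², I and
J × s⁴ with s = L_ref / L).

`rostrabeam` implements this pipeline end to end for anyone comparing
cross-sectional stiffness proxies along tapering biological beams:

* **Phantoms** (`morphotype_spec`, `generate_rostrum_volume`,
  `analytic_ellipse_properties`): parametric hollow-ellipse rostrum volumes
  — platyrostral (flat-wide), longirostrine (tubular), oreinirostral
  (tall-narrow) — with closed-form section properties as ground truth.
* **Section engine** (`threshold_mask`, `close_section`, `mirror_complete`,
  `section_properties`, `place_slices`, `extract_profile`, `size_correct`):
  greyscale thresholding, filling of enclosed voids (emptied tooth alveoli),
  mirror completion of half-preserved sections, per-slice moments, two slice
  placement schemes (25 posterior-anchored slices over the rostrum; 8
  tip-anchored slices over the anterior 18.5% of skull length), and
  analytic or image-resample size correction.
* **Statistics** (`shapiro_normality`, `wilcoxon_paired_z`, `paired_t`,
  `sidak_alpha`, `pairwise_battery`): slice-matched paired comparisons of
  Ix, Iy, J between taxa. Pairings in which either series fails a
  Shapiro–Wilk normality gate use the Wilcoxon signed-rank test in its
  large-sample form z = |W − m(m+1)/4| / √(m(m+1)(2m+1)/24) (no continuity
  correction); the rest use a paired two-tailed t test. Family-wise
  significance uses the Šidák threshold 1 − (1 − α)^(1/n).
* **Pipeline + CLI** (`run_pipeline`, `rostrabeam_cli`): a declarative
  key-value config drives phantom generation or stack ingestion → profiles
  → size correction → test battery → CSVs, log-scale profile plots and a
  run log. Subcommands: `phantom`, `measure`, `compare`, `run`.

Image stacks are numbered PGM slices (ASCII `P2` or binary `P5`) with a
plain-text sidecar carrying voxel spacing and landmarks.

## Worked example

```r
library(rostrabeam)

# three phantoms of equal skull length, measured on 25 slices
cfg <- run_config(
  specimens = list(
    list(label = "flatwide",   morphotype = "platyrostral",  skull_length = 0.4),
    list(label = "tube",       morphotype = "longirostrine", skull_length = 0.4),
    list(label = "tallnarrow", morphotype = "oreinirostral", skull_length = 0.4)),
  scheme = "A", slice_count = 25, reference_taxon = "tube",
  voxel_size = 0.0015, output_dir = "out", seed = 1)
res <- run_pipeline(cfg)

sapply(res$profiles_corrected, function(p) mean(p$properties$Iy))
#>     flatwide         tube   tallnarrow
#> 1.558745e-05 5.441936e-08 5.052242e-07
head(as.data.frame(res$comparisons$raw)[, c("taxon_1","taxon_2","measure","test","statistic","p")], 3)
#>    taxon_1 taxon_2 measure     test statistic            p
#> 1 flatwide    tube      Ix wilcoxon  4.372373 1.229032e-05
#> 2 flatwide    tube      Iy wilcoxon  4.372373 1.229032e-05
#> 3 flatwide    tube       J wilcoxon  4.372373 1.229032e-05
```

The flat-wide phantom has the largest size-corrected Iy (bone far from the
mid-sagittal axis resists sideways bending) — about 300× the tube — while
the tall-narrow phantom is maximal in Ix. All 25 paired differences share
one sign for these pairs, so the signed-rank statistic reaches its extreme
value, z = 4.37: the fingerprint of two profiles that never cross.

The same statistic from first principles:

```r
ps <- generate_paired_series(25, positive_rank_sum = 0, seed = 1)
wilcoxon_paired_z(ps$values_a, ps$values_b)$statistic  # 4.372373
sidak_alpha(0.05, 9)                                   # 0.005683007
```

## Command line

```sh
inst/scripts/rostrabeam phantom --morphotype longirostrine --skull-length 0.4 \
    --voxel 0.0015 --out stacks --prefix tube
inst/scripts/rostrabeam measure --stack stacks:tube --scheme A --slices 25 \
    --threshold 128:255 --size-correct 0.86 --mode analytic --out tube.csv
inst/scripts/rostrabeam compare --profiles tube.csv,flat.csv --out cmp.csv
inst/scripts/rostrabeam run --config run.cfg
```
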