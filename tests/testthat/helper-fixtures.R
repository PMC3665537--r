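# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# Uniform circular tube: a = b = 0.02 m, wall 0.005 m, spanning 0.3 m of a
# 0.4 m skull (the workhorse phantom for oracle and invariance tests).
tube_spec <- function(naris_gap = NULL) {
  morphotype_spec(
    "tube", skull_length = 0.4, rostral_span = 0.3,
    width_profile = axial_profile(c(0, 1), c(0.02, 0.02)),
    height_profile = axial_profile(c(0, 1), c(0.02, 0.02)),
    wall_thickness_profile = axial_profile(c(0, 1), c(0.005, 0.005)),
    naris_gap = naris_gap)
}

# Linearly tapering solid-ish tube (wall thick enough to stay valid).
taper_spec <- function() {
  morphotype_spec(
    "taper", skull_length = 0.4, rostral_span = 0.3,
    width_profile = axial_profile(c(0, 1), c(0.012, 0.030)),
    height_profile = axial_profile(c(0, 1), c(0.010, 0.024)),
    wall_thickness_profile = axial_profile(c(0, 1), c(0.004, 0.008)))
}

# Rasterized solid disc of radius r_px pixels (pixel size px metres) on an
# odd canvas centred on a pixel, so the mid-sagittal column is exact;
# returns a cross_section.
disc_section <- function(r_px, px = 0.001, margin = 2) {
  n <- 2 * (r_px + margin) + 1
  ctr <- r_px + margin + 1
  x <- matrix(rep(seq_len(n), each = n) - ctr, n, n)
  y <- matrix(rep(seq_len(n), times = n) - ctr, n, n)
  cross_section(x^2 + y^2 <= r_px^2, px)
}

# Rasterized annulus with outer radius ro_px and inner ri_px (pixels).
annulus_section <- function(ro_px, ri_px, px = 0.001, margin = 2) {
  n <- 2 * (ro_px + margin) + 1
  ctr <- ro_px + margin + 1
  x <- matrix(rep(seq_len(n), each = n) - ctr, n, n)
  y <- matrix(rep(seq_len(n), times = n) - ctr, n, n)
  r2 <- x^2 + y^2
  cross_section(r2 <= ro_px^2 & r2 > ri_px^2, px)
}

# Three-profile fixture on a shared 25-slice grid for the battery tests:
# smooth deterministic trends plus seeded noise; optionally one taxon gets
# strongly log-skewed noise so its series fail the normality gate.
battery_profiles <- function(seed, skew_taxon = NULL) {
  set.seed(seed)
  pos <- place_slices("A", 1, 25)
  mk <- function(label, base, slope) {
    noise <- function() {
      if (!is.null(skew_taxon) && label == skew_taxon) {
        0.5 * base * exp(rnorm(25, 0, 1.5))  # heavy right skew
      } else {
        rnorm(25, 0, 0.02 * base)
      }
    }
    props <- data.frame(
      area = base * 0.5 + slope * pos,
      Ix = base + slope * pos + noise(),
      Iy = 2 * base + slope * pos + noise(),
      J = 3 * base + 2 * slope * pos + noise())
    specimen_profile(label, 0.5, pos, props)
  }
  list(mk("alpha", 100, 10), mk("beta", 120, 12), mk("gamma", 90, 8))
}
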