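# Synthetic rostrum phantoms: parametric hollow-ellipse volumes with
# closed-form section properties, standing in for CT scans of real skulls.

#' Piecewise-linear axial profile
#'
#' Builds a function of fractional axial position `z` in \[0, 1\] (0 = rostral
#' tip, 1 = posterior end of the measured span) that interpolates linearly
#' between knots. Used for the outer semi-width a(z), semi-height b(z) and
#' wall thickness t(z) of a phantom.
#'
#' @param z numeric vector of knot positions in \[0, 1\], strictly increasing,
#'   covering 0 and 1.
#' @param value numeric vector of profile values at the knots, all > 0.
#' @return a vectorised function z -> value.
#' @export
#' @examples
#' a <- axial_profile(c(0, 1), c(0.02, 0.05))
#' a(0.5)  # 0.035
axial_profile <- function(z, value) {
  stopifnot(length(z) == length(value), length(z) >= 2)
  if (is.unsorted(z, strictly = TRUE)) {
    stop("profile knot positions must be strictly increasing")
  }
  if (z[1] > 0 || z[length(z)] < 1) {
    stop("profile knots must cover [0, 1]")
  }
  if (any(value <= 0)) stop("profile values must be positive")
  force(z); force(value)
  function(f) stats::approx(z, value, xout = f, rule = 2)$y
}

#' Morphotype specification for a synthetic rostrum
#'
#' Describes a bilaterally symmetric, tapering, hollow-elliptical rostrum.
#' Each transverse section is an elliptical tube with outer semi-axes
#' `width_profile(z)` (mediolateral) and `height_profile(z)` (dorsoventral)
#' and wall thickness `wall_thickness_profile(z)`; the cavity is the
#' concentric ellipse with semi-axes reduced by the wall thickness.
#'
#' @param name taxon/morphotype label.
#' @param skull_length total skull length in metres (rostral tip of the
#'   premaxilla to the posterior edge of the quadrate).
#' @param rostral_span measured span in metres (tip to the orbit-equivalent
#'   landmark); must not exceed `skull_length`.
#' @param width_profile,height_profile,wall_thickness_profile functions of
#'   fractional axial position (see [axial_profile()]) giving the outer
#'   semi-width a(z), outer semi-height b(z) and wall thickness t(z), in m.
#' @param rosette_bulge optional function of z returning a multiplicative
#'   factor (>= 1 near the tip) applied to both semi-axes, emulating a
#'   terminal rosette; `NULL` for none.
#' @param naris_gap optional length-2 numeric, the axial interval (fractions)
#'   over which the dorsal wall is absent, giving an open (C-shaped)
#'   section; `NULL` for none.
#' @return an object of class `morphotype_spec`.
#' @seealso [morphotype_preset()] for ready-made morphotypes.
#' @export
morphotype_spec <- function(name, skull_length, rostral_span,
                            width_profile, height_profile,
                            wall_thickness_profile,
                            rosette_bulge = NULL, naris_gap = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(skull_length), skull_length > 0,
            is.numeric(rostral_span), rostral_span > 0,
            is.function(width_profile), is.function(height_profile),
            is.function(wall_thickness_profile))
  if (rostral_span > skull_length) {
    stop("rostral_span must not exceed skull_length")
  }
  if (!is.null(naris_gap)) {
    stopifnot(length(naris_gap) == 2L, naris_gap[1] < naris_gap[2],
              naris_gap[1] >= 0, naris_gap[2] <= 1)
  }
  spec <- list(name = name, skull_length = skull_length,
               rostral_span = rostral_span,
               width_profile = width_profile,
               height_profile = height_profile,
               wall_thickness_profile = wall_thickness_profile,
               rosette_bulge = rosette_bulge, naris_gap = naris_gap)
  class(spec) <- "morphotype_spec"
  # check invariants on a fine grid
  g <- .spec_geometry(spec, seq(0, 1, length.out = 201))
  if (any(g$a <= 0) || any(g$b <= 0)) stop("semi-axes must be positive")
  if (any(g$t <= 0) || any(g$t > pmin(g$a, g$b) + 1e-12)) {
    stop("wall thickness must satisfy 0 < t(z) <= min(a(z), b(z))")
  }
  spec
}

# Evaluate outer semi-axes and wall thickness (rosette bulge applied) at
# fractional positions f.
.spec_geometry <- function(spec, f) {
  a <- spec$width_profile(f)
  b <- spec$height_profile(f)
  t <- spec$wall_thickness_profile(f)
  if (!is.null(spec$rosette_bulge)) {
    bulge <- spec$rosette_bulge(f)
    a <- a * bulge
    b <- b * bulge
  }
  list(a = a, b = b, t = t)
}

#' Ready-made rostrum morphotypes
#'
#' Three parametric morphotypes spanning the archosaur rostral spectrum:
#' \describe{
#'   \item{`"platyrostral"`}{broad, dorsoventrally flattened snout (alligator
#'     pattern): semi-width much larger than semi-height, strong posterior
#'     widening.}
#'   \item{`"longirostrine"`}{narrow tubular snout (gharial pattern):
#'     near-constant circular section along the span.}
#'   \item{`"oreinirostral"`}{tall, mediolaterally compressed snout with a
#'     terminal rosette bulge (spinosaur pattern): semi-height much larger
#'     than semi-width.}
#' }
#' All dimensions scale isometrically with `skull_length`, so phantoms of
#' different stated lengths are shape-identical up to scale.
#'
#' @param morphotype one of `"platyrostral"`, `"longirostrine"`,
#'   `"oreinirostral"`.
#' @param skull_length skull length in metres.
#' @param name optional label (defaults to the morphotype name).
#' @return a [morphotype_spec()].
#' @export
morphotype_preset <- function(morphotype = c("platyrostral", "longirostrine",
                                             "oreinirostral"),
                              skull_length, name = NULL) {
  morphotype <- match.arg(morphotype)
  if (is.null(name)) name <- morphotype
  L <- skull_length
  spec <- switch(morphotype,
    platyrostral = morphotype_spec(
      name, L, rostral_span = 0.65 * L,
      width_profile  = axial_profile(c(0, 1), c(0.10, 0.30) * L),
      height_profile = axial_profile(c(0, 1), c(0.030, 0.090) * L),
      wall_thickness_profile = axial_profile(c(0, 1), c(0.020, 0.030) * L)),
    longirostrine = morphotype_spec(
      name, L, rostral_span = 0.75 * L,
      width_profile  = axial_profile(c(0, 1), c(0.035, 0.045) * L),
      height_profile = axial_profile(c(0, 1), c(0.035, 0.045) * L),
      wall_thickness_profile = axial_profile(c(0, 1), c(0.012, 0.015) * L)),
    oreinirostral = morphotype_spec(
      name, L, rostral_span = 0.60 * L,
      width_profile  = axial_profile(c(0, 1), c(0.040, 0.070) * L),
      height_profile = axial_profile(c(0, 1), c(0.080, 0.160) * L),
      wall_thickness_profile = axial_profile(c(0, 1), c(0.018, 0.025) * L),
      rosette_bulge = function(f) 1 + 0.35 * exp(-(f / 0.08)^2))
  )
  spec
}

# Run code with a private RNG stream; the global .Random.seed is restored.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Rasterize one hollow-ellipse section on pixel-centre grids xs (mediolateral)
# and ys (dorsoventral, positive = dorsal). A pixel belongs to the section iff
# its centre lies inside the outer ellipse and outside the cavity.
.rasterize_section <- function(xs, ys, a, b, t, open_dorsal = FALSE) {
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  outer_in <- (X / a)^2 + (Y / b)^2 <= 1
  ai <- a - t
  bi <- b - t
  if (ai > 0 && bi > 0) {
    cavity <- (X / ai)^2 + (Y / bi)^2 < 1
  } else {
    cavity <- matrix(FALSE, nrow(outer_in), ncol(outer_in))
  }
  mask <- outer_in & !cavity
  if (open_dorsal) {
    # carve a dorsal channel through the wall so the cavity connects to the
    # image border: the section becomes C-shaped (open)
    mask[Y > 0 & abs(X) < 0.30 * a] <- FALSE
  }
  mask
}

#' Generate a voxelised rostrum phantom
#'
#' Rasterizes a [morphotype_spec()] into a 3-D binary bone mask. Slices are
#' transverse (index 1 = rostral tip); within a slice, rows run dorsoventral
#' (row 1 = dorsal-most) and columns mediolateral. The rasterization rule is
#' pixel-centre membership, and the in-plane grid is chosen symmetric about
#' the mid-sagittal column so generated masks are exactly mirror-symmetric
#' (before optional jitter).
#'
#' @param spec a [morphotype_spec()].
#' @param voxel_size in-plane pixel edge length in metres (dy = dx).
#' @param noise_seed optional integer; when given, boundary voxels are
#'   jittered (flipped with small probability) with a private, reproducible
#'   RNG stream. Absent, the output is fully deterministic.
#' @param slice_thickness axial spacing dz in metres; defaults to
#'   `voxel_size` (isotropic voxels).
#' @return an object of class `voxel_volume`: list with `mask` (logical
#'   array, dim = c(nz, ny, nx)), `voxel_spacing` (c(dz, dy, dx) in m),
#'   `landmarks` (axial indices of the rostral tip and the posterior
#'   reference landmark) and `skull_length`.
#' @details The minimum wall thickness must span at least 3 voxels; thinner
#'   walls raise an error naming the offending axial position, since the
#'   rasterized wall would otherwise disconnect.
#' @export
generate_rostrum_volume <- function(spec, voxel_size, noise_seed = NULL,
                                    slice_thickness = voxel_size) {
  stopifnot(inherits(spec, "morphotype_spec"),
            voxel_size > 0, slice_thickness > 0)
  nz <- max(2L, as.integer(round(spec$rostral_span / slice_thickness)) + 1L)
  f <- seq(0, 1, length.out = nz)
  g <- .spec_geometry(spec, f)
  thin <- which(g$t < 3 * voxel_size)
  if (length(thin)) {
    stop(sprintf(
      "wall thickness %.3g m at axial position %.3f spans < 3 voxels of %.3g m; use a finer voxel_size",
      g$t[thin[1]], f[thin[1]], voxel_size))
  }
  # symmetric pixel-centre grid: odd column count, centre column at x = 0
  amax <- max(g$a)
  bmax <- max(g$b)
  hx <- ceiling(1.05 * amax / voxel_size)
  hy <- ceiling(1.05 * bmax / voxel_size)
  xs <- seq(-hx, hx) * voxel_size
  ys <- seq(hy, -hy) * voxel_size  # row 1 = dorsal-most (y > 0)
  mask <- array(FALSE, dim = c(nz, length(ys), length(xs)))
  in_gap <- if (is.null(spec$naris_gap)) rep(FALSE, nz) else
    (f >= spec$naris_gap[1] & f <= spec$naris_gap[2])
  for (k in seq_len(nz)) {
    mask[k, , ] <- .rasterize_section(xs, ys, g$a[k], g$b[k], g$t[k],
                                      open_dorsal = in_gap[k])
  }
  if (!is.null(noise_seed)) {
    mask <- .with_seed(as.integer(noise_seed), {
      for (k in seq_len(nz)) {
        mask[k, , ] <- .jitter_boundary(mask[k, , ])
      }
      mask
    })
  }
  vol <- list(mask = mask,
              voxel_spacing = c(slice_thickness, voxel_size, voxel_size),
              landmarks = c(tip = 1L, posterior = nz),
              skull_length = spec$skull_length,
              name = spec$name)
  class(vol) <- "voxel_volume"
  vol
}

# Flip boundary pixels of a 2-D mask with probability 0.15 each. The boundary
# is the set of foreground pixels 4-adjacent to background plus background
# pixels 4-adjacent to foreground; interior bone and far-field air are
# untouched.
.jitter_boundary <- function(m) {
  nb <- .neighbour_count(m)
  fg_edge <- m & nb < 4L
  bg_edge <- !m & .neighbour_count(!m) < 4L & nb > 0L
  edge <- which(fg_edge | bg_edge)
  if (!length(edge)) return(m)
  flip <- edge[stats::runif(length(edge)) < 0.15]
  m[flip] <- !m[flip]
  m
}

# Number of TRUE 4-neighbours for each cell (borders count missing
# neighbours as FALSE).
.neighbour_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  n <- matrix(0L, nr, nc)
  n[-1, ]  <- n[-1, ]  + m[-nr, ]
  n[-nr, ] <- n[-nr, ] + m[-1, ]
  n[, -1]  <- n[, -1]  + m[, -nc]
  n[, -nc] <- n[, -nc] + m[, -1]
  n
}

#' Closed-form section properties of a (hollow) ellipse
#'
#' Analytic oracle for rasterized sections. For a solid ellipse with
#' semi-width a (mediolateral) and semi-height b (dorsoventral):
#' Ix = pi a b^3 / 4 (about the centroidal mediolateral axis, resisting
#' dorsoventral bending), Iy = pi a^3 b / 4, area = pi a b. A hollow section
#' subtracts the concentric inner ellipse with semi-axes (a - t, b - t).
#' J = Ix + Iy always.
#'
#' @param a,b outer semi-axes in metres.
#' @param t wall thickness in metres; `0` means solid.
#' @return a one-row data.frame with columns `area`, `cx`, `cy`, `Ix`, `Iy`,
#'   `J` (SI units; centroid at the origin).
#' @export
#' @examples
#' analytic_ellipse_properties(0.02, 0.02, 0)      # solid circle r = 2 cm
#' analytic_ellipse_properties(0.02, 0.02, 0.005)  # tube, 5 mm wall
analytic_ellipse_properties <- function(a, b, t = 0) {
  stopifnot(a > 0, b > 0)
  if (t < 0 || t > min(a, b)) {
    stop("wall thickness must satisfy 0 <= t <= min(a, b)")
  }
  solid <- function(a, b) {
    c(area = pi * a * b, Ix = pi * a * b^3 / 4, Iy = pi * a^3 * b / 4)
  }
  p <- solid(a, b)
  if (t > 0 && t < min(a, b)) p <- p - solid(a - t, b - t)
  data.frame(area = p[["area"]], cx = 0, cy = 0,
             Ix = p[["Ix"]], Iy = p[["Iy"]], J = p[["Ix"]] + p[["Iy"]])
}

#' Construct a paired series with a prescribed signed-rank configuration
#'
#' Builds two slice-matched measurement series whose pairwise differences
#' are all nonzero with distinct magnitudes and whose positive differences
#' occupy ranks (by absolute magnitude) summing exactly to
#' `positive_rank_sum`. This pins the Wilcoxon signed-rank statistic W of
#' the pair by construction, which is how the printed test statistics of
#' the worked examples are reproduced without the original CT data.
#'
#' @param n number of pairs.
#' @param positive_rank_sum requested rank sum W of the positive
#'   differences; must lie in \[0, n(n+1)/2\].
#' @param seed integer seed; output is reproducible.
#' @return an object of class `paired_series`: list with `values_a`,
#'   `values_b` and `pairing_key` (slice positions in (0, 1\]).
#' @export
generate_paired_series <- function(n, positive_rank_sum, seed) {
  stopifnot(n >= 1)
  wmax <- n * (n + 1) / 2
  if (positive_rank_sum < 0 || positive_rank_sum > wmax ||
      positive_rank_sum != round(positive_rank_sum)) {
    stop(sprintf("positive_rank_sum must be an integer in [0, %d]", wmax))
  }
  # greedy top-down subset of {1..n} with the exact requested sum
  remaining <- positive_rank_sum
  pos_ranks <- integer(0)
  for (r in n:1) {
    if (remaining >= r) {
      pos_ranks <- c(pos_ranks, r)
      remaining <- remaining - r
    }
  }
  stopifnot(remaining == 0)
  .with_seed(as.integer(seed), {
    # strictly increasing distinct magnitudes; rank i has magnitude mags[i]
    mags <- cumsum(stats::runif(n, 0.5, 1.5))
    signs <- ifelse(seq_len(n) %in% pos_ranks, 1, -1)
    d <- signs * mags
    d <- d[sample.int(n)]          # scatter ranks across slice positions
    b <- 100 + cumsum(stats::runif(n, -1, 1))  # smooth-ish baseline
    out <- list(values_a = b + d, values_b = b,
                pairing_key = seq_len(n) / n)
    class(out) <- "paired_series"
    out
  })
}
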