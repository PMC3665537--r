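# Per-slice section geometry: mask preparation and the second-moment
# computation at the core of the beam-theory analysis.

#' Cross-section container
#'
#' A single transverse binary mask with physical pixel size. Rows run
#' dorsoventral (y), columns mediolateral (x). The mask may contain several
#' connected components (paired bones in one slice).
#'
#' @param mask logical matrix.
#' @param pixel_size numeric length-2 `c(dy, dx)` in metres, or a scalar for
#'   square pixels.
#' @param axial_position fraction of the measured span (0 = rostral tip).
#' @return an object of class `cross_section`.
#' @export
cross_section <- function(mask, pixel_size, axial_position = NA_real_) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (length(pixel_size) == 1L) pixel_size <- c(pixel_size, pixel_size)
  stopifnot(length(pixel_size) == 2L, all(pixel_size > 0))
  s <- list(mask = mask, pixel_size = as.numeric(pixel_size),
            axial_position = axial_position)
  class(s) <- "cross_section"
  s
}

#' Threshold a grayscale slice to a bone mask
#'
#' Pixels whose intensity lies in the closed window `[low, high]` become
#' foreground — the digital equivalent of selecting bone by a user-defined
#' greyscale window in a CT slice.
#'
#' @param grayscale_slice numeric/integer matrix of intensities.
#' @param low,high window bounds, `low <= high`.
#' @param pixel_size,axial_position passed to [cross_section()].
#' @return a [cross_section()]. An empty result is allowed and triggers a
#'   warning (a wrong window on real data), not an error.
#' @export
threshold_mask <- function(grayscale_slice, low, high,
                           pixel_size, axial_position = NA_real_) {
  stopifnot(is.matrix(grayscale_slice), low <= high)
  mask <- grayscale_slice >= low & grayscale_slice <= high
  if (!any(mask)) {
    warning(sprintf("threshold window [%g, %g] selected no pixels", low, high))
  }
  cross_section(mask, pixel_size, axial_position)
}

# Flood fill over FALSE cells of `m` starting from all border FALSE cells;
# returns a logical matrix marking background reachable from the border
# (4-connectivity), implemented as an iterative frontier expansion.
.border_background <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  reach <- matrix(FALSE, nr, nc)
  open <- !m
  reach[1, ]  <- open[1, ]
  reach[nr, ] <- open[nr, ]
  reach[, 1]  <- open[, 1]
  reach[, nc] <- open[, nc]
  repeat {
    grown <- reach
    grown[-1, ]  <- grown[-1, ]  | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1, ]
    grown[, -1]  <- grown[, -1]  | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1]
    grown <- grown & open
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

#' Fill enclosed voids to form a closed section
#'
#' Every background region not connected to the image border is filled with
#' foreground; border-connected background (including the opening of a
#' C-shaped section) is untouched. This is the standard preparation step for
#' second-moment analysis of skull slices: emptied tooth alveoli and other
#' enclosed voids are levelled so the section behaves as a closed tube.
#'
#' @param section a [cross_section()].
#' @return a [cross_section()] with holes filled.
#' @export
close_section <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  filled <- !.border_background(section$mask)
  cross_section(filled, section$pixel_size, section$axial_position)
}

#' Mirror-complete a hemirostrum
#'
#' Restores a bilaterally symmetric section from one preserved half by
#' reflecting it about the mid-sagittal column — the digital analogue of
#' cloning an intact maxilla onto the damaged side. The retained half
#' (including the sagittal column itself) is reflected; overlap at the
#' midline is resolved by union, and the canvas is padded so the reflection
#' always fits. The result is exactly mirror-symmetric about the sagittal
#' column.
#'
#' @param section a [cross_section()].
#' @param sagittal_column column index of the mid-sagittal plane.
#' @param keep_side `"left"` (columns <= sagittal_column) or `"right"`.
#' @return a [cross_section()].
#' @export
mirror_complete <- function(section, sagittal_column,
                            keep_side = c("left", "right")) {
  stopifnot(inherits(section, "cross_section"))
  keep_side <- match.arg(keep_side)
  m <- section$mask
  nc <- ncol(m)
  if (sagittal_column < 1 || sagittal_column > nc) {
    stop("sagittal_column outside the image")
  }
  kept_cols <- if (keep_side == "left") seq_len(sagittal_column) else
    sagittal_column:nc
  half <- m[, kept_cols, drop = FALSE]
  if (!any(half)) stop("retained half contains no foreground")
  w <- length(kept_cols)           # width including the midline column
  out <- matrix(FALSE, nrow(m), 2L * w - 1L)
  if (keep_side == "left") {
    out[, seq_len(w)] <- half
    out[, w:(2L * w - 1L)] <- out[, w:(2L * w - 1L)] | half[, w:1]
  } else {
    out[, w:(2L * w - 1L)] <- half
    out[, seq_len(w)] <- out[, seq_len(w)] | half[, w:1]
  }
  cross_section(out, section$pixel_size, section$axial_position)
}

# Label 4-connected foreground components; returns an integer matrix
# (0 = background).
.label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  todo <- m
  nr <- nrow(m); nc <- ncol(m)
  while (any(todo)) {
    nxt <- nxt + 1L
    seed <- which(todo)[1]
    comp <- matrix(FALSE, nr, nc)
    comp[seed] <- TRUE
    repeat {
      grown <- comp
      grown[-1, ]  <- grown[-1, ]  | comp[-nr, ]
      grown[-nr, ] <- grown[-nr, ] | comp[-1, ]
      grown[, -1]  <- grown[, -1]  | comp[, -nc]
      grown[, -nc] <- grown[, -nc] | comp[, -1]
      grown <- grown & todo
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- nxt
    todo <- todo & !comp
  }
  lab
}

# Moments for a set of pixel-centre coordinates (point-mass convention).
.moments_from_pixels <- function(xs, ys, dA) {
  n <- length(xs)
  cx <- mean(xs); cy <- mean(ys)
  Ix <- sum((ys - cy)^2) * dA
  Iy <- sum((xs - cx)^2) * dA
  data.frame(area = n * dA, cx = cx, cy = cy, Ix = Ix, Iy = Iy, J = Ix + Iy)
}

#' Section properties of a binary cross-section
#'
#' Computes area, centroid and the second moments of area about the
#' centroidal anatomical axes by direct summation over pixel centres:
#' Ix = sum (y_i - ybar)^2 dA (resistance to dorsoventral bending),
#' Iy = sum (x_i - xbar)^2 dA (resistance to mediolateral bending),
#' J = Ix + Iy (resistance to torsion). Pixels are treated as point masses
#' at their centres (no per-pixel self-moment), and all connected components
#' are pooled about their common centroid — the rostrum flexes as a unit.
#' Anatomical image axes are used, not principal axes, because the
#' dorsoventral/mediolateral dichotomy is the quantity of interest; the
#' product moment Ixy is not computed.
#'
#' @param section a [cross_section()] with a nonempty mask.
#' @param per_component if `TRUE`, additionally return per-connected-
#'   component properties (each about its own centroid) as attribute
#'   `"components"`.
#' @return a one-row data.frame with columns `area` (m^2), `cx`, `cy` (m),
#'   `Ix`, `Iy`, `J` (m^4).
#' @export
section_properties <- function(section, per_component = FALSE) {
  stopifnot(inherits(section, "cross_section"))
  m <- section$mask
  if (!any(m)) {
    stop(sprintf("empty mask (axial position %s): no section properties",
                 format(section$axial_position)))
  }
  dy <- section$pixel_size[1]; dx <- section$pixel_size[2]
  dA <- dy * dx
  idx <- which(m, arr.ind = TRUE)
  xs <- (idx[, 2] - 0.5) * dx
  ys <- (idx[, 1] - 0.5) * dy
  out <- .moments_from_pixels(xs, ys, dA)
  if (per_component) {
    lab <- .label_components(m)
    comps <- lapply(seq_len(max(lab)), function(k) {
      ik <- which(lab == k, arr.ind = TRUE)
      .moments_from_pixels((ik[, 2] - 0.5) * dx, (ik[, 1] - 0.5) * dy, dA)
    })
    attr(out, "components") <- do.call(rbind, comps)
  }
  out
}

#' Flexural and torsional stiffness
#'
#' Multiplies the geometric moments by material moduli: flexural stiffness
#' E\*Ix and E\*Iy, torsional stiffness G\*J. Where specimens are assumed to
#' share material properties, the moments alone carry the comparison and
#' E = G = 1 may be used.
#'
#' @param props one-row data.frame from [section_properties()] (or
#'   [analytic_ellipse_properties()]).
#' @param youngs_modulus E in Pa.
#' @param shear_modulus G in Pa.
#' @return named numeric: `flexural_x`, `flexural_y`, `torsional` (N m^2).
#' @export
stiffness <- function(props, youngs_modulus, shear_modulus) {
  stopifnot(youngs_modulus > 0, shear_modulus > 0)
  c(flexural_x = youngs_modulus * props$Ix,
    flexural_y = youngs_modulus * props$Iy,
    torsional  = shear_modulus * props$J)
}

#' Slice placement schemes
#'
#' Two conventions for placing `count` equally spaced transverse slices:
#' \describe{
#'   \item{Scheme A (posterior-anchored)}{position_k = k/count of the
#'     measured span, k = 1..count. With 25 slices, slice 4 sits at 16% and
#'     slices 2 and 6 at 8% and 24% — the crocodilian whole-rostrum scheme.}
#'   \item{Scheme B (tip-anchored)}{position_k = (k-1)/(count-1) \*
#'     span_fraction: the first slice is at the rostral tip and the last at
#'     `span_fraction` of the span. With 8 slices and span 0.185 this is the
#'     anterior-rostrum scheme used for taxa with incomplete posterior
#'     material.}
#' }
#'
#' @param scheme `"A"` or `"B"`.
#' @param span_fraction portion of the measured span covered (0, 1\];
#'   scheme A conventionally uses 1.
#' @param count number of slices, >= 2.
#' @return numeric vector of fractional positions.
#' @export
#' @examples
#' place_slices("A", 1, 25)[4]        # 0.16
#' place_slices("B", 0.185, 8)        # 0 ... 0.185
place_slices <- function(scheme = c("A", "B"), span_fraction = 1, count) {
  scheme <- match.arg(scheme)
  stopifnot(count >= 2, span_fraction > 0, span_fraction <= 1)
  if (scheme == "A") {
    seq_len(count) / count * span_fraction
  } else {
    (seq_len(count) - 1) / (count - 1) * span_fraction
  }
}

#' Extract a section-property profile from a volume
#'
#' For each requested fractional position along the measured span (between
#' the volume's tip and posterior landmarks), selects the nearest stored
#' transverse slice (no interpolation — the analysis works from discrete CT
#' slices), applies the configured preparation (hole filling, optionally
#' mirror completion), and computes [section_properties()].
#'
#' @param volume a `voxel_volume` (see [generate_rostrum_volume()] or
#'   [read_volume()]).
#' @param positions fractional positions from [place_slices()].
#' @param close if `TRUE` (default) apply [close_section()] per slice.
#' @param mirror `NULL`, or `list(column =, side =)` to apply
#'   [mirror_complete()] before measurement.
#' @param taxon label for the profile; defaults to the volume's name.
#' @param keep_sections keep the prepared masks in the profile (needed for
#'   resample-mode size correction). Default `TRUE`.
#' @return an object of class `specimen_profile`: list with `taxon`,
#'   `skull_length`, `slice_positions` (actual fractions used),
#'   `slice_index`, `properties` (data.frame, one row per slice),
#'   `treatment` (`"raw"`), and `sections` (list of [cross_section()] or
#'   `NULL`).
#' @export
extract_profile <- function(volume, positions, close = TRUE, mirror = NULL,
                            taxon = NULL, keep_sections = TRUE) {
  stopifnot(inherits(volume, "voxel_volume"))
  lm <- volume$landmarks
  stopifnot(all(c("tip", "posterior") %in% names(lm)))
  i0 <- lm[["tip"]]; i1 <- lm[["posterior"]]
  idx <- as.integer(round(i0 + positions * (i1 - i0)))
  if (anyDuplicated(idx)) {
    stop("requested positions map to duplicate stored slices; ",
         "the stack is too coarse for this slice scheme (use a finer stack)")
  }
  dy <- volume$voxel_spacing[2]; dx <- volume$voxel_spacing[3]
  actual <- (idx - i0) / (i1 - i0)
  sections <- vector("list", length(idx))
  props <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    s <- cross_section(volume$mask[idx[k], , ], c(dy, dx), actual[k])
    if (!is.null(mirror)) {
      s <- mirror_complete(s, mirror$column, mirror$side)
    }
    if (close) s <- close_section(s)
    sections[[k]] <- s
    props[[k]] <- section_properties(s)
  }
  profile <- list(taxon = if (is.null(taxon)) volume$name else taxon,
                  skull_length = volume$skull_length,
                  positions_requested = positions,
                  slice_positions = actual,
                  slice_index = seq_along(idx),
                  properties = do.call(rbind, props),
                  treatment = "raw",
                  sections = if (keep_sections) sections else NULL)
  class(profile) <- "specimen_profile"
  profile
}

#' Construct a specimen profile from measured values
#'
#' Lightweight constructor for statistics-only workflows (e.g. series read
#' from CSV or injected test fixtures) where no image stack is involved.
#'
#' @param taxon label.
#' @param skull_length skull length in metres.
#' @param slice_positions strictly increasing fractions in \[0, 1\].
#' @param properties data.frame with (at least) columns `Ix`, `Iy`, `J`.
#' @param treatment `"raw"` or `"size_corrected"`.
#' @return a `specimen_profile`.
#' @export
specimen_profile <- function(taxon, skull_length, slice_positions,
                             properties, treatment = "raw") {
  stopifnot(nrow(properties) == length(slice_positions),
            !is.unsorted(slice_positions, strictly = TRUE))
  p <- list(taxon = taxon, skull_length = skull_length,
            positions_requested = slice_positions,
            slice_positions = slice_positions,
            slice_index = seq_along(slice_positions),
            properties = properties, treatment = treatment,
            sections = NULL)
  class(p) <- "specimen_profile"
  p
}

# Nearest-neighbour isotropic rescale of a mask by factor s, keeping the
# pixel size: the new mask samples the original at scaled-back pixel centres.
.rescale_mask <- function(m, s) {
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- max(1L, as.integer(round(nr * s)))
  nc2 <- max(1L, as.integer(round(nc * s)))
  ri <- pmin(nr, pmax(1L, ceiling((seq_len(nr2) - 0.5) / s)))
  ci <- pmin(nc, pmax(1L, ceiling((seq_len(nc2) - 0.5) / s)))
  m[ri, ci, drop = FALSE]
}

#' Size-correct a profile to a reference skull length
#'
#' Rescales a specimen isometrically so that all taxa are compared at a
#' common skull length and shape, not size, drives the comparison. With
#' scale factor s = reference_length / skull_length, areas scale by s^2 and
#' second moments by s^4 (slice aspect ratio preserved).
#'
#' Two modes:
#' \describe{
#'   \item{`"analytic"`}{applies the exact scaling laws to the measured
#'     properties (default; no resampling error).}
#'   \item{`"resample"`}{rescales each stored slice mask isotropically by s
#'     (nearest-neighbour at pixel centres) and recomputes the properties —
#'     mimics image-space rescaling of the scan data and cross-validates the
#'     analytic law.}
#' }
#'
#' @param profile a `specimen_profile` with `treatment == "raw"`.
#' @param reference_length reference skull length in metres.
#' @param mode `"analytic"` or `"resample"`.
#' @return a `specimen_profile` with `treatment == "size_corrected"`.
#' @export
size_correct <- function(profile, reference_length,
                         mode = c("analytic", "resample")) {
  stopifnot(inherits(profile, "specimen_profile"))
  mode <- match.arg(mode)
  if (!is.numeric(reference_length) || reference_length <= 0 ||
      is.null(profile$skull_length) || profile$skull_length <= 0) {
    stop("skull_length and reference_length must be positive")
  }
  s <- reference_length / profile$skull_length
  out <- profile
  if (mode == "analytic") {
    p <- profile$properties
    p$area <- p$area * s^2
    for (cl in intersect(c("cx", "cy"), names(p))) p[[cl]] <- p[[cl]] * s
    for (cl in c("Ix", "Iy", "J")) p[[cl]] <- p[[cl]] * s^4
    out$properties <- p
  } else {
    if (is.null(profile$sections)) {
      stop("resample mode needs the stored slice masks ",
           "(extract_profile(keep_sections = TRUE))")
    }
    props <- lapply(profile$sections, function(sec) {
      m2 <- .rescale_mask(sec$mask, s)
      section_properties(cross_section(m2, sec$pixel_size,
                                       sec$axial_position))
    })
    out$properties <- do.call(rbind, props)
    out$sections <- NULL
  }
  out$skull_length <- reference_length
  out$treatment <- "size_corrected"
  out
}
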