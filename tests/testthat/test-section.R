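# Section engine: thresholding, preparation operators, moments, slice
# placement, profiles, size correction.

test_that("threshold_mask windows intensities and warns on empty result", {
  img <- matrix(c(0, 50, 128, 255), 2, 2)
  s <- threshold_mask(img, 128, 255, 0.001)
  expect_identical(s$mask, img >= 128)
  expect_identical(threshold_mask(img, 50, 50, 0.001)$mask, img == 50)
  expect_warning(threshold_mask(img, 300, 400, 0.001), "no pixels")
  # round-trip: phantom rendered at 255 on 0 recovers the generated mask
  vol <- generate_rostrum_volume(tube_spec(), 0.001, slice_thickness = 0.02)
  img <- ifelse(vol$mask[3, , ], 255, 0)
  expect_identical(threshold_mask(img, 128, 255, 0.001)$mask, vol$mask[3, , ])
})

test_that("close_section fills enclosed voids only", {
  ann <- annulus_section(20, 12)
  disc <- disc_section(20)
  expect_identical(close_section(ann)$mask, disc$mask)
  # C-shaped: cut a channel from the cavity to the border -> unchanged
  cmask <- ann$mask
  cmask[1:nrow(cmask) <= nrow(cmask) / 2, 21:23] <- FALSE
  copen <- cross_section(cmask, 0.001)
  expect_identical(close_section(copen)$mask, cmask)
  # two disjoint rings -> two solid discs (per-component fill)
  two <- cbind(ann$mask, matrix(FALSE, nrow(ann$mask), 3), ann$mask)
  twofilled <- cbind(disc$mask, matrix(FALSE, nrow(disc$mask), 3), disc$mask)
  expect_identical(close_section(cross_section(two, 0.001))$mask, twofilled)
})

test_that("mirror_complete restores symmetric sections", {
  disc <- disc_section(15)
  ctr <- as.integer((ncol(disc$mask) + 1) / 2)
  # idempotence on an already-symmetric input (up to canvas padding)
  sym <- mirror_complete(disc, ctr, "left")
  expect_equal(section_properties(sym), section_properties(disc))
  # half-disc with midline at the flat edge -> full disc properties
  half <- disc$mask
  half[, (ctr + 1):ncol(half)] <- FALSE
  completed <- mirror_complete(cross_section(half, 0.001), ctr, "left")
  expect_identical(completed$mask, completed$mask[, ncol(completed$mask):1])
  expect_equal(section_properties(completed)$Iy,
               section_properties(disc)$Iy, tolerance = 1e-12)
  expect_equal(section_properties(completed)$area,
               section_properties(disc)$area)
  # keep_side = "right" mirrors the other way to the same result
  halfr <- disc$mask
  halfr[, 1:(ctr - 1)] <- FALSE
  completedr <- mirror_complete(cross_section(halfr, 0.001), ctr, "right")
  expect_equal(section_properties(completedr)$Iy,
               section_properties(disc)$Iy)
  # errors
  expect_error(mirror_complete(disc, 999, "left"), "outside")
  empty_half <- cross_section(
    cbind(matrix(FALSE, 10, 5), matrix(TRUE, 10, 5)), 0.001)
  expect_error(mirror_complete(empty_half, 2, "left"), "no foreground")
})

test_that("section_properties implements the summation definition", {
  # single pixel: point-mass convention gives zero moments
  one <- cross_section(matrix(TRUE, 1, 1), 0.002)
  p1 <- section_properties(one)
  expect_identical(c(p1$Ix, p1$Iy, p1$J), c(0, 0, 0))
  expect_equal(p1$area, 4e-6)
  expect_equal(c(p1$cx, p1$cy), c(0.001, 0.001))

  # small hand-computable mask: 1x3 horizontal bar, unit mm pixels
  bar <- cross_section(matrix(TRUE, 1, 3), 0.001)
  pb <- section_properties(bar)
  expect_equal(pb$Ix, 0)
  expect_equal(pb$Iy, (1e-3^2 + 0 + 1e-3^2) * 1e-6)  # sum d^2 * dA
  expect_equal(pb$J, pb$Iy)

  # rasterized solid circle r = 200 px at 1 mm/px vs closed form
  disc <- disc_section(200)
  pd <- section_properties(disc)
  truth <- analytic_ellipse_properties(0.2, 0.2, 0)
  expect_lt(abs(pd$Ix / truth$Ix - 1), 0.01)
  expect_lt(abs(pd$Iy / truth$Iy - 1), 0.01)
  expect_lt(abs(pd$area / truth$area - 1), 0.01)

  expect_error(section_properties(cross_section(matrix(FALSE, 3, 3), 1)),
               "empty mask")
})

test_that("moment invariants: J identity, translation, rotation, pooling", {
  set.seed(11)
  for (rep in 1:10) {
    m <- matrix(runif(40 * 30) < 0.3, 40, 30)
    if (!any(m)) next
    s <- cross_section(m, c(0.002, 0.001))
    p <- section_properties(s)
    # J = Ix + Iy exactly
    expect_identical(p$J, p$Ix + p$Iy)
    # translation: pad rows/cols of background
    shifted <- rbind(matrix(FALSE, 7, ncol(m) + 5),
                     cbind(matrix(FALSE, nrow(m), 5), m))
    ps <- section_properties(cross_section(shifted, c(0.002, 0.001)))
    expect_equal(ps$Ix, p$Ix)
    expect_equal(ps$Iy, p$Iy)
    expect_false(isTRUE(all.equal(ps$cx, p$cx)))
    # 90 degree rotation swaps Ix and Iy (square pixels)
    sq <- cross_section(m, 0.001)
    psq <- section_properties(sq)
    prot <- section_properties(cross_section(t(m)[ncol(m):1, ], 0.001))
    expect_equal(prot$Ix, psq$Iy)
    expect_equal(prot$Iy, psq$Ix)
    expect_equal(prot$J, psq$J)
  }
  # disjoint components pool about the common centroid: two separated
  # discs have much larger Iy than one (parallel-axis contribution)
  disc <- disc_section(10)
  two <- cbind(disc$mask, matrix(FALSE, nrow(disc$mask), 30), disc$mask)
  p2 <- section_properties(cross_section(two, 0.001), per_component = TRUE)
  p1 <- section_properties(disc)
  expect_gt(p2$Iy, 10 * p1$Iy)
  comps <- attr(p2, "components")
  expect_equal(nrow(comps), 2)
  expect_equal(comps$Iy[1], p1$Iy)  # each component about its own centroid
})

test_that("stiffness is the moduli-weighted moments", {
  p <- analytic_ellipse_properties(0.02, 0.015, 0.004)
  s1 <- stiffness(p, 1, 1)
  expect_equal(unname(s1), c(p$Ix, p$Iy, p$J))
  s2 <- stiffness(p, 2e10, 1e10)
  expect_equal(s2[["flexural_x"]], 2e10 * p$Ix)
  expect_equal(s2[["torsional"]], 1e10 * p$J)
  # doubling E doubles flexural terms, leaves torsional unchanged
  s3 <- stiffness(p, 4e10, 1e10)
  expect_equal(s3[["flexural_y"]], 2 * s2[["flexural_y"]])
  expect_equal(s3[["torsional"]], s2[["torsional"]])
})

test_that("slice placement reproduces the two anchoring conventions", {
  a <- place_slices("A", 1, 25)
  expect_equal(a[4], 0.16)
  expect_equal(a[c(2, 6)], c(0.08, 0.24))
  expect_equal(a[25], 1)
  b <- place_slices("B", 0.185, 8)
  expect_equal(b[1], 0)
  expect_equal(b[8], 0.185)
  expect_equal(diff(b), rep(0.185 / 7, 7))
  expect_error(place_slices("A", 1, 1))
})

test_that("extract_profile measures the expected axial trends", {
  vol <- generate_rostrum_volume(tube_spec(), 0.001, slice_thickness = 0.005)
  prof <- extract_profile(vol, place_slices("A", 1, 25))
  expect_s3_class(prof, "specimen_profile")
  expect_equal(nrow(prof$properties), 25)
  # uniform tube: Ix essentially flat across slices
  expect_lt(max(prof$properties$Ix) / min(prof$properties$Ix), 1.02)
  # close_section filled the lumen: area matches the solid disc
  solid <- analytic_ellipse_properties(0.02, 0.02, 0)
  expect_lt(max(abs(prof$properties$area / solid$area - 1)), 0.01)

  # tapering phantom: area strictly decreasing toward the tip
  tp <- extract_profile(
    generate_rostrum_volume(taper_spec(), 0.001, slice_thickness = 0.005),
    place_slices("A", 1, 25))
  expect_true(all(diff(tp$properties$area) > 0))  # tip (pos 0) -> posterior

  # too many positions for a coarse stack
  coarse <- generate_rostrum_volume(tube_spec(), 0.001,
                                    slice_thickness = 0.03)
  expect_error(extract_profile(coarse, place_slices("A", 1, 25)), "finer")
})

test_that("size correction follows the s^2 / s^4 laws", {
  vol <- generate_rostrum_volume(tube_spec(), 0.001, slice_thickness = 0.01)
  prof <- extract_profile(vol, place_slices("A", 1, 10))
  # s = 1: unchanged
  same <- size_correct(prof, prof$skull_length, mode = "analytic")
  expect_equal(same$properties$J, prof$properties$J)
  expect_identical(same$treatment, "size_corrected")
  # s = 2: J exactly 16x
  dbl <- size_correct(prof, 2 * prof$skull_length, mode = "analytic")
  expect_equal(dbl$properties$J, 16 * prof$properties$J)
  expect_equal(dbl$properties$area, 4 * prof$properties$area)
  expect_error(size_correct(prof, -1), "positive")
})

test_that("analytic and resample size correction agree per slice", {
  # the cross-validation scale factor: longest vs shortest study skull
  s <- 86 / 21.7
  vol <- generate_rostrum_volume(taper_spec(), 0.0005,
                                 slice_thickness = 0.01)
  prof <- extract_profile(vol, place_slices("A", 1, 10))
  ref <- prof$skull_length * s
  pa <- size_correct(prof, ref, mode = "analytic")
  pr <- size_correct(prof, ref, mode = "resample")
  for (q in c("area", "Ix", "Iy", "J")) {
    expect_lt(max(abs(pr$properties[[q]] / pa$properties[[q]] - 1)), 0.02)
  }
  # resample mode needs stored masks
  bare <- prof
  bare$sections <- NULL
  expect_error(size_correct(bare, ref, mode = "resample"), "masks")
})

test_that("downscaling a mask by s changes moments by s^4 within 2%", {
  disc <- disc_section(180)
  p1 <- section_properties(disc)
  for (s in c(0.5, 2)) {
    m2 <- rostrabeam:::.rescale_mask(disc$mask, s)
    p2 <- section_properties(cross_section(m2, disc$pixel_size))
    expect_lt(abs(p2$J / (p1$J * s^4) - 1), 0.02)
    expect_lt(abs(p2$area / (p1$area * s^2) - 1), 0.02)
  }
})
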