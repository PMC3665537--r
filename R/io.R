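# Stack and table I/O. Image stacks are numbered PGM slices (the portable
# graymap standard: ASCII "P2" or binary "P5") plus a plain-text sidecar
# with voxel spacing and landmarks. PGM is used because it is a standard
# grayscale raster format that base R can read and write exactly, and the
# ASCII variant keeps fixtures human-readable and versionable.

#' Write a volume as a numbered PGM slice series
#'
#' Each transverse slice becomes `<prefix>_NNNN.pgm` (foreground 255,
#' background 0), and `<prefix>_meta.txt` records the voxel spacing,
#' landmark indices, skull length and slice count.
#'
#' @param volume a `voxel_volume`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (defaults to the volume's name).
#' @param format `"P2"` (ASCII, default) or `"P5"` (binary).
#' @return invisibly, the sidecar path.
#' @export
write_volume <- function(volume, dir, prefix = volume$name, format = "P2") {
  stopifnot(inherits(volume, "voxel_volume"), format %in% c("P2", "P5"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nz <- dim(volume$mask)[1]
  for (k in seq_len(nz)) {
    img <- ifelse(volume$mask[k, , ], 255L, 0L)
    .write_pgm(img, file.path(dir, sprintf("%s_%04d.pgm", prefix, k)), format)
  }
  meta <- file.path(dir, sprintf("%s_meta.txt", prefix))
  writeLines(c(
    sprintf("name = %s", volume$name),
    sprintf("n_slices = %d", nz),
    sprintf("voxel_spacing_m = %.9g %.9g %.9g", volume$voxel_spacing[1],
            volume$voxel_spacing[2], volume$voxel_spacing[3]),
    sprintf("landmark_tip = %d", volume$landmarks[["tip"]]),
    sprintf("landmark_posterior = %d", volume$landmarks[["posterior"]]),
    sprintf("skull_length_m = %.9g", volume$skull_length)
  ), meta)
  invisible(meta)
}

.write_pgm <- function(img, path, format = "P2") {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 255))
  if (format == "P2") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    # one image row per line
    writeLines(apply(img, 1, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
              eos = NULL)
    writeBin(as.raw(as.vector(t(img))), con)  # PGM pixel order is row-major
  }
  invisible(path)
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # read header tokens (magic, width, height, maxval), skipping comments
  while (length(tok) < 4) {
    line <- readLines(con, n = 1)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  if (magic == "P2") {
    vals <- scan(con, what = integer(), quiet = TRUE)
  } else {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  }
  if (length(vals) != w * h) stop("truncated PGM: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Read a PGM slice series back into a volume
#'
#' Inverse of [write_volume()]: reads `<prefix>_NNNN.pgm` plus the sidecar.
#' Grayscale values are binarized with a threshold window (defaults to
#' \[128, 255\], recovering 0/255 phantoms exactly); pass `low`/`high` to
#' window real scan data differently, or `binarize = FALSE` to obtain the
#' raw grayscale slices as an integer array.
#'
#' @param dir directory holding the series.
#' @param prefix file-name prefix.
#' @param low,high greyscale window used for binarization.
#' @param binarize logical; if `FALSE`, `mask` holds grayscale integers.
#' @return a `voxel_volume`.
#' @export
read_volume <- function(dir, prefix, low = 128, high = 255, binarize = TRUE) {
  meta_path <- file.path(dir, sprintf("%s_meta.txt", prefix))
  if (!file.exists(meta_path)) stop("missing sidecar metadata: ", meta_path)
  meta <- .read_kv(meta_path)
  nz <- as.integer(meta[["n_slices"]])
  spacing <- as.numeric(strsplit(meta[["voxel_spacing_m"]], "\\s+")[[1]])
  slices <- lapply(seq_len(nz), function(k) {
    .read_pgm(file.path(dir, sprintf("%s_%04d.pgm", prefix, k)))
  })
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]])
  arr <- array(if (binarize) FALSE else 0L, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) {
    arr[k, , ] <- if (binarize) {
      slices[[k]] >= low & slices[[k]] <= high
    } else slices[[k]]
  }
  vol <- list(mask = arr, voxel_spacing = spacing,
              landmarks = c(tip = as.integer(meta[["landmark_tip"]]),
                            posterior = as.integer(meta[["landmark_posterior"]])),
              skull_length = as.numeric(meta[["skull_length_m"]]),
              name = meta[["name"]])
  class(vol) <- "voxel_volume"
  vol
}

# Parse "key = value" lines; later keys override earlier ones, except the
# repeatable key "specimen" which accumulates.
.read_kv <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (key == "specimen") {
      out$specimen <- c(out$specimen, val)
    } else {
      out[[key]] <- val
    }
  }
  out
}

#' Write a specimen profile as CSV
#'
#' Columns: `slice_index`, `position_fraction`, `area_m2`, `Ix_m4`, `Iy_m4`,
#' `J_m4`, `treatment`. Values are SI; pass `scale_1e7 = TRUE` to emit the
#' supplementary-table convention (values multiplied by 1e7 — note the unit
#' is still m^4 for I and J, m^2 for area).
#'
#' @param profile a `specimen_profile`.
#' @param path output file.
#' @param scale_1e7 multiply values by 1e7 on output.
#' @return invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path, scale_1e7 = FALSE) {
  stopifnot(inherits(profile, "specimen_profile"))
  f <- if (scale_1e7) 1e7 else 1
  df <- data.frame(slice_index = profile$slice_index,
                   position_fraction = profile$slice_positions,
                   position_requested = if (is.null(profile$positions_requested))
                     profile$slice_positions else profile$positions_requested,
                   area_m2 = profile$properties$area * f,
                   Ix_m4 = profile$properties$Ix * f,
                   Iy_m4 = profile$properties$Iy * f,
                   J_m4 = profile$properties$J * f,
                   treatment = profile$treatment)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a profile CSV written by [write_profile_csv()]
#'
#' @param path CSV path.
#' @param taxon label for the profile (defaults to the file name).
#' @param skull_length skull length in metres, if known.
#' @return a `specimen_profile`.
#' @export
read_profile_csv <- function(path, taxon = NULL,
                             skull_length = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice_index", "position_fraction", "area_m2",
            "Ix_m4", "Iy_m4", "J_m4", "treatment")
  if (!all(need %in% names(df))) {
    stop("not a profile CSV (missing columns): ", path)
  }
  props <- data.frame(area = df$area_m2, Ix = df$Ix_m4, Iy = df$Iy_m4,
                      J = df$J_m4)
  prof <- specimen_profile(
    taxon = if (is.null(taxon))
      sub("\\.csv$", "", basename(path)) else taxon,
    skull_length = skull_length,
    slice_positions = df$position_fraction,
    properties = props,
    treatment = df$treatment[1])
  if (!is.null(df$position_requested)) {
    prof$positions_requested <- df$position_requested
  }
  prof
}

#' Write a comparison table as CSV
#'
#' @param table a `comparison_table` from [pairwise_battery()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_comparison_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
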