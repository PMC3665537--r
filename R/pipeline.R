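# Configuration-driven orchestration: phantoms or stacks -> profiles ->
# size correction -> test battery -> tables, plots, log.

#' Build a run configuration
#'
#' @param specimens list of specimen descriptors; each a list with `label`,
#'   `skull_length` (m), and either `morphotype` (a preset name or a
#'   [morphotype_spec()]) or `stack` = list(dir =, prefix =) naming a PGM
#'   series readable by [read_volume()].
#' @param scheme slice placement scheme, `"A"` or `"B"`.
#' @param slice_count number of slices (default 25).
#' @param span_fraction span covered by the scheme (default 1).
#' @param reference_taxon label of the specimen whose skull length anchors
#'   the size correction (conventionally the longest skull).
#' @param threshold greyscale window `c(low, high)` for stack specimens.
#' @param alpha,gate_alpha battery significance and normality-gate levels.
#' @param correction_mode `"analytic"` or `"resample"` size correction.
#' @param voxel_size in-plane voxel size for phantom generation (m).
#' @param output_dir where artifacts are written.
#' @param seed integer seed controlling all randomness of the run.
#' @return a `run_config`.
#' @export
run_config <- function(specimens, scheme = "A", slice_count = 25,
                       span_fraction = 1, reference_taxon,
                       threshold = c(128, 255), alpha = 0.05,
                       gate_alpha = 0.05, correction_mode = "analytic",
                       voxel_size = 0.0015, output_dir = ".", seed = 1L) {
  labels <- vapply(specimens, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("specimen labels must be unique")
  if (!reference_taxon %in% labels) {
    stop("reference_taxon must be one of the specimen labels")
  }
  if (slice_count < 2) stop("slice_count must be at least 2")
  cfg <- list(specimens = specimens, scheme = scheme,
              slice_count = as.integer(slice_count),
              span_fraction = span_fraction,
              reference_taxon = reference_taxon,
              threshold = threshold, alpha = alpha, gate_alpha = gate_alpha,
              correction_mode = correction_mode, voxel_size = voxel_size,
              output_dir = output_dir, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a key-value text file
#'
#' The file holds `key = value` lines (`#` comments allowed). Repeatable
#' `specimen` lines describe one specimen each as space-separated
#' `label field=value` tokens, e.g.
#' ```
#' scheme = A
#' slice_count = 25
#' reference_taxon = gharial
#' seed = 1
#' specimen = gharial   morphotype=longirostrine skull_length=0.86
#' specimen = alligator morphotype=platyrostral  skull_length=0.217
#' specimen = scanned   stack=path/to/dir:prefix skull_length=0.62
#' ```
#'
#' @param path config file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  kv <- .read_kv(path)
  if (is.null(kv$specimen)) stop("config declares no specimens")
  specimens <- lapply(kv$specimen, function(sline) {
    tok <- strsplit(trimws(sline), "\\s+")[[1]]
    sp <- list(label = tok[1])
    for (tk in tok[-1]) {
      p <- strsplit(tk, "=", fixed = TRUE)[[1]]
      if (length(p) != 2) stop("bad specimen field: ", tk)
      sp[[p[1]]] <- p[2]
    }
    if (is.null(sp$skull_length)) {
      stop("specimen ", sp$label, " needs skull_length")
    }
    sp$skull_length <- as.numeric(sp$skull_length)
    if (!is.null(sp$stack)) {
      p <- strsplit(sp$stack, ":", fixed = TRUE)[[1]]
      sp$stack <- list(dir = p[1], prefix = p[2])
    }
    sp
  })
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  chr <- function(key, default) {
    if (is.null(kv[[key]])) default else kv[[key]]
  }
  run_config(
    specimens = specimens,
    scheme = chr("scheme", "A"),
    slice_count = num("slice_count", 25),
    span_fraction = num("span_fraction", 1),
    reference_taxon = chr("reference_taxon",
                          specimens[[1]]$label),
    threshold = c(num("threshold_low", 128), num("threshold_high", 255)),
    alpha = num("alpha", 0.05),
    gate_alpha = num("gate_alpha", 0.05),
    correction_mode = chr("correction_mode", "analytic"),
    voxel_size = num("voxel_size", 0.0015),
    output_dir = chr("output_dir", "."),
    seed = num("seed", 1))
}

# Acquire the volume for one specimen descriptor.
.specimen_volume <- function(sp, cfg) {
  if (!is.null(sp$stack)) {
    read_volume(sp$stack$dir, sp$stack$prefix,
                low = cfg$threshold[1], high = cfg$threshold[2])
  } else if (!is.null(sp$morphotype)) {
    spec <- if (inherits(sp$morphotype, "morphotype_spec")) sp$morphotype
            else morphotype_preset(sp$morphotype, sp$skull_length,
                                   name = sp$label)
    generate_rostrum_volume(spec, cfg$voxel_size,
                            noise_seed = cfg$seed +
                              match(sp$label,
                                    vapply(cfg$specimens, `[[`, "", "label")))
  } else {
    stop("specimen ", sp$label, " has neither a stack nor a morphotype")
  }
}

#' Run the full analysis pipeline
#'
#' Generates or reads each specimen's volume, extracts raw profiles on the
#' configured slice scheme, size-corrects them to the reference taxon's
#' skull length, runs the comparison battery on both treatments, and writes:
#' per-specimen raw and size-corrected profile CSVs, one comparison CSV per
#' treatment, one log-scale profile plot (PDF) per measure per treatment,
#' and a run log recording every decision (threshold, slices used, gate
#' outcomes, Sidak family size, seed). Given a seed the entire artifact set
#' is deterministic.
#'
#' @param config a `run_config` (or path to a config file).
#' @return invisibly, a list with `profiles_raw`, `profiles_corrected`,
#'   `comparisons` (list of two `comparison_table`s), and `files` (all
#'   paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("run seed: %d", config$seed),
                 sprintf("slice scheme: %s, %d slices, span fraction %g",
                         config$scheme, config$slice_count,
                         config$span_fraction),
                 sprintf("threshold window: [%g, %g]", config$threshold[1],
                         config$threshold[2]),
                 sprintf("size correction: %s, reference taxon %s",
                         config$correction_mode, config$reference_taxon))
  positions <- place_slices(config$scheme, config$span_fraction,
                            config$slice_count)
  log_lines <- c(log_lines, sprintf("slice positions: %s",
                                    paste(signif(positions, 4),
                                          collapse = " ")))
  files <- character(0)
  profiles_raw <- list()
  for (sp in config$specimens) {
    vol <- .specimen_volume(sp, config)
    prof <- extract_profile(vol, positions, taxon = sp$label)
    prof$skull_length <- sp$skull_length
    profiles_raw[[sp$label]] <- prof
    f <- file.path(out_dir, sprintf("%s_raw.csv", sp$label))
    write_profile_csv(prof, f)
    files <- c(files, f)
    log_lines <- c(log_lines,
                   sprintf("specimen %s: skull length %g m, %d slices measured",
                           sp$label, sp$skull_length,
                           length(prof$slice_positions)))
  }
  ref_len <- config$specimens[[
    match(config$reference_taxon,
          vapply(config$specimens, `[[`, "", "label"))]]$skull_length
  profiles_corrected <- lapply(profiles_raw, size_correct,
                               reference_length = ref_len,
                               mode = config$correction_mode)
  for (lab in names(profiles_corrected)) {
    f <- file.path(out_dir, sprintf("%s_size_corrected.csv", lab))
    write_profile_csv(profiles_corrected[[lab]], f)
    files <- c(files, f)
  }
  comparisons <- list()
  for (treatment in c("raw", "size_corrected")) {
    profs <- if (treatment == "raw") profiles_raw else profiles_corrected
    tab <- pairwise_battery(profs, alpha = config$alpha,
                            gate_alpha = config$gate_alpha)
    comparisons[[treatment]] <- tab
    f <- file.path(out_dir, sprintf("comparisons_%s.csv", treatment))
    write_comparison_csv(tab, f)
    files <- c(files, f)
    gate <- attr(tab, "gate")
    log_lines <- c(log_lines,
      sprintf("battery (%s): %d tests, Sidak family size %d, threshold %.6g",
              treatment, nrow(tab), attr(tab, "family_size"),
              tab$sidak_threshold[1]),
      sprintf("  gate %s/%s: Shapiro p = %.4g -> %s", gate$taxon,
              gate$measure, gate$shapiro_p,
              ifelse(gate$normal, "normal (t route)",
                     "non-normal (Wilcoxon route)")))
    for (ms in c("Ix", "Iy", "J")) {
      f <- file.path(out_dir, sprintf("profile_%s_%s.pdf", ms, treatment))
      render_profile_plot(profs, ms, treatment, f)
      files <- c(files, f)
    }
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)
  invisible(list(profiles_raw = profiles_raw,
                 profiles_corrected = profiles_corrected,
                 comparisons = comparisons, files = files))
}

#' Plot log-scale section-property profiles
#'
#' Draws log10 of the chosen measure against slice index, one line per
#' taxon, in the style of comparative rostrum-stiffness figures. Nonpositive
#' values cannot be log-transformed and are dropped with a warning.
#'
#' @param profiles list of `specimen_profile`s on a shared slice grid.
#' @param measure `"Ix"`, `"Iy"` or `"J"`.
#' @param treatment label used in the plot title.
#' @param file output PDF path.
#' @return invisibly, `file`.
#' @export
render_profile_plot <- function(profiles, measure, treatment, file) {
  stopifnot(length(profiles) >= 1, measure %in% c("Ix", "Iy", "J"))
  grDevices::pdf(file, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  vals <- lapply(profiles, function(p) p$properties[[measure]])
  if (any(unlist(vals) <= 0)) {
    warning("nonpositive ", measure, " values excluded from log plot")
  }
  logs <- lapply(vals, function(v) {
    out <- rep(NA_real_, length(v))
    out[v > 0] <- log10(v[v > 0])
    out
  })
  nslice <- length(profiles[[1]]$slice_index)
  ylim <- range(unlist(logs), na.rm = TRUE)
  cols <- grDevices::hcl.colors(max(3, length(profiles)), "Dark 3")
  graphics::plot(NA, xlim = c(1, nslice), ylim = ylim,
                 xlab = "slice index (tip to posterior)",
                 ylab = bquote(log[10] ~ .(measure) ~ (m^4)),
                 main = sprintf("%s (%s)", measure, treatment))
  for (i in seq_along(profiles)) {
    graphics::lines(profiles[[i]]$slice_index, logs[[i]], col = cols[i],
                    lwd = 2)
    graphics::points(profiles[[i]]$slice_index, logs[[i]], col = cols[i],
                     pch = 16, cex = 0.6)
  }
  graphics::legend("bottomright",
                   legend = vapply(profiles, `[[`, "", "taxon"),
                   col = cols[seq_along(profiles)], lwd = 2, bty = "n")
  invisible(file)
}
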