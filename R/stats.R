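# Paired comparison battery: normality-gated Wilcoxon signed-rank (normal
# approximation) or paired t, with Sidak family-wise correction.

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] used as the gate that routes
#' a pairing to the nonparametric or the parametric test. A series "passes"
#' when p >= the gate alpha (conventionally 0.05).
#'
#' @param series numeric vector, length >= 3, non-constant.
#' @return list with `statistic` (W) and `p`.
#' @export
shapiro_normality <- function(series) {
  if (length(series) < 3) stop("normality test needs at least 3 values")
  if (stats::sd(series) == 0) {
    stop("normality test undefined for a constant series")
  }
  ht <- stats::shapiro.test(series)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

# Internal: assemble a test-result row.
.test_row <- function(taxon_1, taxon_2, measure, treatment, test_used,
                      statistic, df, p) {
  data.frame(taxon_1 = taxon_1, taxon_2 = taxon_2, measure = measure,
             treatment = treatment, test = test_used,
             statistic = statistic, df = df, p = p,
             stringsAsFactors = FALSE)
}

#' Wilcoxon signed-rank test, large-sample normal approximation
#'
#' Paired two-sided Wilcoxon signed-rank test reported as a z statistic, the
#' convention of legacy statistics suites: differences d = a - b, zero
#' differences dropped, absolute differences ranked (average ranks on ties),
#' W = rank sum of the positive differences, and
#' \deqn{z = |W - m(m+1)/4| / \sqrt{m(m+1)(2m+1)/24}}
#' with m retained pairs — no continuity correction and no tie correction.
#' The two-sided p comes from the standard normal. With all 25 differences
#' of one sign this gives z = 4.37 (2 dp); with only the smallest-magnitude
#' difference opposing, 4.35.
#'
#' @param a,b equal-length numeric vectors of slice-matched measurements.
#' @param taxon_1,taxon_2,measure,treatment optional labels carried into the
#'   result row.
#' @return one-row data.frame: labels, `test = "wilcoxon"`, `statistic`
#'   (|z|), `df = NA`, `p` (two-sided).
#' @export
wilcoxon_paired_z <- function(a, b, taxon_1 = "a", taxon_2 = "b",
                              measure = NA_character_, treatment = "raw") {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("all paired differences are zero")
  if (m < 5) stop("need at least 5 nonzero paired differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  sigma <- sqrt(m * (m + 1) * (2 * m + 1) / 24)
  z <- abs(W - mu) / sigma
  p <- 2 * stats::pnorm(-z)
  .test_row(taxon_1, taxon_2, measure, treatment, "wilcoxon", z, NA_integer_, p)
}

#' Paired two-tailed t test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on the paired differences d = a - b, with
#' df = n - 1 and a two-sided p. Used when both series of a pairing pass the
#' normality gate.
#'
#' @inheritParams wilcoxon_paired_z
#' @return one-row data.frame: labels, `test = "t"`, `statistic` (t, signed),
#'   `df`, `p`.
#' @export
paired_t <- function(a, b, taxon_1 = "a", taxon_2 = "b",
                     measure = NA_character_, treatment = "raw") {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) stop("paired t undefined: differences have zero variance")
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  .test_row(taxon_1, taxon_2, measure, treatment, "t", t, n - 1L, p)
}

#' Sidak family-wise significance threshold
#'
#' For a family of n tests at original level alpha, the per-test threshold
#' is \deqn{\alpha_{adj} = 1 - (1 - \alpha)^{1/n},} the exact correction
#' from which the Bonferroni bound alpha/n is derived (and which it always
#' undercuts for n >= 2). A raw p is family-wise significant iff
#' p < this threshold.
#'
#' @param alpha original significance level, in (0, 1).
#' @param n family size (number of tests), >= 1.
#' @return the adjusted per-test threshold.
#' @export
#' @examples
#' sidak_alpha(0.05, 1)   # 0.05
#' sidak_alpha(0.05, 9)   # 0.005683
sidak_alpha <- function(alpha, n) {
  stopifnot(alpha > 0, alpha < 1, n >= 1)
  1 - (1 - alpha)^(1 / n)
}

#' Run the full pairwise comparison battery
#'
#' For every unordered pair of profiles and each requested measure, applies
#' the normality gate to both series: if either fails (Shapiro-Wilk
#' p < `gate_alpha`), the pairing is tested with [wilcoxon_paired_z()],
#' otherwise with [paired_t()]. All tests run in one call form a single
#' Sidak family (for k taxa and 3 measures, n = 3k(k-1)/2), and each row is
#' flagged both at the raw level and after correction; rows significant raw
#' but not after correction carry the asterisk flag.
#'
#' @param profiles list of `specimen_profile`s sharing slice positions and
#'   treatment.
#' @param measures which property columns to compare.
#' @param alpha raw significance level (default 0.05).
#' @param gate_alpha normality-gate level (default 0.05).
#' @param family_size Sidak family size; defaults to the number of tests in
#'   this battery run, and is configurable when the battery is part of a
#'   larger family.
#' @return a `comparison_table` data.frame: taxon pair, measure, treatment,
#'   test used, statistic, df, p, `sidak_threshold`, `significant_raw`,
#'   `significant_after_sidak`, `asterisk`; attributes `family_size`,
#'   `alpha`, `gate` (data.frame of per-series gate outcomes).
#' @export
pairwise_battery <- function(profiles, measures = c("Ix", "Iy", "J"),
                             alpha = 0.05, gate_alpha = 0.05,
                             family_size = NULL) {
  stopifnot(length(profiles) >= 2)
  # pairing is by equivalent requested locations along the span; the actual
  # stored-slice positions may differ by sub-slice rounding between stacks
  req <- function(p) {
    if (is.null(p$positions_requested)) p$slice_positions
    else p$positions_requested
  }
  pos <- req(profiles[[1]])
  trt <- profiles[[1]]$treatment
  for (p in profiles[-1]) {
    if (length(req(p)) != length(pos) || any(abs(req(p) - pos) > 1e-9)) {
      stop("profiles must share identical slice positions")
    }
    if (!identical(p$treatment, trt)) {
      stop("profiles must share one treatment (raw or size_corrected)")
    }
  }
  labels <- vapply(profiles, function(p) p$taxon, character(1))
  # gate each taxon x measure series once
  gate <- expand.grid(taxon = labels, measure = measures,
                      stringsAsFactors = FALSE)
  gate$shapiro_p <- mapply(function(tx, ms) {
    shapiro_normality(profiles[[match(tx, labels)]]$properties[[ms]])$p
  }, gate$taxon, gate$measure)
  gate$normal <- gate$shapiro_p >= gate_alpha
  rows <- list()
  for (i in seq_along(profiles)) {
    for (j in seq_along(profiles)) {
      if (i >= j) next
      for (ms in measures) {
        a <- profiles[[i]]$properties[[ms]]
        b <- profiles[[j]]$properties[[ms]]
        ok_i <- gate$normal[gate$taxon == labels[i] & gate$measure == ms]
        ok_j <- gate$normal[gate$taxon == labels[j] & gate$measure == ms]
        rows[[length(rows) + 1L]] <- if (ok_i && ok_j) {
          paired_t(a, b, labels[i], labels[j], ms, trt)
        } else {
          wilcoxon_paired_z(a, b, labels[i], labels[j], ms, trt)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  n_family <- if (is.null(family_size)) nrow(tab) else family_size
  thr <- sidak_alpha(alpha, n_family)
  tab$sidak_threshold <- thr
  tab$significant_raw <- tab$p < alpha
  tab$significant_after_sidak <- tab$p < thr
  tab$asterisk <- tab$significant_raw & !tab$significant_after_sidak
  attr(tab, "family_size") <- n_family
  attr(tab, "alpha") <- alpha
  attr(tab, "gate") <- gate
  class(tab) <- c("comparison_table", class(tab))
  tab
}
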