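#' Hit totals by total number of guanines
#'
#' Sums frequency-matrix cells along anti-diagonals (m + n = constant) for
#' interrupted variants, the pooling used to compare tract lengths across
#' alleles.
#'
#' @param fm A [frequency_matrix()].
#' @param interrupt Interrupt bases to pool over (default: all present).
#' @param include_continuous Also add continuous counts at their length k
#'   (default FALSE; the classic pooling covers interrupted tracts only).
#' @return A named integer vector, names = total guanines, values = hits.
#' @export
totals_by_total_g <- function(fm, interrupt = names(fm$counts),
                              include_continuous = FALSE) {
  stopifnot(inherits(fm, "frequency_matrix"))
  tot <- integer(0)
  add <- function(tot, key, val) {
    key <- as.character(key)
    if (!key %in% names(tot)) tot[key] <- 0L
    tot[key] <- tot[key] + val
    tot
  }
  for (x in intersect(interrupt, names(fm$counts))) {
    mat <- fm$counts[[x]]
    for (i in seq_along(rownames(mat))) for (j in seq_along(colnames(mat))) {
      if (mat[i, j] > 0L)
        tot <- add(tot, as.integer(rownames(mat)[i]) +
                        as.integer(colnames(mat)[j]), mat[i, j])
    }
  }
  if (include_continuous)
    for (k in names(fm$continuous))
      if (fm$continuous[k] > 0L) tot <- add(tot, k, fm$continuous[k])
  tot[order(as.integer(names(tot)))]
}

#' Sample skewness
#'
#' The default estimator is the adjusted Fisher-Pearson statistic used by
#' spreadsheet SKEW functions,
#' \deqn{g = \frac{N}{(N-1)(N-2)} \sum_i \left(\frac{x_i - \bar x}{s}\right)^3,}
#' with \eqn{s} the (N-1)-denominator sample standard deviation. The plain
#' moment (biased) estimator is available via `method = "moment"`.
#'
#' @param xs Numeric vector, length >= 3, with nonzero sample variance.
#' @param method `"adjusted"` (default) or `"moment"`.
#' @return The skewness estimate.
#' @export
sample_skewness <- function(xs, method = c("adjusted", "moment")) {
  method <- match.arg(method)
  xs <- as.numeric(xs)
  n <- length(xs)
  if (n < 3L) stop("skewness needs at least 3 observations", call. = FALSE)
  s <- sd(xs)
  if (!is.finite(s) || s == 0)
    stop("skewness undefined for zero-variance data", call. = FALSE)
  z <- (xs - mean(xs)) / s
  if (method == "adjusted") n / ((n - 1) * (n - 2)) * sum(z^3)
  else {
    m2 <- mean((xs - mean(xs))^2); m3 <- mean((xs - mean(xs))^3)
    m3 / m2^1.5
  }
}

#' Quadrant occupancy of a frequency matrix around a pivot variant
#'
#' Partitions interrupted cells by the sign of (m - m0, n - n0) around a
#' pivot cell (default G6AG7, the modal variant). Cells sharing a
#' coordinate with the pivot are tallied separately as `on_axes`, and
#' inclusive quadrant totals (cells with m on-or-beyond and n on-or-beyond
#' the pivot, axes folded in) are reported alongside the strict tallies so
#' both readings of a "quadrant fraction" are auditable. Quadrants are
#' named in (first-run, second-run) coordinates, not figure orientation.
#'
#' @param fm A [frequency_matrix()].
#' @param pivot Integer length-2 vector `c(m0, n0)` (default `c(6, 7)`).
#' @param interrupt Interrupt bases to pool over (default: all present).
#' @return A list with `strict` (named counts: `short_first_long_second`,
#'   `long_first_short_second`, `both_long`, `both_short`, `on_axes`),
#'   `inclusive` (same quadrant names, axes folded in), `fractions`
#'   (inclusive counts / total) and `total`.
#' @export
quadrant_counts <- function(fm, pivot = c(6L, 7L),
                            interrupt = names(fm$counts)) {
  stopifnot(inherits(fm, "frequency_matrix"), length(pivot) == 2L)
  interrupt <- intersect(interrupt, names(fm$counts))
  if (!length(interrupt) || all(vapply(fm$counts[interrupt], sum, 0) == 0))
    stop("no interrupted hits to partition", call. = FALSE)
  m0 <- as.integer(pivot[1]); n0 <- as.integer(pivot[2])
  if (!m0 %in% fm$m_range || !n0 %in% fm$n_range)
    stop("pivot outside matrix bounds", call. = FALSE)
  strict <- c(short_first_long_second = 0L, long_first_short_second = 0L,
              both_long = 0L, both_short = 0L, on_axes = 0L)
  inclusive <- strict[1:4]
  total <- 0L
  for (x in interrupt) {
    mat <- fm$counts[[x]]
    for (i in seq_along(rownames(mat))) for (j in seq_along(colnames(mat))) {
      cnt <- mat[i, j]
      if (cnt == 0L) next
      m <- as.integer(rownames(mat)[i]); n <- as.integer(colnames(mat)[j])
      total <- total + cnt
      if (m == m0 || n == n0) strict["on_axes"] <- strict["on_axes"] + cnt
      else if (m < m0 && n > n0)
        strict["short_first_long_second"] <- strict["short_first_long_second"] + cnt
      else if (m > m0 && n < n0)
        strict["long_first_short_second"] <- strict["long_first_short_second"] + cnt
      else if (m > m0 && n > n0) strict["both_long"] <- strict["both_long"] + cnt
      else strict["both_short"] <- strict["both_short"] + cnt
      if (m <= m0 && n >= n0)
        inclusive["short_first_long_second"] <- inclusive["short_first_long_second"] + cnt
      if (m >= m0 && n <= n0)
        inclusive["long_first_short_second"] <- inclusive["long_first_short_second"] + cnt
      if (m >= m0 && n >= n0) inclusive["both_long"] <- inclusive["both_long"] + cnt
      if (m <= m0 && n <= n0) inclusive["both_short"] <- inclusive["both_short"] + cnt
    }
  }
  list(strict = strict, inclusive = inclusive,
       fractions = inclusive / total, total = total, pivot = c(m0, n0))
}

#' Adenine-position spectrum of interrupted hits
#'
#' Pools interrupted-cell counts by the signed [adenine_position()] of each
#' cell's variant and reports the fraction of interrupted hits at each
#' position.
#'
#' @param fm A [frequency_matrix()].
#' @param interrupt Interrupt bases to pool over (default: all present).
#' @return A data.frame with columns `position`, `count`, `fraction`,
#'   ordered by position. Fractions sum to 1 over occupied positions.
#' @export
position_spectrum <- function(fm, interrupt = names(fm$counts)) {
  stopifnot(inherits(fm, "frequency_matrix"))
  acc <- integer(0)
  for (x in intersect(interrupt, names(fm$counts))) {
    mat <- fm$counts[[x]]
    for (i in seq_along(rownames(mat))) for (j in seq_along(colnames(mat))) {
      cnt <- mat[i, j]
      if (cnt == 0L) next
      pos <- adenine_position(gtract_variant(
        as.integer(rownames(mat)[i]), x, as.integer(colnames(mat)[j])))
      key <- as.character(pos)
      acc[key] <- if (key %in% names(acc)) acc[key] + cnt else cnt
    }
  }
  if (!length(acc))
    return(data.frame(position = integer(), count = integer(),
                      fraction = numeric()))
  out <- data.frame(position = as.integer(names(acc)),
                    count = as.integer(acc),
                    fraction = as.numeric(acc) / sum(acc))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative frequency-versus-termination curve
#'
#' Joins occupied variants (count > 0, interrupted and continuous) to a
#' termination-product table, sorts by ascending TP percentage, and
#' accumulates hit fractions — the curve relating how common an allele is
#' in the population to how efficiently it terminates transcription in
#' vitro. Occupied variants missing from the TP table are excluded with a
#' warning (never imputed); cumulative fractions are taken over the
#' retained hits and end at 1.
#'
#' @param fm A [frequency_matrix()].
#' @param tp A `tp_table` (see [read_tp_table()]).
#' @return A `cumulative_curve` data.frame with columns `variant`,
#'   `tp_percent`, `hit_count`, `cumulative_hit_fraction`; excluded
#'   variants are recorded in attribute `"excluded"`.
#' @seealso [fraction_within()]
#' @export
cumulative_tp_curve <- function(fm, tp) {
  stopifnot(inherits(fm, "frequency_matrix"), inherits(tp, "tp_table"))
  occ <- as_variant_counts(fm)
  idx <- match(occ$variant, tp$variant)
  excluded <- occ$variant[is.na(idx)]
  if (length(excluded))
    warning("no TP value for occupied variant(s): ",
            paste(excluded, collapse = ", "), "; excluded from the curve",
            call. = FALSE)
  keep <- occ[!is.na(idx), , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no occupied variant has a TP value", call. = FALSE)
  keep$tp_percent <- tp$mean_tp[idx[!is.na(idx)]]
  keep <- keep[order(keep$tp_percent, keep$variant), , drop = FALSE]
  out <- data.frame(variant = keep$variant, tp_percent = keep$tp_percent,
                    hit_count = keep$count,
                    cumulative_hit_fraction =
                      cumsum(keep$count) / sum(keep$count),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' Fraction of hits whose variant TP lies in a window
#'
#' @param curve A `cumulative_curve` from [cumulative_tp_curve()].
#' @param lo,hi TP window bounds in percent, inclusive.
#' @return The fraction of (retained) hits with `tp_percent` in
#'   `[lo, hi]`.
#' @export
fraction_within <- function(curve, lo, hi) {
  stopifnot(inherits(curve, "cumulative_curve"), lo <= hi)
  sum(curve$hit_count[curve$tp_percent >= lo & curve$tp_percent <= hi]) /
    sum(curve$hit_count)
}

#' One-stop survey report over a frequency matrix
#'
#' Bundles the population-level statistics into one list (and optionally a
#' JSON file): totals by guanine count, row/column skewness, quadrant
#' asymmetry, adenine-position spectrum, and — when a TP table is given —
#' the cumulative frequency-versus-termination curve.
#'
#' @param fm A [frequency_matrix()].
#' @param tp Optional `tp_table`.
#' @param pivot Pivot cell for [quadrant_counts()].
#' @param path Optional path to write the report as JSON.
#' @return A named list of statistics, invisibly when `path` is given.
#' @export
survey_report <- function(fm, tp = NULL, pivot = c(6L, 7L), path = NULL) {
  stopifnot(inherits(fm, "frequency_matrix"))
  interrupted <- sum(vapply(fm$counts, sum, 0))
  rep <- list(
    total_hits = fm$total_hits,
    interrupted_hits = interrupted,
    continuous_hits = sum(fm$continuous),
    totals_by_total_g = as.list(totals_by_total_g(fm)),
    position_spectrum = position_spectrum(fm))
  row_tot <- if (length(fm$counts)) rowSums(Reduce(`+`, fm$counts)) else NULL
  col_tot <- if (length(fm$counts)) colSums(Reduce(`+`, fm$counts)) else NULL
  if (!is.null(row_tot) && length(row_tot) >= 3 && sd(row_tot) > 0)
    rep$row_total_skewness <- sample_skewness(row_tot)
  if (!is.null(col_tot) && length(col_tot) >= 3 && sd(col_tot) > 0)
    rep$col_total_skewness <- sample_skewness(col_tot)
  if (interrupted > 0) rep$quadrants <- quadrant_counts(fm, pivot = pivot)
  if (!is.null(tp)) {
    curve <- cumulative_tp_curve(fm, tp)
    rep$cumulative_curve <- as.data.frame(curve)
    rep$excluded_from_curve <- attr(curve, "excluded")
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
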