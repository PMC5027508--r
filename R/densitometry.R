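#' Gel lane density profile
#'
#' A 1-D densitometry trace: non-negative pixel densities ordered from the
#' well towards the gel bottom (increasing migration).
#'
#' @param density Numeric vector of non-negative densities (length >= 2).
#' @param lane_id Lane identifier.
#' @param well_pixel Pixel index of the well (default 1).
#' @return A `lane_profile` object.
#' @export
lane_profile <- function(density, lane_id = "lane", well_pixel = 1L) {
  density <- as.numeric(density)
  if (length(density) < 2L || any(!is.finite(density)) || any(density < 0))
    stop("density must be >= 2 finite non-negative values", call. = FALSE)
  well_pixel <- as.integer(well_pixel)
  if (well_pixel < 1L || well_pixel > length(density))
    stop("well_pixel outside the profile", call. = FALSE)
  structure(list(lane_id = as.character(lane_id), density = density,
                 well_pixel = well_pixel),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat("<lane_profile> ", x$lane_id, "  (", length(x$density),
      " px, well at ", x$well_pixel, ")\n", sep = "")
  invisible(x)
}

#' Read/write lane profiles and ladder bands as TSV
#'
#' Lane TSVs have columns `pixel`, `density`; ladder TSVs have `pixel`,
#' `length`.
#'
#' @param path File path.
#' @param lane_id Lane identifier for the returned profile.
#' @param well_pixel Well pixel index.
#' @return `read_lane_profile()`: a [lane_profile()];
#'   `read_ladder_bands()`: a data.frame with `pixel` and `length`.
#' @export
read_lane_profile <- function(path, lane_id = basename(path),
                              well_pixel = 1L) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pixel", "density") %in% names(tab)))
  tab <- tab[order(tab$pixel), , drop = FALSE]
  lane_profile(tab$density, lane_id = lane_id, well_pixel = well_pixel)
}

#' @rdname read_lane_profile
#' @export
read_ladder_bands <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pixel", "length") %in% names(tab)))
  tab[order(tab$pixel), c("pixel", "length")]
}

#' Fit a ladder calibration
#'
#' Fits the monotone pixel-to-length mapping through marker-ladder bands.
#' The default is first-order (piecewise-linear) interpolation between
#' adjacent knots — exact at every knot — with linear extrapolation beyond
#' the knot hull using the terminal segment slopes; a single global
#' least-squares line is available via `method = "global"` for sensitivity
#' checks.
#'
#' @param bands Data.frame with columns `pixel` and `length`; lengths must
#'   decrease strictly as pixels increase (longer fragments migrate less).
#' @param method `"piecewise"` (default) or `"global"`.
#' @return A `ladder_calibration` object.
#' @seealso [pixel_to_length()], [length_to_pixel()]
#' @export
fit_ladder <- function(bands, method = c("piecewise", "global")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(bands), all(c("pixel", "length") %in% names(bands)),
            nrow(bands) >= 2L)
  bands <- bands[order(bands$pixel), , drop = FALSE]
  if (any(diff(bands$pixel) <= 0) || any(diff(bands$length) >= 0))
    stop("ladder bands must be strictly monotone: increasing pixel, ",
         "decreasing length", call. = FALSE)
  structure(list(knots = data.frame(pixel = as.numeric(bands$pixel),
                                    length = as.numeric(bands$length)),
                 method = method),
            class = "ladder_calibration")
}

#' @export
print.ladder_calibration <- function(x, ...) {
  cat("<ladder_calibration> ", nrow(x$knots), " knots, ",
      min(x$knots$length), "-", max(x$knots$length), " nt, method ",
      x$method, "\n", sep = "")
  invisible(x)
}

# interpolate y(xq) through (x, y) knots; linear extrapolation outside hull
interp_extrap <- function(x, y, xq) {
  out <- approx(x, y, xout = xq, ties = "ordered")$y
  lo <- xq < min(x); hi <- xq > max(x)
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xq[lo] - x[1])
  }
  if (any(hi)) {
    k <- length(x)
    s <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
    out[hi] <- y[k] + s * (xq[hi] - x[k])
  }
  attr(out, "extrapolated") <- lo | hi
  out
}

#' Convert between pixel position and DNA length
#'
#' Applies a [fit_ladder()] calibration in either direction. Queries beyond
#' the knot hull are linearly extrapolated and flagged in the
#' `"extrapolated"` attribute of the result.
#'
#' @param cal A `ladder_calibration`.
#' @param pixel,length Numeric query vectors.
#' @return Numeric vector of converted values with attribute
#'   `"extrapolated"` (logical).
#' @export
pixel_to_length <- function(cal, pixel) {
  stopifnot(inherits(cal, "ladder_calibration"))
  if (cal$method == "global") {
    fit <- lm(length ~ pixel, data = cal$knots)
    out <- as.numeric(coef(fit)[1] + coef(fit)[2] * pixel)
    attr(out, "extrapolated") <- pixel < min(cal$knots$pixel) |
      pixel > max(cal$knots$pixel)
    return(out)
  }
  interp_extrap(cal$knots$pixel, cal$knots$length, pixel)
}

#' @rdname pixel_to_length
#' @export
length_to_pixel <- function(cal, length) {
  stopifnot(inherits(cal, "ladder_calibration"))
  if (cal$method == "global") {
    fit <- lm(pixel ~ length, data = cal$knots)
    out <- as.numeric(coef(fit)[1] + coef(fit)[2] * length)
    attr(out, "extrapolated") <- length < min(cal$knots$length) |
      length > max(cal$knots$length)
    return(out)
  }
  # invert by interpolating the reversed knot order (length increasing)
  k <- cal$knots[order(cal$knots$length), , drop = FALSE]
  interp_extrap(k$length, k$pixel, length)
}

#' Quantification regions for termination-product percentages
#'
#' @param tp_window Length window in nt covering the termination products
#'   (default 92-140, the TP1-TP3 region).
#' @param lower_cutoff Lower length cutoff in nt of the total-density
#'   window, i.e. the ~100 nt marker (default 100).
#' @param include_cutoff Include the cutoff pixel itself (default TRUE).
#' @param include_wells Include well material in total density (default
#'   TRUE).
#' @return A `quant_regions` list.
#' @export
quant_regions <- function(tp_window = c(92, 140), lower_cutoff = 100,
                          include_cutoff = TRUE, include_wells = TRUE) {
  stopifnot(length(tp_window) == 2L, tp_window[1] < tp_window[2],
            lower_cutoff <= tp_window[2])
  structure(list(tp_window = as.numeric(tp_window),
                 lower_cutoff = as.numeric(lower_cutoff),
                 include_cutoff = isTRUE(include_cutoff),
                 include_wells = isTRUE(include_wells)),
            class = "quant_regions")
}

#' Termination-product percentage of a lane
#'
#' The quantification used for mini-gel lanes: the density summed over
#' pixels whose calibrated length lies in the TP window, as a percentage of
#' the total lane density from the well down to the ~100 nt marker. The
#' ratio is invariant to uniform rescaling of the lane, so the result is a
#' relative termination efficiency, not an absolute yield.
#'
#' @param profile A [lane_profile()].
#' @param cal A `ladder_calibration`.
#' @param regions A [quant_regions()] (default: TP window 92-140 nt, total
#'   window down to the 100 nt marker inclusive, wells included).
#' @return Termination-product percentage (0-100).
#' @export
quantify_tp_fraction <- function(profile, cal, regions = quant_regions()) {
  stopifnot(inherits(profile, "lane_profile"),
            inherits(cal, "ladder_calibration"),
            inherits(regions, "quant_regions"))
  px <- seq_along(profile$density)
  len <- pixel_to_length(cal, px)
  if (regions$tp_window[1] < min(cal$knots$length) ||
      regions$tp_window[2] > max(cal$knots$length))
    stop("TP window lies (partly) outside the calibration hull",
         call. = FALSE)
  cutoff_px <- length_to_pixel(cal, regions$lower_cutoff)
  in_total <- px >= (if (regions$include_wells) profile$well_pixel
                     else profile$well_pixel + 1L) &
    (if (regions$include_cutoff) px <= cutoff_px else px < cutoff_px)
  in_tp <- len >= regions$tp_window[1] & len <= regions$tp_window[2]
  total <- sum(profile$density[in_total])
  if (total <= 0) stop("zero total density in the total window",
                       call. = FALSE)
  100 * sum(profile$density[in_tp & in_total]) / total
}

#' Normalize a lane to its maximum within a length window
#'
#' Divides every pixel density by the maximum density whose calibrated
#' length falls in `window` (default 92-140 nt, the TP1-TP3 region), so
#' lanes can be overlaid for band-position comparison. Idempotent.
#'
#' @param profile A [lane_profile()].
#' @param cal A `ladder_calibration`.
#' @param window Length window in nt.
#' @return A normalized [lane_profile()].
#' @export
normalize_profile <- function(profile, cal, window = c(92, 140)) {
  stopifnot(inherits(profile, "lane_profile"), length(window) == 2L)
  len <- pixel_to_length(cal, seq_along(profile$density))
  sel <- len >= window[1] & len <= window[2]
  if (!any(sel))
    stop("normalization window maps outside the profile", call. = FALSE)
  mx <- max(profile$density[sel])
  if (mx <= 0) stop("zero maximum density in the normalization window",
                    call. = FALSE)
  lane_profile(profile$density / mx, lane_id = profile$lane_id,
               well_pixel = profile$well_pixel)
}

#' Call band peaks in a calibrated lane
#'
#' Finds local maxima above a height threshold (relative to the lane
#' maximum) via [pracma::findpeaks()], converts their pixel positions to
#' lengths through the calibration, and — when a transcription start site
#' is supplied — maps each length to the reference position of the
#' transcript 3' end via [transcript_end_position()].
#'
#' @param profile A (typically normalized) [lane_profile()].
#' @param cal A `ladder_calibration`.
#' @param min_prominence Minimum peak height as a fraction of the lane
#'   maximum (default 0.05).
#' @param tss_rcrs Optional transcription start site (rCRS position) for
#'   3'-end mapping.
#' @return A data.frame with columns `pixel`, `length_nt`, `height`, and
#'   `end_rcrs` when `tss_rcrs` is given; zero rows when no peak
#'   qualifies.
#' @export
call_peaks <- function(profile, cal, min_prominence = 0.05,
                       tss_rcrs = NULL) {
  stopifnot(inherits(profile, "lane_profile"),
            inherits(cal, "ladder_calibration"))
  y <- profile$density
  empty <- data.frame(pixel = integer(), length_nt = numeric(),
                      height = numeric())
  if (max(y) <= 0) return(empty)
  pk <- pracma::findpeaks(y, minpeakheight = min_prominence * max(y))
  if (is.null(pk)) return(empty)
  out <- data.frame(pixel = as.integer(pk[, 2]),
                    length_nt = as.numeric(pixel_to_length(cal, pk[, 2])),
                    height = as.numeric(pk[, 1]))
  out <- out[order(out$pixel), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(tss_rcrs))
    out$end_rcrs <- vapply(round(out$length_nt), function(L)
      transcript_end_position(tss_rcrs, L), 1L)
  out
}
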