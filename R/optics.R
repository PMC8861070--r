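#' Summed ROI emission from a fiber image
#'
#' Emission at a viewing angle is quantified as the sum of gamma-uncorrected
#' pixel intensities over a region of interest delineating the polished,
#' side-emitting segment of the fiber.
#'
#' @param image Numeric grayscale pixel matrix.
#' @param roi Region of interest: a logical matrix of the same shape, or a
#'   two-column matrix of (row, col) pixel indices.
#' @return The scalar summed intensity.
#' @export
emission_at_angle <- function(image, roi) {
  if (!is.matrix(image) || !is.numeric(image)) abort("`image` must be a numeric matrix.")
  if (is.logical(roi)) {
    if (!all(dim(roi) == dim(image))) abort("logical `roi` must match image dimensions.")
    if (!any(roi)) abort("`roi` is empty.")
    return(sum(image[roi]))
  }
  roi <- as.matrix(roi)
  if (nrow(roi) == 0) abort("`roi` is empty.")
  if (any(roi < 1) || any(roi[, 1] > nrow(image)) || any(roi[, 2] > ncol(image))) {
    abort("`roi` indices fall outside the image.")
  }
  sum(image[roi])
}

#' Angle-resolved emission profile of a side-emitting fiber
#'
#' @param angles_deg Viewing angles in degrees within `[0, 90]`; 0 is radial
#'   (normal to the fiber surface), 90 axial. Typically measured in 25 degree
#'   increments.
#' @param emission Non-negative summed ROI intensities, one per angle.
#' @return A tibble of class `emission_profile`.
#' @export
emission_profile <- function(angles_deg, emission) {
  if (length(angles_deg) != length(emission)) abort("angle/emission lengths differ.")
  if (any(angles_deg < 0 | angles_deg > 90)) abort("angles must lie in [0, 90] degrees.")
  if (any(emission < 0)) abort("emission values must be >= 0.")
  structure(tibble::tibble(angle_deg = angles_deg, emission = emission),
            class = c("emission_profile", class(tibble::tibble())))
}

#' Fit a Lambertian (cosine) emission law
#'
#' A Lambertian emitter obeys `I(angle) = I0 * cos(angle)`. The single
#' coefficient `I0` is estimated by least squares over the measured profile
#' (closed form: `I0 = sum(I * cos) / sum(cos^2)`).
#'
#' @param profile An [emission_profile()] (or tibble with `angle_deg`,
#'   `emission`).
#' @return An object of class `lambertian_fit` with elements `I0`,
#'   `residual_norm`, `r_squared`, `fitted`, `data`. `tidy()` and `glance()`
#'   methods are provided.
#' @export
fit_lambertian <- function(profile) {
  a <- profile$angle_deg
  y <- profile$emission
  if (length(unique(a)) < 2) abort("need at least 2 distinct angles.")
  cth <- cos(a * pi / 180)
  if (all(abs(cth) < 1e-12)) abort("degenerate design: all angles at 90 degrees.")
  I0 <- sum(y * cth) / sum(cth^2)
  fitted <- I0 * cth
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  structure(list(
    I0 = I0,
    residual_norm = sqrt(sum(res^2)),
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    fitted = fitted,
    data = tibble::tibble(angle_deg = a, emission = y, fitted = fitted)
  ), class = "lambertian_fit")
}

#' @export
print.lambertian_fit <- function(x, ...) {
  cat(sprintf("<lambertian_fit> I0 = %.4g, residual norm = %.4g\n",
              x$I0, x$residual_norm))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.lambertian_fit <- function(x, ...) {
  tibble::tibble(term = "I0", estimate = x$I0)
}

#' @export
#' @importFrom generics glance
glance.lambertian_fit <- function(x, ...) {
  tibble::tibble(I0 = x$I0, residual_norm = x$residual_norm,
                 r_squared = x$r_squared, n = nrow(x$data))
}

#' Plot a Lambertian fit against its data
#' @param object A `lambertian_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lambertian_fit <- function(object, ...) {
  grid <- tibble::tibble(angle_deg = seq(0, 90, by = 1))
  grid$fitted <- object$I0 * cos(grid$angle_deg * pi / 180)
  ggplot2::ggplot(object$data, ggplot2::aes(angle_deg, emission)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = fitted), colour = "steelblue") +
    ggplot2::labs(x = "angle from fiber normal (deg)", y = "summed ROI emission",
                  title = sprintf("I0 = %.3g", object$I0)) +
    ggplot2::theme_minimal()
}

#' Cylindrical power density around a side-emitting fiber
#'
#' Assumes the emitted light passes through a cylindrical surface of the
#' evaluation radius surrounding the emitting segment:
#' `density = total_power / (2 * pi * eval_radius * emitting_length)`.
#'
#' @param total_power Light power exiting the fiber segment, mW.
#' @param emitting_length Length of the side-emitting segment, mm.
#' @param eval_radius Radius of the evaluation cylinder, mm (>= the fiber
#'   radius; e.g. 0.015 mm at the fiber surface, 0.1 mm at the spike
#'   detection horizon).
#' @param fiber_radius Fiber radius, mm (default 0.015).
#' @return A tibble with `eval_radius_mm`, `area_mm2`, `density_mW_mm2`.
#' @export
power_density <- function(total_power, emitting_length = 2, eval_radius = 0.015,
                          fiber_radius = 0.015) {
  if (emitting_length <= 0 || fiber_radius <= 0 || any(eval_radius <= 0)) {
    abort("geometry values must be positive.")
  }
  if (total_power < 0) abort("`total_power` must be >= 0.")
  if (any(eval_radius < fiber_radius)) {
    abort("`eval_radius` must be >= the fiber radius.")
  }
  area <- 2 * pi * eval_radius * emitting_length
  tibble::tibble(eval_radius_mm = eval_radius, area_mm2 = area,
                 density_mW_mm2 = total_power / area)
}

#' Addressable fibers on a square connector grid
#'
#' Counts square-lattice positions at the given pitch that fit inside a
#' square of the given area (floor per side). At a 100 um pitch, 1 mm^2
#' accommodates 100 individually addressable fibers.
#'
#' @param pitch_mm Center-to-center fiber spacing, mm.
#' @param area_mm2 Available connector area, mm^2.
#' @return Integer fiber count.
#' @export
addressable_fibers <- function(pitch_mm, area_mm2 = 1) {
  if (pitch_mm <= 0) abort("`pitch_mm` must be > 0.")
  if (area_mm2 < 0) abort("`area_mm2` must be >= 0.")
  side <- sqrt(area_mm2)
  per_side <- floor(side / pitch_mm + 1e-9)
  as.integer(per_side^2)
}

#' PVR transfer curve of one fiber configuration
#'
#' Per-channel photovoltaic-response amplitude time courses at a set of
#' increasing light-intensity levels, used to compare illumination
#' efficiency between fiber configurations.
#'
#' @param amplitudes 3-d array `[channel, intensity, time]` of PVR amplitudes
#'   (uV).
#' @param intensities Strictly increasing photodiode intensity levels.
#' @param linear_limit PVR amplitude up to which the intensity relation is
#'   linear (uV, default 1000).
#' @param saturation Saturation amplitude (uV, default 6000).
#' @return A list of class `pvr_transfer_curve`.
#' @export
pvr_transfer_curve <- function(amplitudes, intensities, linear_limit = 1000,
                               saturation = 6000) {
  if (length(dim(amplitudes)) != 3) abort("`amplitudes` must be [channel, intensity, time].")
  if (dim(amplitudes)[2] != length(intensities)) {
    abort("second dimension of `amplitudes` must match `intensities`.")
  }
  if (any(diff(intensities) <= 0)) abort("intensities must be strictly increasing.")
  if (!all(is.finite(amplitudes))) abort("amplitudes must be finite.")
  structure(list(amplitudes = amplitudes, intensities = intensities,
                 linear_limit = linear_limit, saturation = saturation),
            class = "pvr_transfer_curve")
}

#' PVR-matched intensity ratio between two fiber configurations
#'
#' For each channel, the post-onset time point is found at which configuration
#' A's maximal-intensity PVR is closest to the linear limit (or, if it never
#' reaches it, the time of its maximal amplitude). Configuration B's intensity
#' producing the most similar PVR amplitude at that time point is then found
#' (by default with linear interpolation between measured intensity levels;
#' `interpolate = FALSE` snaps to the nearest level). The per-channel ratio is
#' A's maximal intensity divided by that B intensity; channels where B's curve
#' does not bracket the target amplitude are flagged and excluded from the
#' mean.
#'
#' @param curve_a,curve_b [pvr_transfer_curve()] objects sharing channels.
#' @param interpolate Interpolate between B's intensity levels (default TRUE).
#' @return A list with `per_channel` (tibble: `channel`, `time_index`,
#'   `target_uV`, `intensity_b`, `ratio`, `flagged`) and `mean_ratio`.
#' @export
intensity_ratio <- function(curve_a, curve_b, interpolate = TRUE) {
  stopifnot(inherits(curve_a, "pvr_transfer_curve"),
            inherits(curve_b, "pvr_transfer_curve"))
  nch <- dim(curve_a$amplitudes)[1]
  if (dim(curve_b$amplitudes)[1] != nch) abort("curves must share channels.")
  imax_a <- length(curve_a$intensities)
  per <- purrr::map_dfr(seq_len(nch), function(c) {
    tc_a <- curve_a$amplitudes[c, imax_a, ]        # max-intensity time course
    if (max(tc_a) >= curve_a$linear_limit) {
      ti <- which.min(abs(tc_a - curve_a$linear_limit))
    } else {
      ti <- which.max(tc_a)
    }
    target <- tc_a[ti]
    amp_b <- curve_b$amplitudes[c, , ti]           # B amplitude vs intensity at ti
    flag <- target < min(amp_b) || target > max(amp_b)
    if (flag) {
      ib <- NA_real_
    } else if (interpolate) {
      ib <- stats::approx(amp_b, curve_b$intensities, xout = target, ties = "ordered")$y
    } else {
      ib <- curve_b$intensities[which.min(abs(amp_b - target))]
    }
    tibble::tibble(channel = c, time_index = ti, target_uV = target,
                   intensity_b = ib,
                   ratio = curve_a$intensities[imax_a] / ib,
                   flagged = flag)
  })
  list(per_channel = per,
       mean_ratio = mean(per$ratio[!per$flagged], na.rm = TRUE))
}

#' Read a grayscale fiber image (PNG or TIFF)
#'
#' Gamma-uncorrected pixel intensities are used as stored; color images are
#' averaged to one channel.
#'
#' @param path Path to an 8/16-bit PNG or TIFF file.
#' @return A numeric pixel matrix (rows x columns).
#' @export
read_fiber_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) abort("package 'png' required.")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) abort("package 'tiff' required.")
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Rasterize a polygon ROI (e.g. from a JSON sidecar) to a pixel mask
#'
#' Even-odd ray casting; vertices are (row, col) pixel coordinates, and a
#' pixel belongs to the ROI when its centre lies inside the polygon.
#'
#' @param vertices Two-column matrix of polygon vertices (row, col), or a
#'   path to a JSON file with fields `row` and `col`.
#' @param dim Image dimensions `c(rows, cols)`.
#' @return A logical rows x cols matrix.
#' @export
roi_from_polygon <- function(vertices, dim) {
  if (is.character(vertices)) {
    v <- jsonlite::read_json(vertices, simplifyVector = TRUE)
    vertices <- cbind(v$row, v$col)
  }
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  px <- as.vector(row(matrix(0, dim[1], dim[2])))
  py <- as.vector(col(matrix(0, dim[1], dim[2])))
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- vertices[i, 1]; xi <- vertices[i, 2]
    yj <- vertices[j, 1]; xj <- vertices[j, 2]
    cross <- ((xi > py) != (xj > py)) &
      (px < (yj - yi) * (py - xi) / (xj - xi) + yi)
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, dim[1], dim[2])
}
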