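#' Camera model for a nadir-pointing drone sensor
#'
#' Bundles the intrinsic parameters needed to map pixel measurements to
#' metres on the sea surface: image size, focal length in pixel units,
#' principal point, and Brown--Conrady radial distortion coefficients.
#' Intrinsics are accepted as inputs (e.g. from an external calibration
#' tool); no calibration is performed here.
#'
#' @param sensor_label Either `"RGB"` or `"TIR"`.
#' @param image_width,image_height Image size in pixels.
#' @param focal_length Focal length in pixels (> 0).
#' @param principal_point Numeric length-2, pixel coordinates of the optical
#'   centre. Defaults to the image centre. Must lie inside the image.
#' @param radial_distortion Up to three Brown--Conrady radial coefficients
#'   (k1, k2, k3); shorter vectors are zero-padded.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model("TIR", 640, 512, focal_length = 1000)
#' ground_sample_distance(cam, flight_context(90))
#' @export
camera_model <- function(sensor_label = c("RGB", "TIR"),
                         image_width, image_height,
                         focal_length,
                         principal_point = NULL,
                         radial_distortion = c(0, 0, 0)) {
  sensor_label <- match.arg(sensor_label)
  stopifnot(is.numeric(image_width), image_width > 0,
            is.numeric(image_height), image_height > 0,
            is.numeric(focal_length), focal_length > 0)
  if (is.null(principal_point)) {
    principal_point <- c(image_width / 2, image_height / 2)
  }
  if (length(principal_point) != 2 || !all(is.finite(principal_point))) {
    stop("principal_point must be two finite numbers", call. = FALSE)
  }
  if (principal_point[1] < 0 || principal_point[1] > image_width ||
      principal_point[2] < 0 || principal_point[2] > image_height) {
    stop("principal point must lie inside the image bounds", call. = FALSE)
  }
  k <- as.numeric(radial_distortion)
  if (length(k) > 3) stop("at most three radial coefficients", call. = FALSE)
  k <- c(k, rep(0, 3 - length(k)))
  structure(
    list(sensor_label = sensor_label,
         image_width = as.numeric(image_width),
         image_height = as.numeric(image_height),
         focal_length = as.numeric(focal_length),
         principal_point = as.numeric(principal_point),
         radial_distortion = k),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera model [%s]: %dx%d px, f = %.1f px, pp = (%.1f, %.1f)\n",
              x$sensor_label, x$image_width, x$image_height, x$focal_length,
              x$principal_point[1], x$principal_point[2]))
  cat(sprintf("  radial distortion k1..k3: %s\n",
              paste(signif(x$radial_distortion, 6), collapse = ", ")))
  invisible(x)
}

#' Flight context for photogrammetric scaling
#'
#' @param altitude Altitude above sea level, metres (> 0).
#' @param altitude_sd Reported altitude variability, metres (>= 0).
#'   Barometric telemetry on small drones typically holds this within
#'   about half a metre at survey altitude.
#' @param nadir Logical; `TRUE` when the camera points straight down.
#'   Oblique frames are refused by the measurement functions.
#' @return An object of class `flight_context`.
#' @export
flight_context <- function(altitude, altitude_sd = 0.5, nadir = TRUE) {
  stopifnot(is.numeric(altitude), altitude >= 0,
            is.numeric(altitude_sd), altitude_sd >= 0,
            is.logical(nadir))
  structure(list(altitude = as.numeric(altitude),
                 altitude_sd = as.numeric(altitude_sd),
                 nadir = isTRUE(nadir)),
            class = "flight_context")
}

#' Remove radial lens distortion from a pixel coordinate
#'
#' Applies the Brown--Conrady radial polynomial at the observed pixel's
#' radius from the principal point:
#' `corrected = c + (p - c) * (1 + k1 r^2 + k2 r^4 + k3 r^6)`.
#' With all coefficients zero this is the identity, and the principal point
#' itself is always a fixed point.
#'
#' @param p Numeric length-2 pixel coordinate (x, y).
#' @param cam A [camera_model()].
#' @return Corrected pixel coordinate, numeric length 2.
#' @export
undistort_point <- function(p, cam) {
  stopifnot(inherits(cam, "camera_model"))
  p <- as.numeric(p)
  if (length(p) != 2 || !all(is.finite(p))) {
    stop("point coordinates must be two finite numbers", call. = FALSE)
  }
  d <- p - cam$principal_point
  r2 <- sum(d^2)
  k <- cam$radial_distortion
  scale <- 1 + k[1] * r2 + k[2] * r2^2 + k[3] * r2^3
  cam$principal_point + d * scale
}

#' Ground sample distance at nadir
#'
#' Metres of sea surface covered by one pixel for a nadir view:
#' `altitude / focal_length`. Strictly increasing in altitude and
#' decreasing in focal length. Oblique geometry is refused because ground
#' scale is then no longer uniform across the frame.
#'
#' @param cam A [camera_model()].
#' @param ctx A [flight_context()] with `nadir = TRUE`.
#' @return Metres per pixel.
#' @export
ground_sample_distance <- function(cam, ctx) {
  stopifnot(inherits(cam, "camera_model"), inherits(ctx, "flight_context"))
  if (!ctx$nadir) {
    stop("unsupported geometry: ground sample distance requires a nadir view",
         call. = FALSE)
  }
  ctx$altitude / cam$focal_length
}

#' Measure a real-world length between two annotated pixels
#'
#' Undistorts both endpoints, takes their Euclidean pixel distance, and
#' scales by the ground sample distance. Used for body length (rostrum tip
#' to fluke notch), fluke span (tip to tip) and flukeprint width
#' (endpoints of the axis parallel to the fluke).
#'
#' @param p1,p2 Pixel coordinates, numeric length 2 each.
#' @param cam A [camera_model()].
#' @param ctx A [flight_context()]; must be nadir.
#' @return Length in metres; 0 for coincident points.
#' @export
measure_length <- function(p1, p2, cam, ctx) {
  gsd <- ground_sample_distance(cam, ctx)
  u1 <- undistort_point(p1, cam)
  u2 <- undistort_point(p2, cam)
  sqrt(sum((u1 - u2)^2)) * gsd
}

#' Validate measurement accuracy against a reference object
#'
#' Compares repeated photogrammetric length measurements of an object of
#' known physical length (e.g. a survey vessel) and reports the mean
#' absolute error and the relative error (MAE / true length).
#'
#' @param measurements Numeric vector of measured lengths, metres (>= 1).
#' @param true_length Known physical length, metres (> 0).
#' @return An object of class `reference_validation` with fields
#'   `true_length`, `measured_lengths`, `mean_abs_error`, `rel_error`.
#' @examples
#' validate_reference(c(5.35, 5.65), 5.5)
#' @export
validate_reference <- function(measurements, true_length) {
  measurements <- as.numeric(measurements)
  if (length(measurements) < 1 || !all(is.finite(measurements))) {
    stop("need at least one finite measurement", call. = FALSE)
  }
  stopifnot(is.numeric(true_length), true_length > 0)
  mae <- mean(abs(measurements - true_length))
  structure(
    list(true_length = true_length,
         measured_lengths = measurements,
         mean_abs_error = mae,
         rel_error = mae / true_length),
    class = "reference_validation")
}

#' @export
print.reference_validation <- function(x, ...) {
  cat(sprintf(
    "Reference validation: true length %.3f m, n = %d, MAE = %.3f m (%.2f%%)\n",
    x$true_length, length(x$measured_lengths),
    x$mean_abs_error, 100 * x$rel_error))
  invisible(x)
}

# world metres (ENU, origin at the principal point's ground footprint)
# <-> pixel (origin top-left, x right, y down). North (+y world) maps to
# -y in pixels.
world_to_pixel <- function(xy_m, cam, gsd) {
  cbind(cam$principal_point[1] + xy_m[, 1] / gsd,
        cam$principal_point[2] - xy_m[, 2] / gsd)
}

pixel_to_world <- function(xy_px, cam, gsd) {
  cbind((xy_px[, 1] - cam$principal_point[1]) * gsd,
        -(xy_px[, 2] - cam$principal_point[2]) * gsd)
}
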