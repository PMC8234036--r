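#' Camera specification for coverage planning
#'
#' @param horizontal_fov horizontal field of view in degrees, in (0, 360].
#' @param range detection range in meters; flocks are resolvable up to
#'   about 300 m with the reference optics, hence the default.
#' @return object of class `camera_spec`.
#' @export
camera_spec <- function(horizontal_fov, range = 300) {
  if (horizontal_fov <= 0 || horizontal_fov > 360) {
    stop("horizontal_fov must lie in (0, 360] degrees")
  }
  if (range <= 0) stop("range must be positive")
  structure(list(horizontal_fov = horizontal_fov, range = range),
            class = "camera_spec")
}

#' Detectors needed for full 360-degree coverage
#'
#' The monitored area is a disc of radius `range` centered on the camera
#' mast; each camera sweeps a sector of `horizontal_fov` degrees, so
#' `360 / fov` cameras tile the full circle. The fractional count is
#' reported to one decimal, alongside the nearest-integer recommendation
#' (8.1 cameras means nine leave a margin and eight leave a 2.6-degree
#' gap — the fractional figure makes that trade explicit).
#'
#' @param spec a [camera_spec()].
#' @return object of class `coverage_plan`: `count` (fractional, one
#'   decimal), `cameras` (nearest integer), `horizontal_fov`, `range`.
#' @examples
#' detectors_for_full_circle(camera_spec(44.6))$count  # 8.1
#' detectors_for_full_circle(camera_spec(64.5))$count  # 5.6
#' @export
detectors_for_full_circle <- function(spec) {
  stopifnot(inherits(spec, "camera_spec"))
  exact <- 360 / spec$horizontal_fov
  structure(list(count = round_half_up(exact, 1),
                 cameras = as.integer(round_half_up(exact, 0)),
                 horizontal_fov = spec$horizontal_fov,
                 range = spec$range),
            class = "coverage_plan")
}

#' @export
print.coverage_plan <- function(x, ...) {
  cat(sprintf("360-degree coverage at FOV %g deg, range %g m:\n",
              x$horizontal_fov, x$range))
  cat(sprintf("  %.1f detectors (nearest integer: %d)\n", x$count, x$cameras))
  invisible(x)
}

#' Does a camera sector cover a target?
#'
#' A target is covered when its bearing lies within half the field of view
#' of the camera bearing (wrapped on the circle, sector edges inclusive)
#' and its distance does not exceed the camera range (300 m exactly is
#' covered).
#'
#' @param spec a [camera_spec()].
#' @param camera_bearing,target_bearing bearings in degrees, \[0, 360).
#' @param target_distance meters, >= 0.
#' @return logical.
#' @export
sector_covers <- function(spec, camera_bearing, target_bearing,
                          target_distance) {
  stopifnot(inherits(spec, "camera_spec"))
  if (target_distance < 0) stop("target_distance must be >= 0")
  offset <- abs(((target_bearing - camera_bearing + 180) %% 360) - 180)
  offset <= spec$horizontal_fov / 2 + 1e-9 &&
    target_distance <= spec$range
}
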