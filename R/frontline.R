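#' Stokes settling velocity of a spherical particle
#'
#' Terminal fall speed under Stokes drag,
#' \eqn{v = \rho d^2 g / (18 \mu)}, with g = 981 cm/s^2 and air viscosity
#' \eqn{\mu = 1.8\times10^{-4}} g/(cm s). Respiratory droplets are taken as
#' aqueous (density 1 g/cm^3), so the diameter doubles as the aerodynamic
#' diameter. When the particle Reynolds number
#' \eqn{Re = \rho_{air} v d / \mu} exceeds 1 the Stokes regime no longer
#' strictly holds and the `stokes_ok` attribute is set `FALSE`; the value is
#' still returned (it overestimates the true fall speed, which is
#' conservative when used as an exclusion cutoff).
#'
#' @param diameter_um particle diameter, µm (> 0); vectorized.
#' @param density particle density, g/cm^3 (> 0).
#' @return Settling velocity in cm/s with attributes `reynolds` and
#'   `stokes_ok`.
#' @export
#' @examples
#' settling_velocity(10)    # ~0.30 cm/s
#' settling_velocity(300)   # fast-falling; Stokes flag lowered
settling_velocity <- function(diameter_um, density = 1.0) {
  if (!is.numeric(diameter_um) || any(diameter_um <= 0))
    stop("settling_velocity: diameter must be > 0")
  if (!is.numeric(density) || density <= 0)
    stop("settling_velocity: density must be > 0")
  g <- 981            # cm/s^2
  mu <- 1.8e-4        # g/(cm s), air at room temperature
  rho_air <- 1.2e-3   # g/cm^3
  d_cm <- diameter_um * 1e-4
  v <- density * d_cm^2 * g / (18 * mu)
  re <- rho_air * v * d_cm / mu
  structure(v, reynolds = re, stokes_ok = re <= 1)
}

#' Exclude fast-falling large droplets from a vector field
#'
#' Marks as excluded every valid vector whose downward velocity exceeds the
#' settling velocity of a droplet of `diameter_cutoff_um` — the kinematic
#' signature of droplets too large to ride the air flow. Sizing acts on
#' fall speed rather than apparent image size because individual particles
#' are below the spatial resolution of the measurement. Retained vectors
#' are untouched (pure filtering).
#'
#' @param field a `vector_field` data frame.
#' @param diameter_cutoff_um diameter cutoff, µm (default 300).
#' @param density droplet density, g/cm^3.
#' @return The field with the `excluded` column updated.
#' @export
exclude_fast_falling <- function(field, diameter_cutoff_um = 300,
                                 density = 1.0) {
  stopifnot(is.data.frame(field))
  if (diameter_cutoff_um <= 0)
    stop("exclude_fast_falling: cutoff must be > 0")
  v_cut <- as.numeric(settling_velocity(diameter_cutoff_um, density))
  field$excluded <- field$excluded |
    (field$valid & !is.na(field$vy_cms) & field$vy_cms > v_cut)
  field
}

#' Extract the front-line (distal margin) series
#'
#' For each tracked instant inside the analysis window, selects the valid,
#' non-excluded vector at the greatest horizontal distance from the mouth —
#' the margin of the advancing cloud — and records its time, distance and
#' horizontal velocity. Instants with no qualifying vector are skipped.
#' The first ~0.04 s are normally excluded because the fresh cloud is too
#' dense to resolve individual particle motion.
#'
#' @param field a `vector_field` data frame (one or many frame pairs; must
#'   carry a `pixel_size` attribute or be accompanied by `pixel_size`).
#' @param mouth (x, y) mouth position in px; defaults to the field's
#'   `mouth_position` attribute.
#' @param direction `"x+"` (expectoration along +x, default) or `"x-"`.
#' @param window analysis window `c(t_min, t_max)` in s.
#' @param pixel_size cm per px; defaults to the field attribute.
#' @param label event label, `"sneeze"` or `"cough"` (bookkeeping).
#' @param quantile_q optional: instead of the single most distal vector,
#'   average the vectors in the top `quantile_q` quantile of distance
#'   (disabled when `NULL`).
#' @param require_advance if `TRUE` (default), only vectors moving forward
#'   (`Vh > 0`) qualify as the front margin: the front line is the edge of
#'   an advancing cloud, and distal windows with backward motion are
#'   diffusion-regime scatter, not the front.
#' @return A `frontline_series` data frame with columns `t_s`, `h_cm`,
#'   `vh_cms`, sorted by time, plus `window` and `label` attributes.
#' @export
extract_frontline <- function(field, mouth = NULL, direction = "x+",
                              window = c(0.04, 0.20), pixel_size = NULL,
                              label = "sneeze", quantile_q = NULL,
                              require_advance = TRUE) {
  stopifnot(is.data.frame(field))
  if (is.null(pixel_size)) pixel_size <- attr(field, "pixel_size")
  if (is.null(mouth)) mouth <- attr(field, "mouth_position")
  if (is.null(pixel_size) || is.null(mouth))
    stop("extract_frontline: pixel_size and mouth must be available")
  sgn <- switch(direction, "x+" = 1, "x-" = -1,
                stop("extract_frontline: direction must be 'x+' or 'x-'"))
  ok <- field$valid & !field$excluded &
    field$t_s >= window[1] & field$t_s <= window[2]
  f <- field[ok, , drop = FALSE]
  f$h_cm <- sgn * (f$cx_px - mouth[1]) * pixel_size
  f$vh_cms <- sgn * f$vx_cms
  f <- f[f$h_cm >= 0, , drop = FALSE]
  if (require_advance) f <- f[f$vh_cms > 0, , drop = FALSE]
  if (nrow(f) == 0)
    stop("extract_frontline: no qualifying vectors in the analysis window; ",
         "review the window, texture/peak thresholds or droplet cutoff")
  pick <- function(g) {
    if (is.null(quantile_q)) {
      g[which.max(g$h_cm), c("t_s", "h_cm", "vh_cms")]
    } else {
      top <- g[g$h_cm >= stats::quantile(g$h_cm, 1 - quantile_q), ,
               drop = FALSE]
      data.frame(t_s = g$t_s[1], h_cm = mean(top$h_cm),
                 vh_cms = mean(top$vh_cms))
    }
  }
  out <- do.call(rbind, lapply(split(f, f$t_s), pick))
  out <- out[order(out$t_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "label") <- label
  class(out) <- c("frontline_series", "data.frame")
  out
}

#' Distance-time-velocity table of all valid vectors
#'
#' The full cloud picture: one row per valid, non-excluded vector with its
#' time, horizontal distance from the mouth and horizontal velocity — the
#' table behind a distance-time plot of the cloud colored by velocity.
#'
#' @inheritParams extract_frontline
#' @return Data frame with columns `t_s`, `h_cm`, `vh_cms` (possibly empty).
#' @export
export_velocity_map <- function(field, mouth = NULL, direction = "x+",
                                pixel_size = NULL) {
  stopifnot(is.data.frame(field))
  if (is.null(pixel_size)) pixel_size <- attr(field, "pixel_size")
  if (is.null(mouth)) mouth <- attr(field, "mouth_position")
  if (is.null(pixel_size) || is.null(mouth))
    stop("export_velocity_map: pixel_size and mouth must be available")
  sgn <- if (direction == "x-") -1 else 1
  f <- field[field$valid & !field$excluded, , drop = FALSE]
  data.frame(t_s = f$t_s,
             h_cm = sgn * (f$cx_px - mouth[1]) * pixel_size,
             vh_cms = sgn * f$vx_cms)
}

#' Write a front-line series as CSV with a JSON sidecar
#'
#' @param series a `frontline_series`.
#' @param path CSV output path; sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_frontline <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("t_s", "h_cm", "vh_cms")],
                   path, row.names = FALSE)
  jsonlite::write_json(list(label = attr(series, "label"),
                            window = attr(series, "window")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
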