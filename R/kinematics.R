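#' Exponential velocity-decay model of a plume front
#'
#' Container for the fitted coefficients of the front-line horizontal
#' velocity model \eqn{V_h(t) = A e^{-kt} + c}. The amplitude \eqn{A}
#' (cm/s) is the extrapolated initial front velocity, \eqn{k} (1/s) the
#' decay rate set by air drag on the cloud, and \eqn{c} (cm/s) an additive
#' offset capturing a steady ambient flow (room draught) that the front
#' relaxes onto. Reference values for a sneeze are A = 1500 cm/s, k = 22 1/s,
#' c = 0; for a cough in a draughty room A = 1100 cm/s, k = 32 1/s,
#' c = 27 cm/s.
#'
#' @param A amplitude, cm/s; must be positive.
#' @param k decay rate, 1/s; must be positive.
#' @param c velocity offset (ambient plateau), cm/s; non-negative.
#' @param rms root-mean-square fit residual, cm/s (NA if not fitted).
#' @param n_points number of points the model was fitted to (NA if exact).
#' @return An object of class `decay_model`.
#' @export
#' @examples
#' sneeze <- decay_model(1500, 22, 0)
#' evaluate_velocity(sneeze, 0.1)
decay_model <- function(A, k, c = 0, rms = NA_real_, n_points = NA_integer_) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (A <= 0) stop("decay_model: amplitude A must be > 0")
  if (k <= 0) stop("decay_model: rate k must be > 0")
  if (c < 0) stop("decay_model: offset c must be >= 0")
  structure(list(A = A, k = k, c = c, rms = rms,
                 n_points = as.integer(n_points)),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("Velocity-decay model: Vh(t) = %.4g * exp(-%.4g t) + %.4g cm/s\n",
              x$A, x$k, x$c))
  if (!is.na(x$rms))
    cat(sprintf("  fit RMS %.3g cm/s over %d points\n", x$rms, x$n_points))
  invisible(x)
}

#' Evaluate the front velocity model at given times
#'
#' @param model a [decay_model()].
#' @param t time(s) since release, s; must be non-negative.
#' @return Horizontal front velocity in cm/s, same length as `t`.
#' @export
evaluate_velocity <- function(model, t) {
  stopifnot(inherits(model, "decay_model"), is.numeric(t))
  if (any(t < 0)) stop("evaluate_velocity: t must be >= 0")
  model$A * exp(-model$k * t) + model$c
}

#' Fit the exponential decay model to a front-line series
#'
#' Least-squares fit of \eqn{V_h(t) = A e^{-kt} + c} by Levenberg-Marquardt
#' (via \pkg{minpack.lm}), initialized from a linear regression of
#' \eqn{\log(V_h - c_0)} on \eqn{t}. The offset can be left free, pinned to
#' a known ambient velocity (`fix_offset = 27` mirrors the cough analysis),
#' or pinned to the plateau read off the data (`fix_offset = "plateau"`,
#' the mean of the final three points — how the cough's ~30 cm/s plateau is
#' turned into the written offset).
#'
#' @param series a `frontline_series` or any data frame with columns `t_s`
#'   and `vh_cms`.
#' @param fix_offset `NULL` (offset free), a numeric value in cm/s, or
#'   `"plateau"`.
#' @param robust if `TRUE`, iteratively reweight residuals with soft-L1
#'   weights to damp outliers in noisy front series.
#' @return A [decay_model()] carrying the residual RMS and point count.
#' @export
fit_decay <- function(series, fix_offset = NULL, robust = FALSE) {
  df <- as.data.frame(series)
  if (!all(c("t_s", "vh_cms") %in% names(df)))
    stop("fit_decay: series must have columns t_s and vh_cms")
  t <- df$t_s
  v <- df$vh_cms
  keep <- is.finite(t) & is.finite(v)
  t <- t[keep]; v <- v[keep]
  if (length(t) < 4L)
    stop("fit_decay: need at least 4 points, got ", length(t))
  if (any(v <= 0))
    stop("fit_decay: velocities must be positive")

  fixed_c <- NULL
  if (!is.null(fix_offset)) {
    if (identical(fix_offset, "plateau")) {
      tail_v <- v[order(t)][pmax(1L, length(v) - 2L):length(v)]
      fixed_c <- mean(tail_v)
    } else {
      stopifnot(is.numeric(fix_offset), length(fix_offset) == 1L,
                fix_offset >= 0)
      fixed_c <- fix_offset
    }
  }

  # log-linear initialization: ln(v - c0) = ln A - k t
  c0 <- if (!is.null(fixed_c)) fixed_c else 0.5 * min(v)
  pos <- v - c0 > 0
  if (sum(pos) < 2L) { c0 <- 0; pos <- v > 0 }
  init_fit <- stats::lm(log(v[pos] - c0) ~ t[pos])
  A0 <- exp(unname(stats::coef(init_fit)[1]))
  k0 <- max(1e-3, -unname(stats::coef(init_fit)[2]))

  dat <- data.frame(t = t, v = v)
  wts <- rep(1, length(t))
  fit_once <- function(w) {
    if (is.null(fixed_c)) {
      minpack.lm::nlsLM(v ~ A * exp(-k * t) + c, data = dat,
                        start = list(A = A0, k = k0, c = max(c0, 1e-6)),
                        lower = c(A = 1e-9, k = 1e-9, c = 0),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(v ~ A * exp(-k * t) + fixed_c, data = dat,
                        start = list(A = A0, k = k0),
                        lower = c(A = 1e-9, k = 1e-9),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  fit <- tryCatch(fit_once(wts), error = function(e)
    stop("fit_decay: nonlinear fit failed to converge (init A=", signif(A0, 4),
         ", k=", signif(k0, 4), "): ", conditionMessage(e)))
  if (robust) {
    for (i in 1:3) {
      r <- stats::resid(fit)
      s <- stats::mad(r, constant = 1.4826)
      if (s <= 0) break
      wts <- 1 / sqrt(1 + (r / (3 * s))^2)  # soft-L1 style reweighting
      fit <- fit_once(wts)
    }
  }
  cf <- stats::coef(fit)
  rms <- sqrt(mean(stats::resid(fit)^2))
  decay_model(A = unname(cf["A"]), k = unname(cf["k"]),
              c = if (is.null(fixed_c)) unname(cf["c"]) else fixed_c,
              rms = rms, n_points = length(t))
}

#' Time at which the front velocity decays to a threshold
#'
#' Solves \eqn{A e^{-kt} + c = v} in closed form:
#' \eqn{t = \ln(A / (v - c)) / k}. With the natural-convection current taken
#' as the threshold (about 15 cm/s indoors) this is the momentum-loss time:
#' past it the cloud front drifts with the room air rather than its own
#' momentum.
#'
#' @param model a [decay_model()].
#' @param v_threshold threshold velocity, cm/s; must exceed the model offset
#'   `c` (otherwise the decaying term never brings `Vh` down to it).
#' @return Time in seconds.
#' @export
#' @examples
#' momentum_loss_time(decay_model(1500, 22, 0), 15)   # ~0.209 s
#' momentum_loss_time(decay_model(1100, 32, 27), 30)  # ~0.18 s
momentum_loss_time <- function(model, v_threshold) {
  stopifnot(inherits(model, "decay_model"),
            is.numeric(v_threshold), length(v_threshold) == 1L)
  if (v_threshold <= model$c)
    stop("momentum_loss_time: v_threshold (", v_threshold,
         " cm/s) must exceed the model offset c (", model$c,
         " cm/s); the velocity never reaches the threshold")
  log(model$A / (v_threshold - model$c)) / model$k
}

#' Direct reach: integrated front displacement over a time interval
#'
#' The momentum-driven advance of the front between `t_start` and `t_stop`,
#' obtained by integrating the velocity model in closed form:
#' \deqn{h(t_{stop}) = h_{anchor} + \frac{A}{k}\left(e^{-k t_{start}} -
#'   e^{-k t_{stop}}\right) + c\,(t_{stop} - t_{start}).}
#' The anchor `(t_start, h_anchor)` is explicit because the integration
#' constant — where the front actually is when the model window opens — is a
#' measurement, not part of the fitted model.
#'
#' @param model a [decay_model()].
#' @param t_start lower integration limit, s (the anchor time).
#' @param t_stop upper integration limit, s; may be `Inf`.
#' @param h_anchor front position at `t_start`, cm from the mouth.
#' @param v_threshold optional threshold recorded in the result (purely
#'   informational; use [momentum_loss_time()] to derive `t_stop` from it).
#' @return A `reach_result` list with fields `v_threshold`, `t_stop`,
#'   `t_anchor`, `h_anchor`, `reach` (cm from the mouth).
#' @export
#' @examples
#' m <- decay_model(1500, 22, 0)
#' direct_reach(m, 0, momentum_loss_time(m, 15))
direct_reach <- function(model, t_start = 0, t_stop, h_anchor = 0,
                         v_threshold = NA_real_) {
  stopifnot(inherits(model, "decay_model"),
            is.numeric(t_start), is.numeric(t_stop))
  if (t_start < 0) stop("direct_reach: t_start must be >= 0")
  if (t_stop < t_start) stop("direct_reach: t_stop must be >= t_start")
  offset_term <- if (model$c == 0) 0 else model$c * (t_stop - t_start)
  reach <- h_anchor +
    (model$A / model$k) * (exp(-model$k * t_start) - exp(-model$k * t_stop)) +
    offset_term
  structure(list(v_threshold = v_threshold, t_stop = t_stop,
                 t_anchor = t_start, h_anchor = h_anchor, reach = reach),
            class = "reach_result")
}

#' @export
print.reach_result <- function(x, ...) {
  cat(sprintf(
    "Direct reach: %.3g cm from the mouth (anchor %.3g cm at t=%.4g s, stop t=%.4g s)\n",
    x$reach, x$h_anchor, x$t_anchor, x$t_stop))
  invisible(x)
}

#' Momentum-loss time and reach from a threshold velocity
#'
#' Convenience composition: solve for the momentum-loss time at
#' `v_threshold`, then integrate the model from the anchor to that time.
#'
#' @inheritParams direct_reach
#' @inheritParams momentum_loss_time
#' @param t_anchor anchor time, s.
#' @return A `reach_result` (see [direct_reach()]).
#' @export
reach_from_threshold <- function(model, v_threshold, t_anchor = 0,
                                 h_anchor = 0) {
  t_stop <- momentum_loss_time(model, v_threshold)
  direct_reach(model, t_start = t_anchor, t_stop = t_stop,
               h_anchor = h_anchor, v_threshold = v_threshold)
}
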