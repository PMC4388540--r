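#' Time-activity curve
#'
#' A time-activity curve (TAC) is an activity concentration (arbitrary but
#' consistent units, e.g. kBq/mL) sampled once per frame of a
#' [frame_schedule()]. The `role` records what the curve represents; plasma
#' and whole-blood curves must be non-negative.
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric vector, one activity value per frame.
#' @param role One of `"tissue"`, `"reference"`, `"arterial_roi"`,
#'   `"background"`, `"plasma"`, `"whole_blood"`, `"rate"`.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values,
                role = c("tissue", "reference", "arterial_roi", "background",
                         "plasma", "whole_blood", "rate")) {
  role <- match.arg(role)
  if (!is_frame_schedule(schedule)) stop("schedule must be a frame_schedule")
  values <- as.numeric(values)
  if (length(values) != schedule$F)
    stop("need exactly one value per frame (", schedule$F, ")")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  if (role %in% c("plasma", "whole_blood") && any(values < -1e-12))
    stop(role, " TAC must be non-negative")
  structure(list(schedule = schedule, values = values, role = role),
            class = "tac")
}

is_tac <- function(x) inherits(x, "tac")

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac role=%s> %d frames, range [%.4g, %.4g]\n",
              x$role, x$schedule$F, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(frame_start_min = x$schedule$start,
             frame_duration_min = x$schedule$duration,
             midpoint_min = x$schedule$midpoint,
             value = x$values)
}

#' Cumulative trapezoidal integral of a TAC
#'
#' Integrates the curve from time 0 to `T` by the trapezoid rule over the
#' frame midpoints, with an initial node at (0, 0) — the standard dynamic-PET
#' convention for the running integrals used in graphical analysis. When `T`
#' falls inside a segment, the curve is interpolated linearly and the partial
#' trapezoid is added.
#'
#' @param x A [tac()].
#' @param T Upper limit(s) of integration in minutes; each must lie in
#'   `[0, last midpoint]`.
#' @return Numeric vector of areas (activity x min), one per element of `T`.
#' @export
trapz_integral <- function(x, T) {
  stopifnot(is_tac(x))
  tt <- c(0, x$schedule$midpoint)
  vv <- c(0, x$values)
  cum <- c(0, cumsum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2))
  last <- tt[length(tt)]
  out <- vapply(as.numeric(T), function(Ti) {
    if (!is.finite(Ti) || Ti < 0 || Ti > last + 1e-9)
      stop("T = ", Ti, " outside [0, ", last, "]")
    Ti <- min(Ti, last)
    i <- findInterval(Ti, tt, rightmost.closed = TRUE)
    vT <- vv[i] + (vv[i + 1] - vv[i]) * (Ti - tt[i]) /
      (tt[i + 1] - tt[i])
    if (Ti == tt[i]) cum[i] else cum[i] + (vv[i] + vT) / 2 * (Ti - tt[i])
  }, numeric(1))
  out
}

# running integral evaluated at every frame midpoint
cumint_midpoints <- function(x) trapz_integral(x, x$schedule$midpoint)

#' Finite-difference time derivative of a TAC
#'
#' Central differences on the (possibly non-uniform) midpoint grid, exact for
#' quadratics; one-sided two-point differences at the two ends. For noisy
#' curves the TAC can be pre-smoothed with a cubic smoothing spline.
#'
#' @param x A [tac()] with at least 3 frames.
#' @param smooth Logical; pre-smooth with [stats::smooth.spline()].
#' @param spar Smoothing parameter passed to `smooth.spline` (NULL =
#'   GCV-chosen).
#' @return A `tac` with role `"rate"` holding dC/dt at each midpoint.
#' @export
finite_diff_derivative <- function(x, smooth = FALSE, spar = NULL) {
  stopifnot(is_tac(x))
  t <- x$schedule$midpoint
  v <- x$values
  n <- length(v)
  if (n < 3L) stop("need at least 3 frames to differentiate")
  if (smooth) {
    fit <- if (is.null(spar)) stats::smooth.spline(t, v)
           else stats::smooth.spline(t, v, spar = spar)
    v <- stats::predict(fit, t)$y
  }
  d <- numeric(n)
  i <- 2:(n - 1)
  h1 <- t[i] - t[i - 1]
  h2 <- t[i + 1] - t[i]
  # derivative of the quadratic through three consecutive points
  d[i] <- -h2 / (h1 * (h1 + h2)) * v[i - 1] +
    (h2 - h1) / (h1 * h2) * v[i] +
    h1 / (h2 * (h1 + h2)) * v[i + 1]
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  tac(x$schedule, d, role = "rate")
}

#' Read time-activity curves from CSV
#'
#' Expected dialect: header row with columns `frame_start_min`,
#' `frame_duration_min`, then one column per region.
#'
#' @param path CSV file path.
#' @return Named list of [tac()]s (role `"tissue"`), one per region column.
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame_start_min", "frame_duration_min")
  if (!all(need %in% names(df)))
    stop("TAC CSV must have columns ", paste(need, collapse = ", "))
  sch <- frame_schedule(df$frame_start_min, df$frame_duration_min)
  regions <- setdiff(names(df), c(need, "midpoint_min"))
  if (length(regions) == 0L) stop("no region columns found in ", path)
  out <- lapply(regions, function(r) {
    if (!is.numeric(df[[r]])) stop("non-numeric TAC column '", r, "'")
    tac(sch, df[[r]])
  })
  names(out) <- regions
  out
}

#' Write time-activity curves to CSV
#'
#' @param tacs Named list of [tac()]s on a common schedule, or a single `tac`.
#' @param path Output CSV path.
#' @export
write_tac_csv <- function(tacs, path) {
  if (is_tac(tacs)) tacs <- stats::setNames(list(tacs), tacs$role)
  sch <- tacs[[1]]$schedule
  for (x in tacs) {
    if (!same_schedule(x$schedule, sch)) stop("all TACs must share a schedule")
  }
  df <- data.frame(frame_start_min = sch$start,
                   frame_duration_min = sch$duration)
  for (nm in names(tacs)) df[[nm]] <- tacs[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
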