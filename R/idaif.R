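#' IDAIF estimator parameters
#'
#' Free parameters of the image-derived arterial input function model:
#' `K1`, `k2` (early one-tissue model), `k2a` (effective late washout,
#' `k2a = k2 / (1 + k3/k4)`, so `k2a <= k2`) and the spill-over coefficient
#' `s`. The recovery coefficient `r` and the branch switch times `t_peak`
#' and `t_late` are fixed, not fitted.
#'
#' @param K1,k2,k2a Positive rate constants (min^-1; K1 in mL cm^-3 min^-1).
#' @param s Spill-over coefficient, `>= 0`.
#' @param r Recovery coefficient, in `(0, 1]`.
#' @param t_peak Tissue-curve peak time (minutes); early/blend switch.
#' @param t_late Start of the pure late branch (minutes), default 40.
#' @return Object of class `idaif_params`.
#' @export
idaif_params <- function(K1, k2, k2a = k2, s = 0, r = 1,
                         t_peak = NULL, t_late = 40) {
  if (!is.finite(K1) || K1 <= 0) stop("K1 must be > 0")
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be > 0")
  if (!is.finite(k2a) || k2a <= 0) stop("k2a must be > 0")
  if (k2a > k2 * (1 + 1e-9)) stop("k2a must be <= k2 (k2a = k2/(1+k3/k4))")
  if (s < 0) stop("s must be >= 0")
  if (r <= 0 || r > 1) stop("r must be in (0, 1]")
  if (!is.null(t_peak) && t_peak >= t_late)
    stop("t_peak must be < t_late")
  structure(list(K1 = K1, k2 = k2, k2a = min(k2a, k2), s = s, r = r,
                 t_peak = t_peak, t_late = t_late),
            class = "idaif_params")
}

#' Population parent-fraction model
#'
#' The parent fraction `f(t)` is the fraction of plasma radioactivity
#' attributable to unmetabolized tracer: `f(0) = 1`, non-increasing,
#' `0 < f <= 1`. The default functional form is an exponential decay to a
#' plateau, `f(t) = c + (1 - c) exp(-lambda t)`. The whole-blood conversion
#' direction and a blood-to-plasma scale factor are explicit because
#' population metabolite corrections are applied in either direction in
#' practice.
#'
#' @param form `"exp_plateau"` (default) or `"exponential"`
#'   (`f(t) = exp(-lambda t)`).
#' @param c Plateau level in `(0, 1]` (exp_plateau form), default 0.05.
#' @param lambda Decay rate (min^-1), default 0.15.
#' @param blood_plasma_ratio Whole-blood-to-plasma scale factor, default 1.
#' @param direction `"plasma_to_blood"` (default): whole blood is total
#'   plasma activity, `C_B = C_P / f(t) * ratio` where `C_P` is
#'   parent-compound plasma activity; or `"blood_to_plasma"`:
#'   `C_B = C_P * f(t) * ratio`.
#' @return Object of class `parent_fraction`.
#' @export
parent_fraction_model <- function(form = c("exp_plateau", "exponential"),
                                  c = 0.05, lambda = 0.15,
                                  blood_plasma_ratio = 1,
                                  direction = c("plasma_to_blood",
                                                "blood_to_plasma")) {
  form <- match.arg(form)
  direction <- match.arg(direction)
  if (form == "exp_plateau" && (c <= 0 || c > 1))
    stop("plateau c must be in (0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  if (blood_plasma_ratio <= 0) stop("blood_plasma_ratio must be > 0")
  structure(list(form = form, c = c, lambda = lambda,
                 blood_plasma_ratio = blood_plasma_ratio,
                 direction = direction),
            class = "parent_fraction")
}

#' Evaluate a parent-fraction model
#' @param pf A [parent_fraction_model()].
#' @param t Times (minutes).
#' @return `f(t)` in `(0, 1]`.
#' @export
parent_fraction <- function(pf, t) {
  stopifnot(inherits(pf, "parent_fraction"))
  switch(pf$form,
         exp_plateau = pf$c + (1 - pf$c) * exp(-pf$lambda * t),
         exponential = exp(-pf$lambda * t))
}

# per-frame mean derivative: (Ct(end) - Ct(start)) / duration, with the
# boundary values read off the average-preserving piecewise-linear
# reconstruction of the curve
frame_balance_derivative <- function(ct, smooth = FALSE, spar = NULL) {
  v <- ct$values
  if (smooth) {
    t <- ct$schedule$midpoint
    fit <- if (is.null(spar)) stats::smooth.spline(t, v)
           else stats::smooth.spline(t, v, spar = spar)
    v <- stats::predict(fit, t)$y
  }
  nodes <- avg_preserving_nodes(tac(ct$schedule, v, role = ct$role))
  f <- stats::approxfun(c(0, ct$schedule$midpoint), c(0, nodes), rule = 2)
  (f(ct$schedule$end) - f(ct$schedule$start)) / ct$schedule$duration
}

#' Time of the tissue-curve peak
#'
#' Midpoint of the maximum-value frame; ties broken by the earliest frame.
#' This is the switch point between the early and blended branches of the
#' IDAIF reconstruction.
#'
#' @param ct A [tac()].
#' @return Peak time in minutes.
#' @export
detect_tpeak <- function(ct) {
  stopifnot(is_tac(ct))
  if (all(ct$values == 0)) stop("degenerate all-zero curve: no peak")
  ct$schedule$midpoint[which.max(ct$values)]
}

#' Reconstruct the plasma input from a tissue curve
#'
#' Inverts a dual one-tissue compartment description of a large tissue
#' region's kinetics. Before the tissue peak,
#' `C_P = (1/K1) dCt/dt + (k2/K1) Ct`; after `t_late` the effective washout
#' `k2a` replaces `k2`; in between the two branches are blended with weights
#' `w1` falling linearly from 1 to 0 and `w2 = 1 - w1` over
#' `[t_peak, t_late]`. Negative reconstructed values are floored at zero and
#' counted (attribute `n_floored`).
#'
#' @param ct Tissue [tac()] (typically the cerebellar cortex, the largest
#'   parcellated region; any large region works).
#' @param params An [idaif_params()]; if `t_peak` is NULL it is detected
#'   from `ct`.
#' @param deriv Derivative scheme: `"frame_balance"` (default) uses the
#'   exact identity that the frame average of dCt/dt equals
#'   `(Ct(end) - Ct(start)) / duration`, with frame-boundary values taken
#'   from the average-preserving reconstruction of the curve — the
#'   reconstructed input is then itself a frame-average quantity;
#'   `"central"` uses midpoint central differences
#'   ([finite_diff_derivative()]).
#' @param smooth_derivative Pre-smooth the derivative (for noisy data).
#' @return A plasma-role [tac()] with attribute `n_floored`.
#' @export
aif_from_tissue <- function(ct, params,
                            deriv = c("frame_balance", "central"),
                            smooth_derivative = FALSE) {
  stopifnot(is_tac(ct), inherits(params, "idaif_params"))
  deriv <- match.arg(deriv)
  if (params$K1 <= 0) stop("K1 must be > 0")
  tp <- if (is.null(params$t_peak)) detect_tpeak(ct) else params$t_peak
  tl <- params$t_late
  if (tp >= tl) stop("t_peak (", tp, ") must be < t_late (", tl, ")")
  t <- ct$schedule$midpoint
  d <- if (deriv == "frame_balance") frame_balance_derivative(ct, smooth_derivative)
       else finite_diff_derivative(ct, smooth = smooth_derivative)$values
  early <- (d + params$k2 * ct$values) / params$K1
  late <- (d + params$k2a * ct$values) / params$K1
  w1 <- pmin(1, pmax(0, (tl - t) / (tl - tp)))
  w1[t < tp] <- 1
  cp <- w1 * early + (1 - w1) * late
  n_floored <- sum(cp < 0)
  cp[cp < 0] <- 0
  out <- tac(ct$schedule, cp, role = "plasma")
  attr(out, "n_floored") <- n_floored
  out
}

#' Whole-blood curve from the plasma input
#'
#' Applies the population parent-compound ratio: with the default direction,
#' `C_B(t) = C_P(t) / f(t) * blood_plasma_ratio`.
#'
#' @param cp Plasma [tac()].
#' @param pf A [parent_fraction_model()].
#' @return Whole-blood-role [tac()].
#' @export
whole_blood_from_plasma <- function(cp, pf) {
  stopifnot(is_tac(cp), inherits(pf, "parent_fraction"))
  f <- parent_fraction(pf, cp$schedule$midpoint)
  if (any(f <= 0)) stop("parent fraction reached 0; invalid model")
  g <- if (pf$direction == "plasma_to_blood") 1 / f else f
  tac(cp$schedule, cp$values * g * pf$blood_plasma_ratio,
      role = "whole_blood")
}

#' Arterial-ROI mixing model
#'
#' The arterial ROI sees the true blood signal attenuated by the recovery
#' coefficient plus spill-over from surrounding tissue:
#' `C_ROIa = r C_B + s C_BG`.
#'
#' @param cb Whole-blood [tac()].
#' @param cbg Background [tac()] on the same schedule.
#' @param r Recovery coefficient.
#' @param s Spill-over coefficient.
#' @return Arterial-ROI-role [tac()].
#' @export
roia_model <- function(cb, cbg, r, s) {
  stopifnot(is_tac(cb), is_tac(cbg))
  if (!same_schedule(cb$schedule, cbg$schedule))
    stop("cb and cbg must share a schedule")
  tac(cb$schedule, r * cb$values + s * cbg$values, role = "arterial_roi")
}

# model-predicted arterial-ROI TAC for a parameter set
roia_predict <- function(theta, ct, cbg, pf, smooth_derivative = FALSE) {
  cp <- aif_from_tissue(ct, theta, smooth_derivative = smooth_derivative)
  cb <- whole_blood_from_plasma(cp, pf)
  list(croia = roia_model(cb, cbg, theta$r, theta$s), cp = cp)
}

#' IDAIF cost function
#'
#' Sum of squared differences, over all frames, between the measured
#' arterial-ROI TAC and the model prediction obtained by chaining
#' [aif_from_tissue()], [whole_blood_from_plasma()] and [roia_model()].
#'
#' @param theta An [idaif_params()].
#' @param ct Large-tissue [tac()] driving the reconstruction.
#' @param croia_meas Measured arterial-ROI [tac()].
#' @param cbg Background [tac()].
#' @param pf A [parent_fraction_model()].
#' @param weights Optional per-frame weights (e.g. frame durations);
#'   default unweighted.
#' @return Q, the (optionally weighted) residual sum of squares.
#' @export
idaif_cost <- function(theta, ct, croia_meas, cbg, pf, weights = NULL) {
  stopifnot(is_tac(croia_meas))
  if (!same_schedule(ct$schedule, croia_meas$schedule) ||
      !same_schedule(ct$schedule, cbg$schedule))
    stop("all curves must share a schedule")
  mod <- roia_predict(theta, ct, cbg, pf)$croia
  res <- croia_meas$values - mod$values
  if (is.null(weights)) sum(res^2) else sum(weights * res^2)
}

#' Fit the image-derived arterial input function
#'
#' Bounded nonlinear least squares over `(K1, k2, k2a, s)` minimizing
#' [idaif_cost()]. The constraint `k2a <= k2` is enforced by the
#' reparameterization `k2a = k2 * rho`, `rho` in `(0, 1]`. Multiple seeded
#' starts (log-uniform for the rates) are run and the lowest-cost solution
#' kept.
#'
#' @param ct Large-tissue [tac()].
#' @param croia_meas Measured arterial-ROI [tac()].
#' @param cbg Background [tac()].
#' @param r Recovery coefficient in `(0, 1]` (fixed; from
#'   [recovery_coefficient()]).
#' @param pf A [parent_fraction_model()].
#' @param t_late Late-branch switch (minutes), default 40.
#' @param n_starts Number of multi-starts (default 5).
#' @param seed RNG seed for the starts.
#' @param init Optional named list/vector `(K1, k2, rho, s)` used as the
#'   first start.
#' @param lower,upper Bounds on `(K1, k2, rho, s)`.
#' @param weights Residual weights: `"none"` (default), `"duration"`,
#'   `"ivar"` (duration / activity, approximate inverse variance;
#'   recommended for noisy data) or a numeric vector.
#' @param smooth_derivative Pre-smooth dCt/dt (for noisy data).
#' @return List: `params` ([idaif_params()]), `cp` (fitted plasma [tac()]),
#'   `diagnostics` (per-start costs, convergence codes, active bounds).
#' @export
fit_idaif <- function(ct, croia_meas, cbg, r, pf,
                      t_late = 40, n_starts = 5, seed = 1L, init = NULL,
                      lower = c(K1 = 0.01, k2 = 0.01, rho = 0.05, s = 0),
                      upper = c(K1 = 2, k2 = 2, rho = 1, s = 2),
                      weights = "none", smooth_derivative = FALSE) {
  if (r <= 0 || r > 1) stop("r must be in (0, 1]")
  if (!is.numeric(weights) && !is.null(weights))
    weights <- fit_weights(weights, croia_meas)
  tp <- detect_tpeak(ct)
  obj <- function(x) {
    # out-of-range probes (numerical gradients step past the bounds)
    # receive a finite penalty rather than an error
    q <- tryCatch({
      th <- idaif_params(K1 = x[1], k2 = x[2], k2a = min(x[2] * x[3], x[2]),
                         s = max(x[4], 0), r = r, t_peak = tp,
                         t_late = t_late)
      mod <- roia_predict(th, ct, cbg, pf,
                          smooth_derivative = smooth_derivative)$croia
      res <- croia_meas$values - mod$values
      if (is.null(weights)) sum(res^2) else sum(weights * res^2)
    }, error = function(e) NA_real_)
    if (!is.finite(q)) 1e30 else q
  }
  starts <- list()
  if (!is.null(init)) starts[[1]] <- as.numeric(init[c("K1", "k2", "rho", "s")])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1]] <-
      c(exp(stats::runif(1, log(0.05), log(0.5))),
        exp(stats::runif(1, log(0.05), log(0.5))),
        stats::runif(1, 0.2, 1),
        stats::runif(1, 0, 0.5))
  }
  fits <- lapply(starts, function(x0) {
    x0 <- pmin(pmax(x0, lower), upper)
    tryCatch(
      stats::optim(x0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) list(value = Inf, convergence = -1L,
                               message = conditionMessage(e)))
  })
  qs <- vapply(fits, function(f) f$value, numeric(1))
  if (all(!is.finite(qs))) stop("all IDAIF fit starts failed")
  best <- fits[[which.min(qs)]]
  x <- best$par
  params <- idaif_params(K1 = x[1], k2 = x[2], k2a = x[2] * x[3], s = x[4],
                         r = r, t_peak = tp, t_late = t_late)
  pred <- roia_predict(params, ct, cbg, pf,
                       smooth_derivative = smooth_derivative)
  at_bounds <- names(lower)[x <= lower + 1e-8 | x >= upper - 1e-8]
  list(params = params, cp = pred$cp,
       diagnostics = list(Q = min(qs), Q_per_start = qs,
                          convergence = best$convergence,
                          active_bounds = at_bounds,
                          n_floored = attr(pred$cp, "n_floored"),
                          t_peak = tp))
}
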