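# Independent numerical oracles. These deliberately avoid the package's
# analytic convolution path: the 2TC oracle integrates the coupled rate
# equations with a classic fixed-step RK4, and curve summaries are
# recomputed with plain loops.

# RK4 integration of the two-tissue compartment rate equations
#   dC_ND/dt = K1 Cp - (k2 + k3) C_ND + k4 C_S
#   dC_S/dt  = k3 C_ND - k4 C_S
# Returns the total tissue curve C_ND + C_S on a uniform grid.
rk4_2tc_oracle <- function(K1, k2, k3, k4, cp_fun, t_end = 60, dt = 1 / 600) {
  n <- round(t_end / dt)
  t <- seq(0, t_end, by = dt)
  cp_half <- cp_fun(seq(0, t_end, by = dt / 2))   # nodes and half-steps
  ct <- numeric(n + 1)
  y1 <- 0; y2 <- 0
  deriv <- function(cp, y1, y2)
    c(K1 * cp - (k2 + k3) * y1 + k4 * y2, k3 * y1 - k4 * y2)
  for (i in seq_len(n)) {
    cp0 <- cp_half[2 * i - 1]; cpm <- cp_half[2 * i]; cp1 <- cp_half[2 * i + 1]
    a <- deriv(cp0, y1, y2)
    b <- deriv(cpm, y1 + dt / 2 * a[1], y2 + dt / 2 * a[2])
    c_ <- deriv(cpm, y1 + dt / 2 * b[1], y2 + dt / 2 * b[2])
    d <- deriv(cp1, y1 + dt * c_[1], y2 + dt * c_[2])
    y1 <- y1 + dt / 6 * (a[1] + 2 * b[1] + 2 * c_[1] + d[1])
    y2 <- y2 + dt / 6 * (a[2] + 2 * b[2] + 2 * c_[2] + d[2])
    ct[i + 1] <- y1 + y2
  }
  list(t = t, ct = ct)
}

# frame averages of a densely sampled curve, by direct per-frame trapezoid
frame_average_oracle <- function(t, y, sch) {
  vapply(seq_len(sch$F), function(i) {
    sel <- which(t >= sch$start[i] - 1e-9 & t <= sch$end[i] + 1e-9)
    ts <- t[sel]; ys <- y[sel]
    sum((ys[-1] + ys[-length(ys)]) / 2 * diff(ts)) / (ts[length(ts)] - ts[1])
  }, numeric(1))
}

# Logan slope from continuous curves with dense-grid integrals: the
# reference comparator for linearization-bias statements
dense_logan_oracle <- function(kin, cp_fun, window = c(30, 60),
                               t_end = 60, dt = 1 / 600) {
  t <- seq(0, t_end, by = dt)
  cp <- cp_fun(t)
  ode <- rk4_2tc_oracle(kin$K1, kin$k2, kin$k3, kin$k4, cp_fun,
                        t_end = t_end, dt = dt)
  ct <- ode$ct
  cum <- function(y) cumsum(c(0, (y[-1] + y[-length(y)]) / 2 * dt))
  sch <- make_schedule()
  mid <- sch$midpoint
  sel <- mid >= window[1] & mid <= window[2]
  ii <- round(mid[sel] / dt) + 1
  y <- cum(ct)[ii] / ct[ii]
  x <- cum(cp)[ii] / ct[ii]
  unname(stats::coef(stats::lm(y ~ x))[2])
}

# same physical volume represented on an f-times finer grid (voxel
# replication: identical piecewise-constant function, different sampling)
upsample_replicate <- function(vol, f) {
  d <- dim(vol$data)
  a <- vol$data[rep(seq_len(d[1]), each = f),
                rep(seq_len(d[2]), each = f),
                rep(seq_len(d[3]), each = f)]
  volume_image(a, vol$voxel_mm / f)
}
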