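test_that("idaif_params and parent_fraction_model enforce invariants", {
  expect_error(idaif_params(K1 = 0, k2 = 0.1), "K1")
  expect_error(idaif_params(K1 = 0.2, k2 = 0.1, k2a = 0.2), "k2a")
  expect_error(idaif_params(K1 = 0.2, k2 = 0.1, r = 1.5), "r must")
  expect_error(idaif_params(K1 = 0.2, k2 = 0.1, t_peak = 45, t_late = 40),
               "t_peak")
  pf <- parent_fraction_model()
  expect_equal(parent_fraction(pf, 0), 1)
  tt <- seq(0, 90, by = 1)
  ft <- parent_fraction(pf, tt)
  expect_true(all(diff(ft) <= 0) && all(ft > 0) && all(ft <= 1))
  expect_error(parent_fraction_model(c = 0), "plateau")
})

test_that("detect_tpeak picks the earliest maximum midpoint", {
  sch <- make_schedule()
  expect_equal(detect_tpeak(tac(sch, seq_len(26))), sch$midpoint[26])
  v <- dnorm(sch$midpoint, mean = 8, sd = 3)
  expect_equal(detect_tpeak(tac(sch, v)), sch$midpoint[which.max(v)])
  v2 <- c(1:5, 9, 9, 9, 8:1, rep(0.5, 10))
  expect_equal(detect_tpeak(tac(sch, v2)), sch$midpoint[6])
  expect_error(detect_tpeak(tac(sch, rep(0, 26))), "degenerate")
})

test_that("aif_from_tissue inverts the 1TC model in the dense limit", {
  sch <- dense_schedule(dur = 0.05)
  aif <- make_aif(sch)
  f <- attr(aif, "fun")
  ct <- forward_1tc(0.2, 0.15, f, sch)
  th <- idaif_params(K1 = 0.2, k2 = 0.15, k2a = 0.15, s = 0, r = 1)
  cp <- aif_from_tissue(ct, th)
  expect_lt(max(abs(cp$values - aif$values)) / max(aif$values), 0.02)
})

test_that("aif_from_tissue is linear and handles degenerate input", {
  sub <- fixture_subject()
  th <- sub$truth$theta
  cp1 <- aif_from_tissue(sub$tacs$cerebellum, th)
  ct5 <- tac(sub$schedule, 5 * sub$tacs$cerebellum$values)
  cp5 <- aif_from_tissue(ct5, th)
  expect_equal(cp5$values, 5 * cp1$values, tolerance = 1e-12)
  # all-zero curve with an explicit t_peak maps to an all-zero input
  z <- tac(sub$schedule, rep(0, 26))
  thz <- idaif_params(K1 = 0.2, k2 = 0.1, s = 0, r = 1, t_peak = 5)
  expect_equal(aif_from_tissue(z, thz)$values, rep(0, 26))
  # floored-negative frames are counted
  expect_lte(attr(cp1, "n_floored"), 1)
})

test_that("whole_blood_from_plasma applies the parent-fraction in both directions", {
  # schedule with a frame midpoint exactly at t = 60
  sch <- frame_schedule(start = c(0, 59.5), duration = c(1, 1))
  cp <- tac(sch, c(1, 1), role = "plasma")
  pf1 <- parent_fraction_model(form = "exponential", lambda = 0)
  expect_equal(whole_blood_from_plasma(cp, pf1)$values, c(1, 1))
  pf2 <- parent_fraction_model(form = "exponential", lambda = 0.02)
  cb <- whole_blood_from_plasma(cp, pf2)
  expect_equal(cb$values[2], exp(1.2), tolerance = 1e-6)
  pf3 <- parent_fraction_model(form = "exponential", lambda = 0.02,
                               direction = "blood_to_plasma")
  expect_equal(whole_blood_from_plasma(cp, pf3)$values[2], exp(-1.2),
               tolerance = 1e-6)
})

test_that("roia_model mixes blood and background per-frame", {
  sch <- make_schedule()
  cb <- tac(sch, rep(2, 26), role = "whole_blood")
  cbg <- tac(sch, rep(5, 26), role = "background")
  expect_equal(roia_model(cb, cbg, 1, 0)$values, cb$values)
  expect_equal(roia_model(cb, cbg, 0, 1)$values, cbg$values)
  expect_equal(roia_model(cb, cbg, 0.5, 0.2)$values, rep(2, 26))
  other <- tac(make_schedule(data.frame(n = 5, dur = 1)), rep(1, 5),
               role = "background")
  expect_error(roia_model(cb, other, 1, 0), "schedule")
})

test_that("idaif_cost is zero at truth and matches a brute-force loop", {
  sub <- fixture_subject()
  q0 <- idaif_cost(sub$truth$theta, sub$tacs$cerebellum, sub$croia,
                   sub$cbg, sub$pf)
  expect_lt(q0 / sum(sub$croia$values^2), 1e-12)
  th2 <- sub$truth$theta; th2$s <- th2$s + 0.1
  expect_gt(idaif_cost(th2, sub$tacs$cerebellum, sub$croia, sub$cbg,
                       sub$pf), 0)
  # independent residual re-summation
  mod <- roia_model(
    whole_blood_from_plasma(
      aif_from_tissue(sub$tacs$cerebellum, th2), sub$pf),
    sub$cbg, th2$r, th2$s)
  q_loop <- 0
  for (i in seq_len(26))
    q_loop <- q_loop + (sub$croia$values[i] - mod$values[i])^2
  expect_equal(idaif_cost(th2, sub$tacs$cerebellum, sub$croia, sub$cbg,
                          sub$pf), q_loop, tolerance = 1e-12)
})

test_that("fit_idaif recovers the generating parameters and input", {
  sub <- fixture_subject()
  fit <- fixture_idaif_fit()
  expect_lt(abs(fit$params$s - sub$s) / sub$s, 0.05)
  expect_lt(abs(fit$params$K1 - sub$truth$theta$K1) / sub$truth$theta$K1,
            0.05)
  late <- sub$schedule$midpoint > 1
  expect_lt(max(abs(fit$cp$values[late] - sub$cp_implied$values[late])) /
              max(sub$cp_implied$values), 0.05)
  expect_lte(fit$diagnostics$n_floored, 1)   # < 5% of 26 frames
})

test_that("fit_idaif is invariant to joint rescaling of the curves", {
  sub <- fixture_subject()
  fit <- fixture_idaif_fit()
  c0 <- 3.7
  scale_tac <- function(x) tac(x$schedule, c0 * x$values, role = x$role)
  fit2 <- fit_idaif(scale_tac(sub$tacs$cerebellum), scale_tac(sub$croia),
                    scale_tac(sub$cbg), r = sub$r, pf = sub$pf, seed = 7L)
  expect_equal(fit2$params$s, fit$params$s, tolerance = 1e-3)
  expect_equal(fit2$params$K1, fit$params$K1, tolerance = 1e-3)
  expect_equal(fit2$diagnostics$Q / fit$diagnostics$Q, c0^2,
               tolerance = 0.05)
})

test_that("full fit attains a cost no worse than the s-fixed restricted fit", {
  sub <- fixture_subject()
  fit <- fixture_idaif_fit()
  # restricted fit: s pinned at truth, (K1, k2, rho) free (direct 3-D
  # minimization of the package cost, independent of fit_idaif)
  o <- stats::optim(c(0.2, 0.2, 0.8), function(x) {
    th <- idaif_params(K1 = x[1], k2 = x[2], k2a = x[2] * min(x[3], 1),
                       s = sub$s, r = sub$r, t_peak = sub$t_peak,
                       t_late = 40)
    idaif_cost(th, sub$tacs$cerebellum, sub$croia, sub$cbg, sub$pf)
  }, method = "L-BFGS-B", lower = c(0.01, 0.01, 0.05), upper = c(2, 2, 1),
  control = list(factr = 1e3))
  expect_lte(fit$diagnostics$Q, o$value + 1e-8 * sum(sub$croia$values^2))
})

test_that("the true parameters beat 1000 random draws on the cost surface", {
  sub <- fixture_subject()
  q0 <- idaif_cost(sub$truth$theta, sub$tacs$cerebellum, sub$croia,
                   sub$cbg, sub$pf)
  set.seed(99)
  worst <- Inf
  for (i in 1:1000) {
    K1 <- exp(runif(1, log(0.05), log(0.5)))
    k2 <- exp(runif(1, log(0.05), log(0.5)))
    th <- idaif_params(K1 = K1, k2 = k2, k2a = k2 * runif(1, 0.2, 1),
                       s = runif(1, 0, 0.5), r = sub$r,
                       t_peak = sub$t_peak, t_late = 40)
    q <- idaif_cost(th, sub$tacs$cerebellum, sub$croia, sub$cbg, sub$pf)
    worst <- min(worst, q)
  }
  expect_lte(q0, worst)
})
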