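test_that("proportional curves give slope = ratio, intercept 0", {
  sch <- make_schedule()
  cp <- make_aif(sch)
  ct <- tac(sch, 3 * cp$values)
  la <- logan_arterial(ct, cp)
  expect_equal(la$slope, 3, tolerance = 1e-8)
  expect_lt(abs(la$intercept), 1e-8)
  expect_identical(la$n_points, 6L)   # 5-min frames with midpoints in 30-60
})

test_that("arterial Logan recovers VT up to linearization bias", {
  sch <- make_schedule()
  cp <- make_aif(sch)
  f <- attr(cp, "fun")
  k <- kinetics_2tc(0.25, 0.35, 0.05, 0.03)
  ct <- forward_2tc(k, f, sch)
  slope <- logan_arterial(ct, cp)$slope
  # the dense-grid continuous-curve oracle carries the same linearization
  # bias; implementation and oracle must agree closely
  oracle <- dense_logan_oracle(k, f)
  expect_equal(slope, oracle, tolerance = 0.01)
  # bias against the analytic VT is real (~3% here) but bounded
  expect_lt(abs(slope - k$vt) / k$vt, 0.05)
})

test_that("AIF scaling inversely scales the Logan slope, exactly", {
  sub <- fixture_subject()
  ct <- sub$tacs$precuneus
  cp <- sub$true_aif
  s1 <- logan_arterial(ct, cp)$slope
  cp2 <- tac(sub$schedule, 2 * cp$values, role = "plasma")
  s2 <- logan_arterial(ct, cp2)$slope
  expect_equal(s1 / s2, 2, tolerance = 1e-10)
  # rescaling BOTH curves leaves the slope unchanged
  ct3 <- tac(sub$schedule, 3 * ct$values)
  cp3 <- tac(sub$schedule, 3 * cp$values, role = "plasma")
  expect_equal(logan_arterial(ct3, cp3)$slope, s1, tolerance = 1e-10)
})

test_that("reference Logan of a region against itself gives DVR 1", {
  sub <- fixture_subject()
  for (x in list(sub$tacs$cerebellum, sub$tacs$caudate,
                 tac(sub$schedule, runif(26, 1, 10)))) {
    for (k2p in c(0.05, 0.16, 0.5)) {
      lr <- logan_reference(x, x, k2prime = k2p)
      expect_equal(lr$slope, 1, tolerance = 1e-8)
      # with Ct = Cr the model forces y = x - 1/k2': intercept is -1/k2'
      expect_equal(lr$intercept, -1 / k2p, tolerance = 1e-6)
    }
  }
})

test_that("reference Logan estimates DVR = 1 + k3/k4 for a matched pair", {
  sch <- make_schedule()
  f <- attr(make_aif(sch), "fun")
  # reference washout fixed at the conventional 0.16/min; identical K1/k2
  cr <- forward_2tc(kinetics_2tc(0.45, 0.16), f, sch)
  ct <- forward_2tc(kinetics_2tc(0.45, 0.16, 0.02, 0.04), f, sch)
  lr <- logan_reference(ct, cr, k2prime = 0.16)
  expect_equal(lr$slope, 1.5, tolerance = 0.03)
})

test_that("DVR is insensitive to k2prime over a 10-fold range", {
  sch <- make_schedule()
  f <- attr(make_aif(sch), "fun")
  cr <- forward_2tc(kinetics_2tc(0.45, 0.16), f, sch)
  ct <- forward_2tc(kinetics_2tc(0.45, 0.16, 0.02, 0.04), f, sch)
  slopes <- vapply(c(0.05, 0.1, 0.16, 0.3, 0.5),
                   function(k2p) logan_reference(ct, cr, k2prime = k2p)$slope,
                   numeric(1))
  expect_lt(diff(range(slopes)) / slopes[3], 0.035)
})

test_that("window selection and error paths behave as specified", {
  sch <- make_schedule()
  cp <- make_aif(sch)
  ct <- tac(sch, 2 * cp$values)
  # boundary midpoints are included (closed interval)
  la <- logan_arterial(ct, cp, window = c(32.5, 57.5))
  expect_identical(la$n_points, 6L)
  expect_error(logan_arterial(ct, cp, window = c(58, 60)),
               "fewer than 2")
  v <- ct$values; v[25] <- 0
  expect_error(logan_arterial(tac(sch, v), cp), "frame")
  con <- tac(sch, rep(1, 26))
  expect_error(logan_arterial(con, tac(sch, rep(0, 26), role = "plasma")),
               "singular")
})

test_that("narrowing the window toward late times moves the slope toward VT", {
  sub <- fixture_subject()
  ct <- sub$tacs$precuneus
  cp <- sub$true_aif
  vt <- sub$truth$vt["precuneus"]
  s_wide <- logan_arterial(ct, cp, window = c(15, 60))$slope
  s_mid <- logan_arterial(ct, cp, window = c(30, 60))$slope
  s_late <- logan_arterial(ct, cp, window = c(40, 60))$slope
  err <- abs(c(s_wide, s_mid, s_late) - vt)
  expect_true(all(diff(err) < 0))
})

test_that("mcdvr is the plain roster mean and flags missing regions", {
  expect_equal(mcdvr(c(a = 1, b = 1, c = 1), c("a", "b", "c")), 1)
  expect_equal(mcdvr(list(a = 1.2, b = 1.4), c("a", "b")), 1.3)
  expect_equal(mcdvr(c(a = 1.7, b = 9), "a"), 1.7)
  expect_error(mcdvr(c(a = 1), c("a", "z")), "missing.*z")
})
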