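test_that("polynomial fit interpolates exact polynomial samples", {
  t <- seq(0, 120, length.out = 12)
  co <- c(900, -0.8, 0.004, -1e-5) # a0..a3
  y <- co[1] + co[2] * t + co[3] * t^2 + co[4] * t^3
  fit <- fit_bmd_curve(tibble::tibble(time_months = t, bmd = y),
    "polynomial", degree = 3)
  expect_equal(fit$coefficients, co, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict(fit, t), y, tolerance = 1e-9)
})

test_that("degenerate or short series are rejected", {
  expect_error(
    fit_bmd_curve(tibble::tibble(time_months = c(0, 12), bmd = c(900, 890)),
      "polynomial", degree = 1),
    class = "osteofem_input_error"
  )
  expect_error(
    fit_bmd_curve(tibble::tibble(time_months = c(0, 0, 12),
      bmd = c(900, 900, 890)), "polynomial", degree = 1),
    class = "osteofem_input_error"
  )
  expect_error(
    fit_bmd_curve(tibble::tibble(time_months = 0:4, bmd = c(1, 2, 3, 4, 5)),
      "polynomial", degree = 5),
    class = "osteofem_input_error"
  )
})

test_that("asymptotic fit recovers generating parameters from noisy data", {
  truth <- c(rho0 = 900, rho_lim = 700, a = 0.02, t_m = 240)
  s <- generate_asymptotic_series(seed = 7)
  fit <- fit_bmd_curve(s, "exp_asymptotic")
  est <- unlist(fit$coefficients)
  expect_lt(max((abs(est - truth) / truth)[c(1, 2, 4)]), 0.05)
  expect_lt(abs(est["a"] - truth["a"]) / truth["a"], 0.25)
  expect_gte(fit$r_squared, 0.98)
  # refitting the curve's own (noise-free) samples is idempotent
  t <- s$time_months
  clean <- tibble::tibble(time_months = t,
    bmd = predict(fit, t, extrapolate = TRUE))
  fit2 <- fit_bmd_curve(clean, "exp_asymptotic")
  expect_equal(unlist(fit2$coefficients), est, tolerance = 1e-4)
})

test_that("asymptotic family honours its closed form and domain", {
  co <- list(rho0 = 900, rho_lim = 700, a = 0.02, t_m = 240)
  cv <- bmd_curve("exp_asymptotic", co)
  expect_equal(predict(cv, 0), 900)
  # independent hand evaluation at t = 120
  expect_equal(predict(cv, 120),
    900 + (700 - 900) * (1 - exp(-0.02 * 120 / (240 - 120))))
  # approaches rho_lim near t_m
  expect_equal(predict(cv, 239.999, extrapolate = TRUE), 700, tolerance = 0.1)
  expect_error(predict(cv, 240, extrapolate = TRUE),
    class = "osteofem_domain_error")
  # never negative on [0, 180] for physical parameters
  for (rl in c(50, 400, 880)) {
    cv2 <- bmd_curve("exp_asymptotic",
      list(rho0 = 900, rho_lim = rl, a = 0.3, t_m = 200))
    expect_true(all(predict(cv2, seq(0, 180, by = 3)) >= 0))
  }
})

test_that("evaluation horizon is enforced unless extrapolation is requested", {
  cv <- bmd_curve("polynomial", c(900, -0.5), fit_window = c(0, 120))
  expect_equal(predict(cv, 180), 900 - 0.5 * 180)
  expect_error(predict(cv, 200), class = "osteofem_domain_error")
  expect_equal(predict(cv, 200, extrapolate = TRUE), 800)
  expect_error(predict(cv, -1), class = "osteofem_input_error")
  # constant polynomial evaluates to a0 anywhere
  expect_equal(predict(bmd_curve("polynomial", 950), c(0, 90, 180)),
    rep(950, 3))
})

test_that("model selection minimizes MSE with parsimony tie-breaks", {
  t <- seq(0, 120, by = 12)
  lin <- tibble::tibble(time_months = t, bmd = 900 - 0.6 * t)
  best <- select_bmd_curve(lin,
    candidates = list(list(family = "polynomial", degree = 1),
      list(family = "polynomial", degree = 3)))
  expect_equal(best$family, "polynomial")
  expect_length(best$coefficients, 2) # the tie broke towards fewer params
  # asymptotic data prefers the asymptotic family over a quadratic
  s <- generate_asymptotic_series(seed = 11)
  best2 <- select_bmd_curve(s,
    candidates = list(list(family = "polynomial", degree = 2),
      list(family = "exp_asymptotic")))
  expect_equal(best2$family, "exp_asymptotic")
  cands <- attr(best2, "candidates")
  expect_true(all(best2$mse <= cands$mse[cands$converged] + 1e-12))
  expect_error(select_bmd_curve(lin, candidates = list()),
    class = "osteofem_input_error")
})

test_that("patient adaptation is an exact translation", {
  cv <- bmd_template_curve("natural")
  # offset zero when the measurement sits on the curve
  same <- adapt_to_patient(cv, 0, predict(cv, 0))
  expect_equal(predict(same, c(0, 60, 120)), predict(cv, c(0, 60, 120)))
  # +50 offset raises every evaluation by exactly 50
  up <- adapt_to_patient(cv, 0, predict(cv, 0) + 50)
  tt <- seq(0, 180, by = 9)
  expect_equal(predict(up, tt), predict(cv, tt) + 50, tolerance = 1e-12)
  # anchoring: passes through the measurement at t0
  measured <- 812.5
  ad <- adapt_to_patient(cv, 24, measured)
  expect_equal(predict(ad, 24), measured, tolerance = 1e-12)
  # natural and treated curves adapted to one patient coincide at t0
  tr <- adapt_to_patient(bmd_template_curve("alendronate_like"), 24, measured)
  expect_equal(predict(ad, 24), predict(tr, 24), tolerance = 1e-12)
})

test_that("piecewise schedules are continuous and reject bad segmentations", {
  rise <- bmd_curve("exponential", list(k = 50, a0 = 900, rates = 0.1))
  fall <- bmd_curve("polynomial", c(900, -0.9))
  sched <- compose_schedule(list(
    list(curve = rise, start = 0, end = 36),
    list(curve = fall, start = 36, end = 96),
    list(curve = rise, start = 96, end = 180)
  ))
  for (tj in c(36, 96)) {
    expect_lt(abs(predict(sched, tj - 1e-7) - predict(sched, tj + 1e-7)), 1e-5)
  }
  one <- compose_schedule(list(list(curve = rise, start = 0, end = 180)))
  tt <- seq(0, 180, by = 10)
  expect_equal(predict(one, tt), predict(rise, tt))
  expect_error(compose_schedule(list(
    list(curve = rise, start = 0, end = 40),
    list(curve = fall, start = 36, end = 90)
  )), "overlap", class = "osteofem_input_error")
  expect_error(compose_schedule(list(
    list(curve = rise, start = 0, end = 30),
    list(curve = fall, start = 36, end = 90)
  )), "gap", class = "osteofem_input_error")
})

test_that("synthetic series generators honour their template contracts", {
  nat <- generate_bmd_series("natural", noise_sd = 0, n_points = 20)
  expect_true(all(diff(nat$bmd) < 0))
  for (tpl in c("alendronate_like", "ibandronate_like", "pth_switch_like")) {
    s <- generate_bmd_series(tpl, noise_sd = 0, n_points = 25, t_max = 180)
    expect_gt(s$bmd[which.min(abs(s$time_months - 12))], s$bmd[1])
    # therapy stays at or above the natural course (same baseline)
    n <- generate_bmd_series("natural", noise_sd = 0, n_points = 25,
      t_max = 180)
    expect_true(all(s$bmd >= n$bmd - 1e-9))
  }
  a <- generate_bmd_series("natural", noise_sd = 4, seed = 99)
  b <- generate_bmd_series("natural", noise_sd = 4, seed = 99)
  expect_identical(a, b)
  expect_error(generate_bmd_series("statin_like"))
  expect_error(generate_bmd_series("natural", n_points = 2),
    class = "osteofem_input_error")
  # generators must not disturb the global RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(generate_bmd_series("natural", seed = 5)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("curve tidiers expose coefficients and fit quality", {
  fit <- fit_bmd_curve(generate_bmd_series("natural", noise_sd = 1, seed = 2),
    "polynomial", degree = 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_true(all(c("family", "r.squared", "mse") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
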