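# engine tests run on the shared coarse femur to stay fast
times6 <- seq(0, 36, by = 12)

test_that("constant BMD curves give stationary fields and zero delta P", {
  flat <- bmd_curve("polynomial", 900)
  res <- run_evolution(healthy_femur_bmd(), flat, coarse_femur,
    times = times6)
  expect_equal(max(abs(res$delta_p), na.rm = TRUE), 0)
  for (k in 2:length(times6)) {
    expect_equal(res$eps_c[k, ], res$eps_c[1, ], tolerance = 1e-12)
    expect_equal(res$probability[k, ], res$probability[1, ],
      tolerance = 1e-12)
  }
  nk <- res$region_curves[res$region_curves$region == "neck", ]
  expect_equal(nk$delta_p, rep(0, nrow(nk)))
})

test_that("baseline anchoring: evaluated zone BMD at t0 equals the measured sBMD", {
  res <- run_evolution(healthy_femur_bmd(), "natural", coarse_femur,
    times = times6)
  base <- res$zone_table[res$zone_table$time_months == 0, ]
  measured <- standardize_bmd(healthy_femur_bmd()$bmd, "hologic")
  expect_equal(base$bmd[order(base$zone)], measured, tolerance = 1e-12)
  expect_equal(res$delta_p[1, !is.na(res$delta_p[1, ])],
    rep(0, sum(!is.na(res$delta_p[1, ]))))
})

test_that("declining BMD makes neck fracture probability non-decreasing", {
  res <- run_evolution(healthy_femur_bmd(), "natural", coarse_femur,
    times = times6)
  neck <- res$region_curves[res$region_curves$region == "neck", ]
  expect_true(all(diff(neck$probability) >= -1e-12))
  expect_gt(neck$delta_p[nrow(neck)], 0)
  inc <- probability_increase(res)
  expect_equal(inc$regions$delta_p, res$region_curves$delta_p)
  expect_equal(inc$elements[1, !is.na(inc$elements[1, ])],
    rep(0, sum(!is.na(inc$elements[1, ]))))
})

test_that("scenario dominance: higher BMD never raises fracture probability", {
  nat <- run_evolution(healthy_femur_bmd(), "natural", coarse_femur,
    times = times6)
  tr <- run_evolution(healthy_femur_bmd(), "alendronate_like", coarse_femur,
    times = times6)
  n1 <- nat$region_curves[nat$region_curves$region == "neck", ]
  n2 <- tr$region_curves[tr$region_curves$region == "neck", ]
  expect_true(all(n1$probability >= n2$probability - 1e-12))
  expect_true(all(n1$delta_p >= n2$delta_p - 1e-12))
})

test_that("runs are deterministic and damage is cortical-only by default", {
  a <- run_evolution(healthy_femur_bmd(), "natural", coarse_femur,
    times = c(0, 24))
  b <- run_evolution(healthy_femur_bmd(), "natural", coarse_femur,
    times = c(0, 24))
  expect_identical(a$probability, b$probability)
  ct <- coarse_femur$tissue == "cortical"
  expect_false(anyNA(a$damage[, ct]))
  expect_true(all(is.na(a$damage[, !ct])))
  # probability stays in [0, 1]
  expect_true(all(a$probability[, ct] >= 0 & a$probability[, ct] <= 1))
})

test_that("irreversible mode keeps the running damage maximum", {
  # alendronate raises BMD, so instantaneous damage falls; the irreversible
  # variant must hold the baseline maximum instead
  rev <- run_evolution(healthy_femur_bmd(), "alendronate_like", coarse_femur,
    times = c(0, 12, 24))
  irr <- run_evolution(healthy_femur_bmd(), "alendronate_like", coarse_femur,
    times = c(0, 12, 24), irreversible = TRUE)
  ct <- coarse_femur$tissue == "cortical"
  expect_true(any(rev$damage[2, ct] < rev$damage[1, ct]))
  expect_true(all(diff(irr$damage[, ct]) >= -1e-15))
})

test_that("patient tables missing zones are rejected", {
  expect_error(
    run_evolution(healthy_femur_bmd()[-3, ], "natural", coarse_femur,
      times = c(0, 12)),
    "zone", class = "osteofem_input_error"
  )
  expect_error(
    run_evolution(healthy_femur_bmd(), "natural", coarse_femur,
      times = c(12, 24)),
    class = "osteofem_input_error"
  )
})

test_that("exported maps round-trip through VTK with delta P in percent", {
  res <- run_evolution(healthy_femur_bmd(), "natural", coarse_femur,
    times = c(0, 24))
  path <- withr::local_tempfile(fileext = ".vtk")
  export_maps(res, 24, path = path)
  back <- read_vtk(path)
  ct <- !is.na(res$damage[2, ])
  expect_equal(back$cell_data$damage[ct], res$damage[2, ct],
    tolerance = 1e-12)
  expect_equal(back$cell_data$delta_p[ct], 100 * res$delta_p[2, ct],
    tolerance = 1e-12)
  expect_equal(back$cell_data$eps_c, res$eps_c[2, ], tolerance = 1e-12)
  # zero-change run exports all-zero delta P
  flat <- run_evolution(healthy_femur_bmd(), bmd_curve("polynomial", 900),
    coarse_femur, times = c(0, 24))
  path2 <- withr::local_tempfile(fileext = ".vtk")
  export_maps(flat, 24, fields = "delta_p", path = path2)
  # non-cortical elements carry the NA sentinel; cortical values are all zero
  expect_equal(max(abs(read_vtk(path2)$cell_data$delta_p[ct])), 0)
  expect_error(export_maps(res, 13, path = path),
    class = "osteofem_input_error")
  expect_error(export_maps(res, 24, fields = "von_mises", path = path),
    class = "osteofem_input_error")
})

test_that("tidiers and plots summarize the evolution result", {
  res <- run_evolution(healthy_femur_bmd(), "natural", coarse_femur,
    times = c(0, 24))
  td <- tidy(res)
  expect_true(all(c("time_months", "region", "probability", "delta_p")
    %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_times, 2)
  expect_s3_class(autoplot(res), "ggplot")
})
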