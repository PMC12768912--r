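triangle <- tibble::tibble(t_min = c(0, 30, 60), glucose_mmol_l = c(5, 7, 5))
crossing <- tibble::tibble(t_min = c(0, 30, 60), glucose_mmol_l = c(5, 6, 4))

test_that("iAUC matches hand-computed trapezoid fixtures", {
  # ((0+2)/2)*30 + ((2+0)/2)*30
  expect_equal(compute_iauc(triangle), 60, tolerance = 1e-12)
  # second segment crosses baseline at t = 45: 15 + 7.5
  expect_equal(compute_iauc(crossing), 22.5, tolerance = 1e-12)
  flat <- tibble::tibble(t_min = c(0, 10, 20), glucose_mmol_l = c(5, 5, 5))
  expect_equal(compute_iauc(flat), 0)
  below <- tibble::tibble(t_min = c(0, 10, 20), glucose_mmol_l = c(5, 4, 4.5))
  expect_equal(compute_iauc(below), 0)
})

test_that("iAUC equals fine-grid numeric integration on random traces", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    t <- sort(runif(n, 0, 120))
    t <- t + seq_along(t) * 1e-6 # guard strict monotonicity
    y <- 5 + rnorm(n, 0, 1.5)
    baseline <- runif(1, 4, 6)
    got <- compute_iauc(tibble::tibble(t_min = t, glucose_mmol_l = y),
                        baseline = baseline, window = NULL)
    want <- oracle_iauc_numeric(t, y, baseline)
    if (want > 1e-8) expect_lt(abs(got - want) / want, 1e-9)
  }
})

test_that("iAUC invariances hold", {
  set.seed(7)
  t <- sort(runif(12, 0, 120))
  y <- 5 + rnorm(12)
  tr <- tibble::tibble(t_min = t, glucose_mmol_l = y)
  base <- 5
  ref <- compute_iauc(tr, baseline = base, window = NULL)

  # baseline shift invariance
  shifted <- tr; shifted$glucose_mmol_l <- y + 2
  expect_equal(compute_iauc(shifted, baseline = base + 2, window = NULL), ref)

  # scale linearity in time and in excess concentration
  tscaled <- tibble::tibble(t_min = 3 * t, glucose_mmol_l = y)
  expect_equal(compute_iauc(tscaled, baseline = base, window = NULL), 3 * ref)
  vscaled <- tibble::tibble(t_min = t, glucose_mmol_l = base + 2 * (y - base))
  expect_equal(compute_iauc(vscaled, baseline = base, window = NULL), 2 * ref)

  # refinement consistency: inserting an interpolated reading changes nothing
  tm <- (t[4] + t[5]) / 2
  ym <- approx(t, y, xout = tm)$y
  refined <- tibble::tibble(t_min = sort(c(t, tm)),
                            glucose_mmol_l = c(y[1:4], ym, y[5:12]))
  expect_equal(compute_iauc(refined, baseline = base, window = NULL), ref)

  # monotonicity: raising any single reading never decreases iAUC
  for (k in c(1, 6, 12)) {
    up <- tr; up$glucose_mmol_l[k] <- up$glucose_mmol_l[k] + 0.5
    expect_gte(compute_iauc(up, baseline = base, window = NULL), ref)
  }
})

test_that("fasting glucose takes the last pre-ingestion reading", {
  tr <- tibble::tibble(t_min = c(-4, -2, 0, 2),
                       glucose_mmol_l = c(5.0, 5.1, 5.3, 5.6))
  expect_equal(fasting_glucose(tr), 5.3)
  tr2 <- tibble::tibble(t_min = c(2, 4), glucose_mmol_l = c(5.2, 5.4))
  expect_warning(fg <- fasting_glucose(tr2), "first reading")
  expect_equal(fg, 5.2)
  expect_error(fasting_glucose(tibble::tibble(t_min = numeric(),
                                              glucose_mmol_l = numeric())),
               "at least")
  expect_error(compute_iauc(tibble::tibble(t_min = c(0, 0, 10),
                                           glucose_mmol_l = c(5, 5, 6))),
               "strictly increasing")
})

test_that("summaries bundle the component metrics", {
  s <- summarize_trace(triangle)
  expect_equal(s$iauc, 60)
  expect_equal(s$peak, 7)
  expect_equal(s$fasting, 5)
  expect_equal(s$time_above_baseline, 60)

  flat <- tibble::tibble(t_min = c(0, 60), glucose_mmol_l = c(5, 5))
  sf <- summarize_trace(flat)
  expect_equal(sf$iauc, 0)
  expect_equal(sf$peak, sf$fasting)
  expect_equal(sf$time_above_baseline, 0)

  below <- tibble::tibble(t_min = c(0, 30, 60), glucose_mmol_l = c(5, 4, 4))
  expect_equal(summarize_trace(below)$iauc, 0)
})

test_that("integration window is clipped exactly", {
  tr <- tibble::tibble(t_min = c(0, 60, 180), glucose_mmol_l = c(5, 7, 5))
  # within [0, 120]: up-leg area 60 + down-leg from 7 at 60 to 6 at 120
  expect_equal(compute_iauc(tr), 60 + (2 + 1) / 2 * 60)
  expect_equal(compute_iauc(tr, window = NULL), 60 + 120)
})

test_that("CGM reader converts units and validates schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(participant_id = "P1", t_min = c(0, 30),
                                  glucose_mg_dl = c(90.08, 108.096)), path)
  tr <- read_cgm_csv(path)
  expect_equal(tr$glucose_mmol_l, c(5.0, 6.0), tolerance = 1e-6)

  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(participant_id = "P1", t_min = 0, foo = 5),
                   path2)
  expect_error(read_cgm_csv(path2), "glucose")
})
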