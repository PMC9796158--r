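gaussian_series <- function(a, b, c, d = 0, days = c(10, 25, 40, 55, 70, 85, 100, 115)) {
  data.frame(das = days, value = d + a * exp(-(days - b)^2 / (2 * c^2)))
}

test_that("noiseless series refit to their generating parameters", {
  ser <- gaussian_series(100, 90, 20)
  cv <- fit_growth_curve(ser)
  expect_equal(cv$a, 100, tolerance = 1e-6)
  expect_equal(cv$b, 90, tolerance = 1e-6)
  expect_equal(cv$c, 20, tolerance = 1e-6)
  expect_equal(cv$d, 0, tolerance = 1e-6)
  expect_lt(cv$rss, 1e-10)

  with_offset <- gaussian_series(55, 72, 14, d = 12)
  cv2 <- fit_growth_curve(with_offset)
  expect_equal(c(cv2$a, cv2$b, cv2$c, cv2$d), c(55, 72, 14, 12), tolerance = 1e-5)

  expect_error(fit_growth_curve(data.frame(das = c(10, 30, 50, 70, 90), value = 5)),
               "all trait values are equal")
  expect_error(fit_growth_curve(gaussian_series(100, 90, 20)[1:4, ]), "at least 5")
})

test_that("noisy refits recover the peak day within tolerance", {
  set.seed(17)
  errs <- replicate(50, {
    ser <- gaussian_series(100, 90, 20)
    ser$value <- ser$value + rnorm(nrow(ser), 0, 2)
    abs(fit_growth_curve(ser)$b - 90)
  })
  expect_lte(median(errs), 3)
})

test_that("the growth-difference curve is the analytic derivative", {
  cv <- fit_growth_curve(gaussian_series(100, 90, 20))
  fx <- growth_difference_curve(cv, step = 0.1)
  at_b <- fx$rate[which.min(abs(fx$das - cv$b))]
  expect_lt(abs(at_b), 0.02) # derivative ~0 at the peak

  expect_true(all(fx$rate[fx$das < cv$b - 3 * cv$c] > 0))
  expect_true(all(fx$rate[fx$das > cv$b + 3 * cv$c] < 0))

  # central-difference oracle
  t <- seq(15, 110, by = 2.5)
  h <- 1e-3
  numeric_d <- (eval_growth_curve(cv, t + h) - eval_growth_curve(cv, t - h)) / (2 * h)
  expect_lt(max(abs(numeric_d - eval_growth_curve(cv, t, deriv = 1))), 1e-6)
})

test_that("knee points sit at the inflection days b +/- c", {
  cv <- fit_growth_curve(gaussian_series(100, 90, 20))
  kp <- locate_knee_points(cv)
  expect_equal(kp$kp1, 70, tolerance = 1e-4)
  expect_equal(kp$kp2, 110, tolerance = 1e-4)
  expect_equal(kp$rgp_days, 40, tolerance = 1e-4)
  expect_false(kp$clipped)

  narrow <- fit_growth_curve(gaussian_series(80, 50, 5, days = seq(20, 80, by = 10)))
  kpn <- locate_knee_points(narrow)
  expect_equal(c(kpn$kp1, kpn$kp2), c(45, 55), tolerance = 0.1)

  # clipping: kp2 beyond the sampled domain
  late <- list(a = 100, b = 95, c = 10, d = 0, domain = c(0, 100))
  class(late) <- "growth_curve"
  kpl <- locate_knee_points(late)
  expect_equal(kpl$kp2, 100)
  expect_true(kpl$clipped)

  none <- list(a = 100, b = 300, c = 10, d = 0, domain = c(0, 100))
  class(none) <- "growth_curve"
  expect_false(locate_knee_points(none)$defined)
})

test_that("fastest growth rate sits at the rising inflection with closed-form value", {
  cv <- fit_growth_curve(gaussian_series(100, 90, 20))
  fgr <- fastest_growth_rate(cv)
  expect_equal(fgr$fgr_day, 70, tolerance = 0.1)
  expect_equal(fgr$fgr_value, (100 / 20) * exp(-0.5), tolerance = 1e-3)

  cv2 <- fit_growth_curve(gaussian_series(200, 90, 20))
  fgr2 <- fastest_growth_rate(cv2)
  expect_equal(fgr2$fgr_value / fgr$fgr_value, 2, tolerance = 1e-3)
  expect_equal(fgr2$fgr_day, fgr$fgr_day)

  set.seed(23)
  for (i in 1:10) {
    a <- runif(1, 50, 150); b <- runif(1, 60, 100); c <- runif(1, 12, 25)
    cvr <- fit_growth_curve(gaussian_series(a, b, c))
    f <- fastest_growth_rate(cvr)
    expect_lt(abs(f$fgr_day - (b - c)), 0.1 + 1e-3)
  }
})

test_that("average growth rate matches its closed-form definition", {
  cv <- fit_growth_curve(gaussian_series(100, 90, 20))
  f70 <- eval_growth_curve(cv, 70); f0 <- eval_growth_curve(cv, 0)
  expect_equal(average_growth_rate(cv, 0, 70),
               100 * (f70 - f0) / (70 * 100), tolerance = 1e-6)
  expect_equal(average_growth_rate(cv, 0, 70), 0.8664, tolerance = 1e-3)

  # symmetric interval about the peak: zero net growth
  expect_equal(average_growth_rate(cv, 70, 110), 0, tolerance = 1e-6)
  expect_error(average_growth_rate(cv, 50, 50), "before")
  expect_equal(average_growth_rate(cv, 0, 70, normalize = FALSE),
               (f70 - f0) / 70, tolerance = 1e-9)
})

test_that("normalized curvature peaks at the vertex with kappa = a / c^2", {
  cv <- fit_growth_curve(gaussian_series(100, 90, 20))
  fx <- curvature_curve(cv, step = 0.1)
  expect_equal(attr(fx, "max_curvature"), 100 / 400, tolerance = 1e-4)
  expect_equal(max(fx$curvature), 1)
  expect_equal(fx$das[which.max(fx$curvature)], 90, tolerance = 0.1)

  # quadratic-vertex oracle: near its peak a Gaussian is y ~ const - (a/c^2) t^2/2,
  # so a = 50, c = 5 gives the parabola y = -x^2 locally, kappa(vertex) = 2
  quad <- fit_growth_curve(gaussian_series(50, 60, 5, days = seq(40, 80, by = 5)))
  expect_equal(aerialpheno:::curvature_values(quad, quad$b), 2, tolerance = 1e-6)

  flat <- list(a = 0, b = 50, c = 10, d = 5, domain = c(0, 100))
  class(flat) <- "growth_curve"
  fxf <- curvature_curve(flat)
  expect_true(attr(fxf, "flat"))
  expect_true(all(fxf$curvature == 0))
})

test_that("stage days come from the curvature extrema", {
  cv <- fit_growth_curve(gaussian_series(100, 90, 20, days = seq(10, 115, by = 15)))
  st <- estimate_stage_days(curvature_curve(cv))
  expect_equal(st$max_trait_day, 90, tolerance = 0.2)
  expect_equal(st$ripening_day, 110, tolerance = 1)

  # still-rising curve: peak beyond the domain, no ripening minimum
  rising <- list(a = 100, b = 150, c = 30, d = 0, domain = c(10, 80))
  class(rising) <- "growth_curve"
  st2 <- estimate_stage_days(curvature_curve(rising))
  expect_true(is.na(st2$ripening_day))
})

test_that("dynamic phenotypes compose the closed forms", {
  dp <- dynamic_phenotypes(gaussian_series(100, 90, 20))
  expect_equal(dp$rgp_start, 70, tolerance = 1e-3)
  expect_equal(dp$rgp_end, 110, tolerance = 1e-3)
  expect_equal(dp$fgr_day, 70, tolerance = 0.1)
  expect_equal(dp$max_day, 90, tolerance = 1e-4)
  expect_equal(dp$max_value, 100, tolerance = 1e-4)
  expect_equal(dp$agr_to_fgr, 0.8664, tolerance = 1e-2)

  capped <- dynamic_phenotypes(gaussian_series(0.9, 80, 25, d = 0.3), value_cap = 1)
  expect_equal(capped$max_value, 1)

  expect_error(dynamic_phenotypes(gaussian_series(100, 90, 20)[1:4, ]), "at least 5")
})

test_that("phenotype days shift with time and values scale with amplitude", {
  base <- dynamic_phenotypes(gaussian_series(100, 90, 20))
  days <- c(10, 25, 40, 55, 70, 85, 100, 115)
  shifted <- dynamic_phenotypes(data.frame(das = days + 15,
                                           value = gaussian_series(100, 90, 20)$value))
  for (f in c("rgp_start", "rgp_end", "fgr_day", "max_day")) {
    expect_equal(shifted[[f]], base[[f]] + 15, tolerance = 0.11)
  }
  expect_equal(shifted$rgp_days, base$rgp_days, tolerance = 0.01)
  expect_equal(shifted$fgr_value, base$fgr_value, tolerance = 1e-4)
  expect_equal(shifted$agr_in_rgp, base$agr_in_rgp, tolerance = 1e-4)

  scaled <- dynamic_phenotypes(gaussian_series(300, 90, 20))
  expect_equal(scaled$fgr_value, 3 * base$fgr_value, tolerance = 1e-4)
  expect_equal(scaled$fgr_day, base$fgr_day, tolerance = 0.01)
  expect_equal(scaled$agr_to_max, base$agr_to_max, tolerance = 1e-4)
})

test_that("the phenotype table handles mixed good and degenerate series", {
  good <- generate_growth_series(data.frame(plot_id = c("P1", "P2"),
                                            a = c(100, 80), b = c(90, 85),
                                            c = c(20, 18), d = 0), seed = 5)
  flatline <- data.frame(plot_id = "P3", das = c(10, 25, 40, 55, 70),
                         trait = "h90", value = 7)
  tab <- dynamic_phenotype_table(rbind(good, flatline))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$fit_error[tab$plot_id != "P3"], c("", ""))
  expect_match(tab$fit_error[tab$plot_id == "P3"], "equal")
  expect_true(all(is.na(tab$max_day[tab$plot_id == "P3"])))
  expect_equal(tab$max_day[tab$plot_id == "P1"], 90, tolerance = 0.11)
})
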