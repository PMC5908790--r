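test_that("T0 normalization follows its definition and averages replicate wells", {
  # signal equal to the T0 mean is 100%; twice the mean is 200%
  d <- normalize_to_t0(c(10, 100), c(100, 200), t0_signals = c(100, 100),
                       dmso_signals = c(300))
  expect_equal(d$response, c(100, 200))
  # uneven anchors: T0 wells {90, 110} average to 100, so signal 150 -> 150
  d2 <- normalize_to_t0(50, 150, t0_signals = c(90, 110), dmso_signals = 300)
  expect_equal(d2$response, 150)
  expect_equal(d2$dmso_level, 300)
  # replicate wells at the same concentration are arithmetically averaged
  d3 <- normalize_to_t0(c(10, 10, 100), c(90, 110, 50), t0_signals = 100,
                        dmso_signals = 200)
  expect_equal(d3$conc, c(10, 100))
  expect_equal(d3$response, c(100, 50))
  expect_error(normalize_to_t0(10, 100, numeric(0), 300), "anchor")
  expect_error(normalize_to_t0(10, 100, c(100, -5), 300), "anchor")
})

test_that("noise-free 4PL fits recover the generating parameters", {
  cv <- fourpl_curve(0, 300, 1000, 1)
  fit <- fit_fourpl(make_curve_data(cv))
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$curve$bottom - 0), 1e-4)
  expect_lt(abs(fit$curve$top - 300) / 300, 1e-6)
  expect_lt(abs(fit$curve$inflection - 1000) / 1000, 1e-6)
  expect_lt(abs(fit$curve$slope - 1), 1e-6)
  # flat data: degenerate, flagged, no exception
  flat <- normalized_curve_data(c(1, 10, 100, 1000), rep(100, 4), dmso_level = 100)
  ffit <- fit_fourpl(flat)
  expect_true(ffit$degenerate)
  expect_lt(ffit$curve$top - ffit$curve$bottom, 1.01)
})

test_that("curve inversion is closed-form, censors correctly and round-trips", {
  cv <- fourpl_curve(0, 300, 1000, 1)
  expect_equal(invert_fourpl(cv, 200)$value, 500)
  expect_equal(invert_fourpl(cv, 100)$value, 2000)
  expect_equal(invert_fourpl(cv, 350)$censor, "unreachable")
  expect_equal(invert_fourpl(cv, -5)$censor, "unreachable")
  gt <- invert_fourpl(cv, 100, max_conc = 1500)
  expect_equal(gt$censor, "gt_max")
  expect_equal(gt$value, 1500)  # carries the bound
  # round trip to 1e-9 relative across random curves, including rising ones;
  # doses span the informative window (response within 0.1-99.9% of the span,
  # where a finite assay can resolve the level at all)
  set.seed(42)
  for (i in 1:25) {
    s <- sample(c(-1, 1), 1) * runif(1, 0.5, 3)
    cu <- fourpl_curve(runif(1, 0, 90), runif(1, 120, 400), 10^runif(1, 0, 4), s)
    x <- cu$inflection * 10^(runif(5, -3, 3) / abs(s))
    y <- fourpl_response(cu, x)
    xi <- vapply(y, function(l) invert_fourpl(cu, l)$value, numeric(1))
    expect_lt(max(abs(xi - x) / x), 1e-9)
  }
})

test_that("growth metrics match closed forms, censor correctly and agree with a grid oracle", {
  cv <- fourpl_curve(0, 300, 1000, 1)
  dat <- make_curve_data(cv)  # dmso 300, max 30000
  gm <- growth_metrics(fit_fourpl(dat), dat)
  expect_lt(abs(gm$gic50$value - 500) / 500, 1e-3)
  expect_lt(abs(gm$gic100$value - 2000) / 2000, 1e-3)
  expect_lt(abs(gm$dec50$value - 5000) / 5000, 1e-3)
  # Ymin - T0 from the fitted curve restricted to the tested range:
  # 300/(1 + 30000/1000) - 100
  expect_lt(abs(gm$ymin_minus_t0 - (300 / 31 - 100)), 1e-3)
  # grid-search inversion oracle agrees to 0.1%
  for (lv in c(200, 100, 50)) {
    expect_lt(abs(grid_invert_oracle(cv, lv, 1, 30000) -
                    invert_fourpl(cv, lv)$value) / invert_fourpl(cv, lv)$value,
              1e-3)
  }
  # cytostatic-only curve: floor above the death level censors dEC50 and gIC100
  cyto <- fourpl_curve(120, 300, 1000, 1)
  gmc <- growth_metrics(cyto, make_curve_data(cyto))
  expect_equal(gmc$dec50$censor, "unreachable")
  expect_equal(gmc$gic100$censor, "unreachable")
  expect_equal(gmc$gic50$censor, "none")
  # shallow responder: midpoint of the growth window beyond the tested range
  res <- fourpl_curve(180, 300, 5e6, 1)
  gmr <- growth_metrics(res, make_curve_data(res))
  expect_equal(gmr$gic50$censor, "gt_max")
  # degenerate fit: all concentrations censored, ymin from the DMSO level
  flat <- normalized_curve_data(c(1, 10, 100, 1000), rep(250, 4), dmso_level = 250)
  gmd <- growth_metrics(fit_fourpl(flat), flat)
  expect_true(all(c(gmd$gic50$censor, gmd$gic100$censor, gmd$dec50$censor) != "none"))
  expect_equal(gmd$ymin_minus_t0, 150)
})

test_that("attained metrics are ordered gIC50 <= gIC100 <= dEC50 and scale-equivariant", {
  set.seed(7)
  for (i in 1:40) {
    cu <- fourpl_curve(runif(1, 0, 45), runif(1, 150, 400),
                       10^runif(1, 1, 3.5), runif(1, 0.6, 2.5))
    dat <- make_curve_data(cu)
    gm <- growth_metrics(cu, dat)
    vals <- c(gm$gic50$value, gm$gic100$value, gm$dec50$value)
    cens <- c(gm$gic50$censor, gm$gic100$censor, gm$dec50$censor)
    if (all(cens == "none")) expect_true(all(diff(vals) >= 0))
    # multiplying all concentrations by k multiplies the metrics by k
    k <- 7.3
    cu_k <- fourpl_curve(cu$bottom, cu$top, cu$inflection * k, cu$slope)
    gm_k <- growth_metrics(cu_k, make_curve_data(cu_k, concs = dat$conc * k))
    if (gm$gic50$censor == "none")
      expect_equal(gm_k$gic50$value, k * gm$gic50$value, tolerance = 1e-9)
  }
})

test_that("replicate aggregation uses geometric means and the censoring policy", {
  gm <- function(g50, cens = "none", ymin = 10, mx = 30000) {
    structure(list(gic50 = list(value = g50, censor = cens),
                   gic100 = list(value = g50 * 2, censor = cens),
                   dec50 = list(value = g50 * 4, censor = cens),
                   ymin_minus_t0 = ymin, dmso_level = 300, max_tested_conc = mx),
              class = "growth_metrics")
  }
  # geometric mean: {100, 10000} -> 1000
  ag <- aggregate_replicates(list(gm(100), gm(10000)))
  expect_equal(ag$gic50$value, 1000)
  expect_equal(ag$ymin_minus_t0, 10)
  expect_false(ag$partial[["gic50"]])
  # one censored + one 500 -> 500, flagged partial
  ag2 <- aggregate_replicates(list(gm(30000, "gt_max"), gm(500)))
  expect_equal(ag2$gic50$value, 500)
  expect_true(ag2$partial[["gic50"]])
  # censored in the aggregate only if censored in all replicates
  ag3 <- aggregate_replicates(list(gm(20000, "gt_max", mx = 20000),
                                   gm(30000, "gt_max", mx = 30000)))
  expect_equal(ag3$gic50$censor, "gt_max")
  expect_equal(ag3$gic50$value, 30000)  # largest bound
  # single replicate is the identity
  expect_equal(aggregate_replicates(list(gm(550)))$gic50$value, 550)
  expect_error(aggregate_replicates(list()), "at least one")
})

test_that("2% measurement noise leaves the fitted inflection within 20% of truth", {
  set.seed(314)
  truth <- fourpl_curve(20, 250, 800, 1.1)
  concs <- 30000 / 3^(9:0)
  ok <- 0L
  for (i in 1:200) {
    y <- fourpl_response(truth, concs) * rnorm(10, 1, 0.02)
    fit <- fit_fourpl(normalized_curve_data(concs, y, dmso_level = 250))
    ok <- ok + (abs(fit$curve$inflection - 800) / 800 < 0.2)
  }
  expect_gte(ok, 190)  # >= 95% of runs
})
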