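truth_default <- kinetic_model(kon = 2.2e5, koff = 0.16, Rmax = 0.8)

test_that("equilibrium response at C = KD plateaus at Rmax/2", {
  tr <- kinetic_model(1e5, 1e-3, 1.0)  # slow off-rate: needs long association
  sg <- simulate_sensorgram(tr, tr$KD, t_assoc = 2e5, t_dissoc = 10, dt = 1000)
  assoc <- sg$traces[sg$traces$phase == "association", ]
  expect_equal(tail(assoc$response, 1), tr$Rmax / 2, tolerance = 1e-3)
})

test_that("dissociation is log-linear with slope -koff", {
  sg <- simulate_sensorgram(truth_default, 250e-9)
  dis <- sg$traces[sg$traces$phase == "dissociation" & sg$traces$response > 1e-12, ]
  fit <- lm(log(response) ~ time, data = dis)
  expect_equal(unname(coef(fit)["time"]), -truth_default$koff, tolerance = 1e-6)
})

test_that("observed association rates recover kon*C + koff from noiseless traces", {
  concs <- dilution_series(500e-9, 5)
  sg <- simulate_sensorgram(truth_default, concs, dt = 0.5)
  for (C in concs) {
    tr <- sg$traces[sg$traces$concentration == C & sg$traces$phase == "association", ]
    Req <- truth_default$Rmax * C / (C + truth_default$KD)
    # log-transform: log(1 - R/Req) = -kobs * t
    keep <- tr$time > 0 & tr$response / Req < 0.999
    slope <- coef(lm(log(1 - tr$response[keep] / Req) ~ tr$time[keep]))[[2]]
    expect_equal(-slope, truth_default$kon * C + truth_default$koff,
                 tolerance = 1e-6)
  }
})

test_that("noiseless global fit recovers the generating parameters to 0.1%", {
  d <- make_bli_dataset(truth_default, noise_sd = 0)
  ft <- fit_1to1(d$sensorgram)
  expect_true(ft$converged)
  expect_lt(abs(ft$model$kon - truth_default$kon) / truth_default$kon, 1e-3)
  expect_lt(abs(ft$model$koff - truth_default$koff) / truth_default$koff, 1e-3)
  expect_lt(abs(ft$model$Rmax - truth_default$Rmax) / truth_default$Rmax, 1e-3)
  expect_identical(ft$model$KD, ft$model$koff / ft$model$kon)
})

test_that("fit at 2% noise recovers kon and koff within 5%", {
  d <- make_bli_dataset(truth_default, noise_sd = 0.02 * truth_default$Rmax,
                        seed = 7)
  ft <- fit_1to1(d$sensorgram)
  expect_true(ft$converged)
  expect_lt(abs(ft$model$kon - truth_default$kon) / truth_default$kon, 0.05)
  expect_lt(abs(ft$model$koff - truth_default$koff) / truth_default$koff, 0.05)
  expect_true(all(is.finite(ft$stderr)))
})

test_that("koff from dissociation-only data matches the global fit within error", {
  d <- make_bli_dataset(truth_default, noise_sd = 0.02 * truth_default$Rmax,
                        seed = 3)
  ft <- fit_1to1(d$sensorgram)
  dis <- d$sensorgram$traces[d$sensorgram$traces$phase == "dissociation", ]
  dis$t0 <- dis$time - d$sensorgram$t_assoc
  dis$cid <- as.integer(factor(dis$concentration))
  f2 <- nls(
    response ~ A[cid] * exp(-kd * t0), data = dis,
    start = list(A = vapply(split(dis, dis$cid),
                            function(x) max(x$response), numeric(1)),
                 kd = 0.1))
  koff_dis <- coef(f2)[["kd"]]
  tol <- 3 * max(ft$stderr[["koff"]], 1e-4)
  expect_lt(abs(koff_dis - ft$model$koff), tol)
})

test_that("degenerate designs come back flagged, not as exceptions", {
  # single concentration at KD, association only
  sg <- simulate_sensorgram(truth_default, truth_default$KD, t_assoc = 180,
                            t_dissoc = 0, dt = 1)
  sg$traces <- sg$traces[sg$traces$phase == "association", ]
  ft <- fit_1to1(sg)
  expect_false(ft$converged)
  expect_match(ft$reason, "non-identifiable")
  expect_null(ft$model)

  # two concentrations but only 2-fold apart
  sg2 <- simulate_sensorgram(truth_default, c(100e-9, 200e-9))
  expect_false(fit_1to1(sg2)$converged)
})

test_that("response scaling moves Rmax only", {
  d <- make_bli_dataset(truth_default, noise_sd = 0.01 * truth_default$Rmax,
                        seed = 9)
  ft1 <- fit_1to1(d$sensorgram)
  scaled <- d$sensorgram
  scaled$traces$response <- scaled$traces$response * 5
  ft2 <- fit_1to1(scaled)
  expect_equal(ft2$model$Rmax / ft1$model$Rmax, 5, tolerance = 1e-3)
  expect_equal(ft2$model$kon, ft1$model$kon, tolerance = 1e-3)
  expect_equal(ft2$model$koff, ft1$model$koff, tolerance = 1e-3)
})

test_that("a bivalent analyte shows at least 10-fold apparent avidity gain", {
  bi <- simulate_bivalent_sensorgram(truth_default, dilution_series(500e-9, 6))
  ft <- fit_1to1(bi)
  expect_true(ft$converged)
  expect_lt(ft$model$KD, truth_default$KD / 10)
})

test_that("simulation validates inputs and is reproducible by seed", {
  expect_error(simulate_sensorgram(truth_default, c(1e-9, -1e-9)), "> 0")
  expect_error(kinetic_model(-1, 1, 1))
  s1 <- simulate_sensorgram(truth_default, 1e-7, noise_sd = 0.01, seed = 5)
  s2 <- simulate_sensorgram(truth_default, 1e-7, noise_sd = 0.01, seed = 5)
  s3 <- simulate_sensorgram(truth_default, 1e-7, noise_sd = 0.01, seed = 6)
  expect_identical(s1$traces$response, s2$traces$response)
  expect_false(identical(s1$traces$response, s3$traces$response))
})
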