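test_that("the noise-free sensorgram equals the closed form", {
  ka <- 1e5; kd <- 1e-3; Rmax <- 120; C <- 5e-8
  sg <- simulate_sensorgram(ka, kd, Rmax, C, t_assoc = 100, t_dissoc = 200,
                            dt = 0.5)
  kobs <- ka * C + kd
  Req <- ka * C * Rmax / kobs
  t <- sg$times
  expected <- ifelse(
    t <= 100, Req * (1 - exp(-kobs * t)),
    Req * (1 - exp(-kobs * 100)) * exp(-kd * (t - 100)))
  expect_equal(sg$response, expected, tolerance = 1e-12)
})

test_that("with kd = 0 the association plateau is Rmax", {
  sg <- simulate_sensorgram(1e5, 0, 80, 1e-6, t_assoc = 5000, t_dissoc = 10)
  expect_equal(max(sg$response), 80, tolerance = 1e-4)
})

test_that("dissociation half-life is ln(2)/kd", {
  kd <- 1.15e-3                      # printed myostatin/myostatin off-rate
  half <- log(2) / kd                # ~602.7 s
  expect_equal(half, 602.7, tolerance = 1e-4)
  sg <- simulate_sensorgram(1e5, kd, 100, 1e-7, t_assoc = 180,
                            t_dissoc = 1500, dt = 0.1)
  r <- function(t) sg$response[which.min(abs(sg$times - t))]
  expect_equal(r(180 + half) / r(180), 0.5, tolerance = 1e-3)
  expect_equal(r(180 + 2 * half) / r(180), 0.25, tolerance = 1e-3)
})

test_that("noise-free curves are monotone and Req is bounded by Rmax", {
  set.seed(67)
  for (rep in 1:10) {
    ka <- 10^runif(1, 3, 6); kd <- 10^runif(1, -5, -2)
    Rmax <- runif(1, 50, 500)
    concs <- sort(10^runif(4, -9, -6))
    reqs <- vapply(concs, function(C) {
      sg <- simulate_sensorgram(ka, kd, Rmax, C)
      assoc <- sg$response[sg$times <= sg$t_assoc_end]
      dissoc <- sg$response[sg$times >= sg$t_assoc_end]
      expect_true(all(diff(assoc) >= -1e-9))
      expect_true(all(diff(dissoc) <= 1e-9))
      ka * C * Rmax / (ka * C + kd)
    }, 0)
    expect_true(all(diff(reqs) > 0))       # Req increases with concentration
    expect_true(all(reqs <= Rmax))
  }
})

test_that("simulation noise is reproducible by seed and leaves the RNG alone", {
  a <- simulate_sensorgram(1e4, 1e-3, 100, 1e-8, noise_sd = 2, seed = 5)
  b <- simulate_sensorgram(1e4, 1e-3, 100, 1e-8, noise_sd = 2, seed = 5)
  expect_identical(a$response, b$response)
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(simulate_sensorgram(1e4, 1e-3, 100, 1e-8,
                                              noise_sd = 2, seed = 5))
  expect_identical(rnorm(1), x1)
  expect_error(simulate_sensorgram(1e4, 1e-3, 100, 1e-8, dt = 0), "dt")
})

test_that("the global fit recovers exact-model parameters to <0.1%", {
  conc <- c(6.25, 12.5, 25, 50, 100) * 1e-9
  truth <- list(ka = 4.01e4, kd = 9.88e-4, Rmax = 150)
  sgs <- lapply(conc, function(C)
    simulate_sensorgram(truth$ka, truth$kd, truth$Rmax, C))
  fit <- fit_kinetics(sgs)
  expect_lt(abs(fit$ka - truth$ka) / truth$ka, 1e-3)
  expect_lt(abs(fit$kd - truth$kd) / truth$kd, 1e-3)
  expect_lt(abs(fit$Rmax - truth$Rmax) / truth$Rmax, 1e-3)
  expect_equal(fit$KD, fit$kd / fit$ka)     # exact identity
  expect_false(fit$ill_conditioned)
})

test_that("single-concentration fits are flagged ill-conditioned", {
  sg <- simulate_sensorgram(1e5, 1e-3, 100, 5e-8)
  expect_true(fit_kinetics(list(sg))$ill_conditioned)
})

test_that("kd_from_rates reproduces the printed equilibrium constants", {
  expect_equal(kd_from_rates(1, 1), 1)
  expect_equal(kd_from_rates(4.41e4, 4.32e-6), 9.79e-11, tolerance = 0.01)
  expect_equal(kd_from_rates(5.58e3, 1.15e-3), 2.061e-7, tolerance = 1e-3)
  expect_error(kd_from_rates(0, 1), "ka")
})

test_that("sensorgram CSV round trip preserves curves and phases", {
  sgs <- lapply(c(1e-8, 5e-8), function(C)
    simulate_sensorgram(1e5, 1e-3, 100, C, noise_sd = 1, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensorgrams_csv(sgs, f)
  back <- read_sensorgrams_csv(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$response, sgs[[1]]$response)
  expect_equal(back[[2]]$concentration, 5e-8)
  expect_equal(back[[1]]$t_assoc_end, 180)
})
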