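# 1:1 Langmuir surface plasmon resonance: closed-form sensorgram simulation
# and global least-squares fitting of (ka, kd, Rmax) across a concentration
# series. Inputs are assumed reference-subtracted response units.

langmuir_response <- function(t, ka, kd, Rmax, conc, t_assoc) {
  kobs <- ka * conc + kd
  Req <- if (kobs > 0) ka * conc * Rmax / kobs else 0
  r_assoc <- Req * (1 - exp(-kobs * pmin(t, t_assoc)))
  r_end <- Req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc, r_assoc, r_end * exp(-kd * (t - t_assoc)))
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Association phase \eqn{R(t) = R_{eq}(1 - e^{-(k_a C + k_d)t})} with
#' \eqn{R_{eq} = k_a C R_{max}/(k_a C + k_d)}; dissociation phase
#' \eqn{R(t) = R(t_{assoc}) e^{-k_d (t - t_{assoc})}}. Gaussian noise of sd
#' `noise_sd` RU is added when positive, reproducibly under `seed`.
#'
#' @param ka Association rate, 1/(M s).
#' @param kd Dissociation rate, 1/s (0 allowed: plateau at `Rmax`).
#' @param Rmax Analyte binding capacity, RU.
#' @param concentration Analyte concentration, M.
#' @param t_assoc,t_dissoc Phase durations, s (defaults 180/300 as in the
#'   standard kinetic protocol).
#' @param dt Sampling interval, s (> 0).
#' @param noise_sd Gaussian noise sd, RU.
#' @param seed Optional integer seed (local RNG stream; the caller's RNG state
#'   is untouched).
#' @return A `sensorgram`: list with `concentration`, `times`, `response`,
#'   `t_assoc_end`.
#' @export
simulate_sensorgram <- function(ka, kd, Rmax, concentration,
                                t_assoc = 180, t_dissoc = 300, dt = 1,
                                noise_sd = 0, seed = NULL) {
  stopifnot(ka > 0, kd >= 0, Rmax > 0, concentration > 0,
            t_assoc > 0, t_dissoc > 0)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  resp <- langmuir_response(times, ka, kd, Rmax, concentration, t_assoc)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    resp <- resp + rnorm(length(resp), 0, noise_sd)
  }
  structure(list(concentration = concentration, times = times,
                 response = resp, t_assoc_end = t_assoc),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram> C = %.3g M, %d points, association ends at %g s\n",
              x$concentration, length(x$times), x$t_assoc_end))
  invisible(x)
}

#' Write/read sensorgrams as CSV
#'
#' Columns: `time_s`, `response_RU`, `concentration_M`, `phase`.
#' @param sensorgrams List of `sensorgram` objects.
#' @param path CSV path.
#' @export
write_sensorgrams_csv <- function(sensorgrams, path) {
  rows <- lapply(sensorgrams, function(sg) {
    data.frame(time_s = sg$times, response_RU = sg$response,
               concentration_M = sg$concentration,
               phase = ifelse(sg$times <= sg$t_assoc_end,
                              "association", "dissociation"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensorgrams_csv
#' @return `read_sensorgrams_csv`: a list of `sensorgram` objects (one per
#'   concentration/injection block in file order).
#' @export
read_sensorgrams_csv <- function(path) {
  df <- utils::read.csv(path)
  # consecutive rows with the same concentration form one curve
  block <- cumsum(c(TRUE, diff(match(df$concentration_M,
                                     unique(df$concentration_M))) != 0 |
                      diff(df$time_s) < 0))
  lapply(split(df, block), function(d) {
    ta <- max(d$time_s[d$phase == "association"])
    structure(list(concentration = d$concentration_M[1], times = d$time_s,
                   response = d$response_RU, t_assoc_end = ta),
              class = "sensorgram")
  })
}

fit_residuals <- function(logp, sensorgrams, masks) {
  ka <- exp(logp[1]); kd <- exp(logp[2]); Rmax <- exp(logp[3])
  unlist(lapply(seq_along(sensorgrams), function(i) {
    sg <- sensorgrams[[i]]
    pred <- langmuir_response(sg$times, ka, kd, Rmax, sg$concentration,
                              sg$t_assoc_end)
    (sg$response - pred)[masks[[i]]]
  }), use.names = FALSE)
}

#' Globally fit 1:1 Langmuir kinetics to a sensorgram set
#'
#' Damped least squares on log-parameters with shared (ka, kd, Rmax) across
#' all curves. Initialization: a log-linear fit of the dissociation phase of
#' the largest-response curve gives kd; per-curve observed-rate estimates
#' regressed on concentration (kobs = ka C + kd) give ka; Rmax follows from
#' the association plateau. The first `exclude_s` seconds after each phase
#' boundary are excluded from the fit (injection artifacts) by default.
#'
#' @param sensorgrams List of `sensorgram` objects (>= 2 concentrations
#'   recommended; single-curve fits are flagged ill-conditioned).
#' @param exclude_s Seconds excluded after each phase start (default 2).
#' @param maxit Optimizer iteration budget.
#' @return A `kinetic_fit`: `ka`, `kd`, `KD` (= kd/ka exactly), `Rmax`, `rss`,
#'   `per_curve_rss`, `convergence`, `ill_conditioned`.
#' @export
fit_kinetics <- function(sensorgrams, exclude_s = 2, maxit = 2000L) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(length(sensorgrams) >= 1L)
  ill <- length(unique(vapply(sensorgrams, `[[`, 0, "concentration"))) < 2L
  masks <- lapply(sensorgrams, function(sg) {
    sg$times > exclude_s &
      !(sg$times > sg$t_assoc_end & sg$times <= sg$t_assoc_end + exclude_s)
  })

  # --- initialization --------------------------------------------------
  top <- which.max(vapply(sensorgrams, function(sg) max(sg$response), 0))
  sg <- sensorgrams[[top]]
  dis <- sg$times > sg$t_assoc_end + exclude_s & sg$response > 0
  kd0 <- 1e-4
  if (sum(dis) > 5L) {
    sl <- coef(lm(log(sg$response[dis]) ~ sg$times[dis]))[2]
    if (is.finite(sl) && sl < 0) kd0 <- -sl
  }
  kd0 <- max(kd0, 1e-8)
  kobs <- conc <- numeric(0)
  for (s2 in sensorgrams) {
    a <- s2$times <= s2$t_assoc_end & s2$times > exclude_s
    r <- s2$response[a]; tt <- s2$times[a]
    plateau <- max(mean(tail(r, max(5L, length(r) %/% 10L))), max(r) * 0.5)
    # time to reach 63.2% of plateau approximates 1/kobs
    i63 <- which(r >= 0.632 * plateau)[1]
    if (!is.na(i63) && tt[i63] > 0) {
      kobs <- c(kobs, 1 / tt[i63]); conc <- c(conc, s2$concentration)
    }
  }
  ka0 <- if (length(kobs) >= 2L) {
    slope <- coef(lm(kobs ~ conc))[2]
    if (is.finite(slope) && slope > 0) slope else 1e4
  } else 1e4
  Rmax0 <- {
    kobs_top <- ka0 * sg$concentration + kd0
    req_top <- max(sg$response) /
      max(1 - exp(-kobs_top * sg$t_assoc_end), 1e-6)
    max(req_top * (ka0 * sg$concentration + kd0) / (ka0 * sg$concentration),
        max(sg$response))
  }

  obj <- function(logp) sum(fit_residuals(logp, sensorgrams, masks)^2)
  p0 <- log(c(ka0, kd0, Rmax0))
  fit1 <- optim(p0, obj, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-12))
  fit2 <- tryCatch(
    optim(fit1$par, obj, method = "BFGS",
          control = list(maxit = 500L, reltol = 1e-14)),
    error = function(e) fit1)
  best <- if (fit2$value <= fit1$value) fit2 else fit1
  if (!is.finite(best$value)) {
    stop("kinetic fit did not converge (non-finite objective)", call. = FALSE)
  }
  p <- exp(best$par)
  per_curve <- vapply(seq_along(sensorgrams), function(i) {
    sg <- sensorgrams[[i]]
    pred <- langmuir_response(sg$times, p[1], p[2], p[3], sg$concentration,
                              sg$t_assoc_end)
    sum(((sg$response - pred)[masks[[i]]])^2)
  }, 0)
  structure(list(ka = p[1], kd = p[2], KD = p[2] / p[1], Rmax = p[3],
                 rss = best$value, per_curve_rss = per_curve,
                 convergence = best$convergence,
                 ill_conditioned = ill),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> ka = %.3g 1/(M s), kd = %.3g 1/s, KD = %.3g M, Rmax = %.3g RU (rss %.3g)%s\n",
    x$ka, x$kd, x$KD, x$Rmax, x$rss,
    if (x$ill_conditioned) " [ill-conditioned: single concentration]" else ""))
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param ka Association rate, 1/(M s), > 0.
#' @param kd Dissociation rate, 1/s.
#' @return KD = kd/ka (M).
#' @export
kd_from_rates <- function(ka, kd) {
  if (any(ka == 0)) stop("ka must be non-zero", call. = FALSE)
  kd / ka
}
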