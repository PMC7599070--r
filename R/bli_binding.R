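# 1:1 Langmuir biolayer-interferometry model: simulation, steady-state and
# kinetic fitting, and mutant/wild-type affinity fold changes.

#' Construct 1:1 binding parameters
#'
#' @param kon Association rate constant (M^-1 s^-1).
#' @param koff Dissociation rate constant (s^-1).
#' @param rmax Maximal response (response units).
#' @return Object of class `binding_params` with derived `kd = koff / kon`
#'   (molar).
#' @export
binding_params <- function(kon, koff, rmax = 1) {
  stopifnot(kon > 0, koff > 0, rmax > 0)
  structure(list(kon = kon, koff = koff, rmax = rmax, kd = koff / kon),
            class = "binding_params")
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Association: `R(t) = Req * (1 - exp(-(kon * C + koff) * t))` with
#' `Req = rmax * C / (C + kd)`; dissociation: exponential decay from the
#' response at the end of association with rate `koff`. Gaussian noise of the
#' given standard deviation is added with the given seed; `noise_sd = 0`
#' returns the exact model.
#'
#' @param params A [binding_params()].
#' @param conc Analyte concentration (M).
#' @param t_assoc,t_dissoc Phase durations (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Gaussian noise SD (response units).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return `data.frame` with `time_s`, `response`, `analyte_conc_M`, `phase`
#'   (`"association"`/`"dissociation"`), and attribute `t_assoc`.
#' @export
simulate_sensorgram <- function(params, conc, t_assoc = 600, t_dissoc = 600,
                                dt = 1, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "binding_params"), dt > 0)
  if (conc < 0) stop("analyte concentration cannot be negative")
  ta <- seq(0, t_assoc, by = dt)
  td <- seq(t_assoc + dt, t_assoc + t_dissoc, by = dt)
  req <- params$rmax * conc / (conc + params$kd)
  kobs <- params$kon * conc + params$koff
  r_assoc <- req * (1 - exp(-kobs * ta))
  r_end <- req * (1 - exp(-kobs * t_assoc))
  r_dissoc <- r_end * exp(-params$koff * (td - t_assoc))
  response <- c(r_assoc, r_dissoc)
  if (noise_sd > 0) {
    response <- response + with_seed(seed, stats::rnorm(length(response),
                                                        0, noise_sd))
  }
  out <- data.frame(
    time_s = c(ta, td),
    response = response,
    analyte_conc_M = conc,
    phase = c(rep("association", length(ta)),
              rep("dissociation", length(td))),
    stringsAsFactors = FALSE
  )
  attr(out, "t_assoc") <- t_assoc
  out
}

#' Fit the steady-state 1:1 binding isotherm
#'
#' Least-squares fit of `Req = rmax * C / (C + kd)`. As in the kinetics
#' module, rmax is conditionally linear given kd, so the fit is a
#' deterministic 1-D search over log10(kd).
#'
#' @param conc Analyte concentrations (M), at least 3 spanning >= 4-fold.
#' @param req Equilibrium responses, same length.
#' @return List of class `steady_state_fit`: `kd` (M), `rmax`,
#'   `residual_sse`, flags `saturated` (all responses equal; kd
#'   unidentifiable) and `narrow_range` (< 4-fold concentration span).
#' @export
fit_steady_state <- function(conc, req) {
  stopifnot(length(conc) == length(req), length(conc) >= 3L, all(conc > 0))
  span <- max(conc) / min(conc)
  narrow <- span < 4
  if (narrow) warning("concentration span < 4-fold; Kd poorly constrained")
  if (length(unique(req)) == 1L) {
    warning("all responses equal: saturated regime, Kd unidentifiable")
    return(structure(list(kd = NA_real_, rmax = req[1L],
                          residual_sse = 0, saturated = TRUE,
                          narrow_range = narrow),
                     class = "steady_state_fit"))
  }
  sse_of <- function(log10_kd) {
    kd <- 10^log10_kd
    g <- conc / (conc + kd)
    rmax <- sum(req * g) / sum(g * g)
    sum((req - rmax * g)^2)
  }
  lo <- log10(min(conc)) - 4
  hi <- log10(max(conc)) + 4
  grid <- seq(lo, hi, length.out = 400L)
  i0 <- which.min(vapply(grid, sse_of, numeric(1)))
  step <- grid[2L] - grid[1L]
  opt <- stats::optimize(sse_of, lower = max(lo, grid[i0] - 2 * step),
                         upper = min(hi, grid[i0] + 2 * step), tol = 1e-13)
  kd <- 10^opt$minimum
  g <- conc / (conc + kd)
  rmax <- sum(req * g) / sum(g * g)
  structure(list(kd = kd, rmax = rmax, residual_sse = opt$objective,
                 saturated = FALSE, narrow_range = narrow),
            class = "steady_state_fit")
}

#' Extract equilibrium responses from sensorgrams
#'
#' The steady-state response per trace is the mean of the last 5% of
#' association-phase samples.
#'
#' @param sensorgrams List of sensorgram `data.frame`s.
#' @return `data.frame` with `analyte_conc_M` and `req`.
#' @export
equilibrium_responses <- function(sensorgrams) {
  rows <- lapply(sensorgrams, function(sg) {
    a <- sg[sg$phase == "association", , drop = FALSE]
    k <- max(1L, ceiling(0.05 * nrow(a)))
    data.frame(analyte_conc_M = a$analyte_conc_M[1L],
               req = mean(utils::tail(a$response, k)))
  })
  do.call(rbind, rows)
}

#' Globally fit kinetic 1:1 binding parameters across sensorgrams
#'
#' Fits kon, koff and a shared rmax by least squares over all traces; rmax is
#' conditionally linear given (kon, koff), leaving a 2-D Nelder-Mead search
#' on the log scale, started from a log-linear dissociation fit for koff and
#' the association-rate relation `kobs = kon * C + koff` for kon.
#'
#' @param sensorgrams List of sensorgram `data.frame`s at >= 2 analyte
#'   concentrations (a single concentration triggers a local-fit warning).
#' @return A [binding_params()] with added `residual_sse`.
#' @export
fit_kinetics <- function(sensorgrams) {
  stopifnot(length(sensorgrams) >= 1L)
  concs <- vapply(sensorgrams, function(sg) sg$analyte_conc_M[1L], numeric(1))
  if (length(unique(concs)) < 2L) {
    warning("single analyte concentration: kon/koff weakly identified")
  }
  # koff start: pooled log-linear regression on dissociation phases
  koff0 <- stats::median(vapply(sensorgrams, function(sg) {
    d <- sg[sg$phase == "dissociation", , drop = FALSE]
    d <- d[d$response > 0, , drop = FALSE]
    if (nrow(d) < 3L) return(NA_real_)
    -unname(stats::coef(stats::lm(log(d$response) ~ d$time_s))[2L])
  }, numeric(1)), na.rm = TRUE)
  if (!is.finite(koff0) || koff0 <= 0) koff0 <- 1e-3
  kon0 <- koff0 / stats::median(concs)
  model_sse <- function(theta) {
    kon <- exp(theta[1L]); koff <- exp(theta[2L])
    kd <- koff / kon
    shapes <- lapply(sensorgrams, function(sg) {
      ta <- attr(sg, "t_assoc")
      if (is.null(ta)) ta <- max(sg$time_s[sg$phase == "association"])
      C <- sg$analyte_conc_M[1L]
      kobs <- kon * C + koff
      f <- (C / (C + kd)) * (1 - exp(-kobs * pmin(sg$time_s, ta)))
      dis <- sg$phase == "dissociation"
      f[dis] <- (C / (C + kd)) * (1 - exp(-kobs * ta)) *
        exp(-koff * (sg$time_s[dis] - ta))
      f
    })
    y <- unlist(lapply(sensorgrams, `[[`, "response"))
    f <- unlist(shapes)
    rmax <- sum(y * f) / sum(f * f)
    sum((y - rmax * f)^2)
  }
  opt <- stats::optim(c(log(kon0), log(koff0)), model_sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt <- stats::optim(opt$par, model_sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  kon <- exp(opt$par[1L]); koff <- exp(opt$par[2L])
  # recover rmax at the optimum
  kd <- koff / kon
  y <- unlist(lapply(sensorgrams, `[[`, "response"))
  f <- unlist(lapply(sensorgrams, function(sg) {
    ta <- attr(sg, "t_assoc")
    if (is.null(ta)) ta <- max(sg$time_s[sg$phase == "association"])
    C <- sg$analyte_conc_M[1L]
    kobs <- kon * C + koff
    shape <- (C / (C + kd)) * (1 - exp(-kobs * pmin(sg$time_s, ta)))
    dis <- sg$phase == "dissociation"
    shape[dis] <- (C / (C + kd)) * (1 - exp(-kobs * ta)) *
      exp(-koff * (sg$time_s[dis] - ta))
    shape
  }))
  rmax <- sum(y * f) / sum(f * f)
  out <- binding_params(kon = kon, koff = koff, rmax = rmax)
  out$residual_sse <- opt$value
  out
}

#' Fit the dissociation rate from a single dissociation phase
#'
#' Log-linear regression of response on time over the dissociation phase;
#' exact for a noise-free exponential.
#'
#' @param sensorgram One sensorgram `data.frame`.
#' @return `koff` (s^-1).
#' @export
fit_dissociation_rate <- function(sensorgram) {
  d <- sensorgram[sensorgram$phase == "dissociation" &
                    sensorgram$response > 0, , drop = FALSE]
  stopifnot(nrow(d) >= 3L)
  -unname(stats::coef(stats::lm(log(response) ~ time_s, data = d))[2L])
}

#' Affinity fold change between a mutant and the wild type
#'
#' @param mutant_kd,wildtype_kd Dissociation constants (same units).
#' @return `mutant_kd / wildtype_kd` (> 1 means weaker binding).
#' @export
affinity_fold <- function(mutant_kd, wildtype_kd) {
  if (wildtype_kd <= 0) stop("wild-type Kd must be positive")
  mutant_kd / wildtype_kd
}
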