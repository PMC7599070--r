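# Single-timepoint phosphatase kinetics: dilution design, standard-curve
# conversion, Michaelis-Menten fitting with a reliability flag for K_M,
# enzyme-unit calibration and pNPP normalisation.
#
# The assay model is P = t * E * (kcat/KM) * C / (C/KM + 1): product released
# after a fixed incubation, with C the initial substrate concentration held
# constant over the window (no depletion correction; the short 15-min format
# keeps conversion low at the concentrations that inform the fit).

#' Construct a serial-dilution series
#'
#' @param top_concentration Stock concentration in uM (default 1000, i.e.
#'   1 mM).
#' @param fold Dilution factor per step (default 1.5).
#' @param n_steps Number of wells.
#' @param mix_factor In-well dilution when enzyme is added (default 40/50 for
#'   40 ul substrate + 10 ul enzyme).
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(top_concentration = 1000, fold = 1.5,
                            n_steps = 16L, mix_factor = 40 / 50) {
  stopifnot(fold > 1, mix_factor > 0, mix_factor <= 1, n_steps >= 1L)
  structure(list(top_concentration = top_concentration, fold = fold,
                 n_steps = as.integer(n_steps), mix_factor = mix_factor),
            class = "dilution_series")
}

#' Final in-well substrate concentrations of a dilution series
#'
#' @param series A [dilution_series()].
#' @return Numeric vector: `top * mix_factor / fold^i` for `i = 0 ..
#'   n_steps - 1`, in uM.
#' @export
final_concentrations <- function(series) {
  series$top_concentration * series$mix_factor /
    series$fold^(seq_len(series$n_steps) - 1L)
}

#' Construct a phosphate standard curve
#'
#' @param slope Absorbance (A620) per uM phosphate; must be positive.
#' @param intercept Background absorbance.
#' @return An object of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept = 0) {
  if (slope <= 0) stop("standard-curve slope must be positive")
  structure(list(slope = slope, intercept = intercept),
            class = "standard_curve")
}

#' Convert absorbance readings to phosphate concentrations
#'
#' Inverts the linear standard curve; values below the background are clamped
#' to 0 and counted in the `n_clamped` attribute.
#'
#' @param a620 Absorbance readings at 620 nm.
#' @param curve A [standard_curve()].
#' @return Phosphate concentrations in uM, with attribute `n_clamped`.
#' @export
absorbance_to_phosphate <- function(a620, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  p <- (a620 - curve$intercept) / curve$slope
  n_clamped <- sum(p < 0)
  if (n_clamped > 0L) {
    warning(n_clamped, " reading(s) below background clamped to 0")
  }
  p <- pmax(p, 0)
  attr(p, "n_clamped") <- n_clamped
  p
}

# Given KM, the model P = eff * [t*E*C/(C/KM + 1)] is linear in eff, so the
# conditional least-squares efficiency and SSE have closed forms. The full
# fit therefore reduces to a 1-D search over log10(KM).
mm_profile <- function(log10_km, conc, product, t, enzyme) {
  km <- 10^log10_km
  g <- t * enzyme * conc / (conc / km + 1)
  eff <- sum(product * g) / sum(g * g)
  eff <- max(eff, 0)
  list(eff = eff, sse = sum((product - eff * g)^2))
}

#' Fit the single-timepoint Michaelis-Menten model
#'
#' Least-squares fit of `P = t * E * (kcat/KM) * C / (C/KM + 1)` to product
#' concentrations measured at one timepoint over a substrate dilution series.
#' The fit is performed as a profiled 1-D optimisation over log10(K_M) (the
#' efficiency is conditionally linear), which is deterministic and covers
#' K_M from `min(conc)/1000` to `10^4 * max(conc)`.
#'
#' `km_reliable` is set `FALSE` when the fitted K_M exceeds the largest assay
#' concentration or when its 95% profile-likelihood interval spans more than
#' one decade: in the linear regime only the ratio kcat/K_M is identified.
#'
#' @param conc Substrate concentrations (uM), at least 4 distinct values.
#' @param product Measured product concentrations (uM), same length.
#' @param t Incubation time in minutes (default 15).
#' @param enzyme Enzyme amount in units U (default 1).
#' @return List of class `kinetic_fit`: `kcat_over_km` (product uM per min
#'   per U per uM substrate at the linear limit; numerically equal to the
#'   conventionally printed uM min^-1 U^-1 value), `km` (uM), `kcat`
#'   (`kcat_over_km * km`), `km_reliable`, `km_ci` (95% profile interval),
#'   `residual_sse`, `n`.
#' @export
fit_single_timepoint_mm <- function(conc, product, t = 15, enzyme = 1) {
  stopifnot(length(conc) == length(product), t > 0, enzyme > 0)
  keep <- is.finite(conc) & is.finite(product)
  conc <- conc[keep]; product <- product[keep]
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct substrate concentrations")
  }
  if (all(product == 0)) stop("all product readings are zero")
  lo <- log10(min(conc)) - 3
  hi <- log10(max(conc)) + 4
  sse_of <- function(x) mm_profile(x, conc, product, t, enzyme)$sse
  # coarse grid then local golden-section refinement: deterministic and
  # immune to shoulders in the profiled SSE
  grid <- seq(lo, hi, length.out = 400L)
  sse_grid <- vapply(grid, sse_of, numeric(1))
  i0 <- which.min(sse_grid)
  step <- grid[2L] - grid[1L]
  opt <- stats::optimize(sse_of, lower = max(lo, grid[i0] - 2 * step),
                         upper = min(hi, grid[i0] + 2 * step), tol = 1e-12)
  best_log_km <- opt$minimum
  at <- mm_profile(best_log_km, conc, product, t, enzyme)
  km <- 10^best_log_km
  n <- length(conc)
  # 95% profile-likelihood interval for KM: SSE threshold from the F(1, n-2)
  # quantile applied to the profiled sum of squares
  sse_min <- at$sse
  thresh <- if (n > 2L && sse_min > 0) {
    sse_min * (1 + stats::qf(0.95, 1, n - 2) / (n - 2))
  } else {
    sse_min + 1e-12
  }
  inside <- grid[sse_grid <= thresh]
  km_ci <- if (length(inside) > 0L) 10^range(inside) else c(km, km)
  ci_decades <- log10(km_ci[2L]) - log10(km_ci[1L])
  at_upper_bound <- best_log_km >= hi - 0.05
  km_reliable <- km <= max(conc) && ci_decades <= 1 && !at_upper_bound
  structure(list(kcat_over_km = at$eff, km = km, kcat = at$eff * km,
                 km_reliable = km_reliable, km_ci = km_ci,
                 residual_sse = sse_min, n = n),
            class = "kinetic_fit")
}

#' Predicted product for a single-timepoint MM assay
#'
#' @param conc Substrate concentrations (uM).
#' @param kcat_over_km Catalytic efficiency (per min per U per uM at the
#'   linear limit).
#' @param km Michaelis constant (uM).
#' @param t Time (min).
#' @param enzyme Enzyme amount in units U.
#' @return Product concentrations (uM).
#' @export
predict_mm_product <- function(conc, kcat_over_km, km, t = 15, enzyme = 1) {
  t * enzyme * kcat_over_km * conc / (conc / km + 1)
}

#' Calibrate phosphatase activity in units
#'
#' One unit is the amount of enzyme that releases 15 uM phosphate in 15 min
#' from 125 uM standard substrate peptide, so activity is `p15 / 15` and is
#' linear in enzyme amount within the linear response regime.
#'
#' @param p15 Phosphate released (uM) after 15 min under standard conditions.
#' @return Activity in U.
#' @export
calibrate_activity <- function(p15) {
  if (any(p15 < 0)) stop("phosphate concentration cannot be negative")
  p15 / 15
}

#' Fit a hyperbolic pNPP response for cross-enzyme normalisation
#'
#' Different phosphatase preparations are put on a common activity scale with
#' a para-nitrophenylphosphate assay; the A405 signal is fit to
#' `A = Vmax * C / (C + KM)`. Duplicate concentrations are averaged before
#' fitting.
#'
#' @param conc pNPP concentrations (mM), at least 4 distinct.
#' @param a405 Product absorbance readings, same length.
#' @return List with `vmax`, `km` (mM), `residual_sse`, `n`.
#' @export
fit_pnpp <- function(conc, a405) {
  stopifnot(length(conc) == length(a405))
  agg <- vapply(split(a405, conc), mean, numeric(1))
  c_u <- as.numeric(names(agg))
  if (length(c_u) < 4L) stop("need at least 4 distinct pNPP concentrations")
  if (all(agg == 0)) stop("all readings are zero")
  # A = Vmax*C/(C+KM) equals the assay model with t*E = 1, eff = Vmax/KM
  fit <- fit_single_timepoint_mm(c_u, agg, t = 1, enzyme = 1)
  list(vmax = fit$kcat, km = fit$km, km_reliable = fit$km_reliable,
       residual_sse = fit$residual_sse, n = fit$n)
}

#' Catalytic-efficiency fold between two kinetic fits
#'
#' @param fit_a,fit_b `kinetic_fit` objects; the fold is
#'   `fit_a$kcat_over_km / fit_b$kcat_over_km`.
#' @return Fold enhancement of a over b.
#' @export
efficiency_fold <- function(fit_a, fit_b) {
  if (fit_b$kcat_over_km <= 0) stop("reference efficiency must be positive")
  fit_a$kcat_over_km / fit_b$kcat_over_km
}

#' Read a kinetics plate CSV
#'
#' Columns: `well`, `substrate_conc_uM` (or `dilution_step`), `a620`.
#'
#' @param path CSV path.
#' @param series Optional [dilution_series()] used to resolve
#'   `dilution_step` into concentrations.
#' @return `data.frame` with at least `substrate_conc_uM` and `a620`.
#' @export
read_plate_csv <- function(path, series = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"substrate_conc_uM" %in% names(tab)) {
    if (!"dilution_step" %in% names(tab) || is.null(series)) {
      stop("plate CSV needs substrate_conc_uM, or dilution_step plus a series")
    }
    concs <- final_concentrations(series)
    tab$substrate_conc_uM <- concs[tab$dilution_step]
  }
  stopifnot("a620" %in% names(tab))
  tab
}
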