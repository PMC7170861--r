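# Lipid-binding and kinase assay analytics: SPR steady-state isotherms,
# sedimentation fraction bound, and kinase fold activity.

#' Construct an equilibrium binding isotherm
#'
#' Concentration-response pairs from a steady-state surface plasmon
#' resonance experiment: equilibrium response (RU) versus analyte protein
#' concentration (uM).
#'
#' @param concentrations Analyte concentrations in uM, positive and
#'   distinct, length >= 3.
#' @param responses Equilibrium responses in RU, same length.
#' @param label Surface/lipid name.
#' @param background_corrected Has carrier-lipid background been
#'   subtracted? (informational flag).
#' @return A list of class `isotherm`.
#' @export
isotherm <- function(concentrations, responses, label = NA_character_,
                     background_corrected = FALSE) {
  concentrations <- as.numeric(concentrations)
  responses <- as.numeric(responses)
  if (length(concentrations) < 3L ||
      length(responses) != length(concentrations)) {
    stop_input("need >= 3 concentration-response pairs of equal length")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop_input("concentrations must be positive and finite")
  }
  if (anyDuplicated(concentrations)) {
    stop_input("concentrations must be distinct")
  }
  if (any(!is.finite(responses))) stop_input("responses must be finite")
  ord <- order(concentrations)
  structure(list(concentrations = concentrations[ord],
                 responses = responses[ord], label = as.character(label),
                 background_corrected = isTRUE(background_corrected)),
            class = "isotherm")
}

#' Parameters for the synthetic isotherm generator
#'
#' @param kd Equilibrium dissociation constant, uM (> 0).
#' @param rmax Saturating response, RU (> 0).
#' @param concentrations Strictly increasing positive concentrations, uM.
#' @param noise_sd Gaussian response noise s.d., RU (0 = exact model).
#' @param seed Integer seed.
#' @return A list of class `isotherm_sim_params`.
#' @export
isotherm_sim_params <- function(kd, rmax,
                                concentrations = exp(seq(log(0.25), log(64),
                                                         length.out = 8)),
                                noise_sd = 0, seed = 1L) {
  assert_scalar_number(kd, "kd", min = 0, strict_min = TRUE)
  assert_scalar_number(rmax, "rmax", min = 0, strict_min = TRUE)
  concentrations <- as.numeric(concentrations)
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop_input("concentrations must be positive and strictly increasing")
  }
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  structure(list(kd = kd, rmax = rmax, concentrations = concentrations,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "isotherm_sim_params")
}

# Langmuir 1:1 steady-state model.
req_model <- function(conc, kd, rmax) rmax / (1 + kd / conc)

#' Simulate a steady-state binding isotherm
#'
#' `response_i = rmax / (1 + kd / C_i) + N(0, noise_sd)`; `noise_sd = 0`
#' reproduces the closed form exactly.
#'
#' @param params An [isotherm_sim_params()] object.
#' @return An [isotherm()].
#' @export
simulate_isotherm <- function(params) {
  if (!inherits(params, "isotherm_sim_params")) {
    stop_input("`params` must come from isotherm_sim_params()")
  }
  p <- params
  resp <- req_model(p$concentrations, p$kd, p$rmax)
  if (p$noise_sd > 0) {
    resp <- withr::with_seed(p$seed, {
      resp + stats::rnorm(length(resp), 0, p$noise_sd)
    })
  }
  isotherm(p$concentrations, resp, label = "synthetic",
           background_corrected = TRUE)
}

#' Subtract carrier-lipid background responses
#'
#' Element-wise subtraction of the responses measured on a carrier-only
#' (e.g. plain phosphatidylcholine) surface.
#'
#' @param responses,background_responses Equal-length RU vectors.
#' @return Corrected responses.
#' @export
background_correct <- function(responses, background_responses) {
  if (!is.numeric(responses) || !is.numeric(background_responses) ||
      length(responses) != length(background_responses)) {
    stop_input("response vectors must be numeric and of equal length")
  }
  responses - background_responses
}

#' Fit a steady-state affinity isotherm
#'
#' Nonlinear least squares for `Req = Rmax / (1 + KD / C)`: minimizes the
#' residual sum of squares over `(KD, Rmax)`, parameterized on the log
#' scale so positivity is structural. Default initialization is
#' `KD = median(concentrations)`, `Rmax = max(responses)`; iteration stops
#' at relative parameter change below 1e-10 or 500 iterations. Optional
#' per-point weights multiply the squared residuals.
#'
#' @param iso An [isotherm()].
#' @param init Optional `c(kd, rmax)` starting values.
#' @param weights Optional non-negative weights, one per point.
#' @return A list of class `isotherm_fit`: `kd` (uM), `rmax` (RU), `rss`,
#'   `converged`, `n_iter`, `fitted`, plus the input isotherm.
#' @examples
#' iso <- simulate_isotherm(isotherm_sim_params(kd = 3.16, rmax = 100))
#' fit_isotherm(iso)$kd
#' @export
fit_isotherm <- function(iso, init = NULL, weights = NULL) {
  if (!inherits(iso, "isotherm")) stop_input("`iso` must be an isotherm()")
  conc <- iso$concentrations
  resp <- iso$responses
  if (length(unique(resp)) == 1L) {
    stop_compute("responses are flat: KD is not identifiable")
  }
  if (is.null(weights)) weights <- rep(1, length(conc))
  if (length(weights) != length(conc) || any(weights < 0)) {
    stop_input("`weights` must be non-negative, one per point")
  }
  if (is.null(init)) {
    init <- c(stats::median(conc), max(resp))
  }
  if (length(init) != 2L || any(init <= 0)) {
    stop_input("`init` must be positive c(kd, rmax)")
  }
  rss_fn <- function(lp) {
    sum(weights * (resp - req_model(conc, exp(lp[1]), exp(lp[2])))^2)
  }
  opt <- stats::nlminb(log(init), rss_fn,
                       control = list(x.tol = 1e-10, rel.tol = 1e-14,
                                      iter.max = 500, eval.max = 2000))
  kd <- exp(opt$par[1]); rmax <- exp(opt$par[2])
  structure(
    list(kd = kd, rmax = rmax, rss = opt$objective,
         converged = opt$convergence == 0, n_iter = opt$iterations,
         fitted = req_model(conc, kd, rmax), isotherm = iso),
    class = "isotherm_fit"
  )
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit> KD = %.4g uM, Rmax = %.4g RU, RSS = %.3g (%s, %d iter)\n",
              x$kd, x$rmax, x$rss,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Percent of maximal binding
#'
#' Equilibrium response divided by the response measured (or fitted) at
#' saturation, times 100.
#'
#' @param req Equilibrium response(s), RU (vectorized).
#' @param r_saturation Saturating response, RU (> 0); pass the fitted
#'   `rmax` when no observed plateau is available.
#' @return Percentages.
#' @export
percent_max_binding <- function(req, r_saturation) {
  if (!is.numeric(req)) stop_input("`req` must be numeric")
  assert_scalar_number(r_saturation, "r_saturation", min = 0,
                       strict_min = TRUE)
  100 * req / r_saturation
}

#' Fraction of protein bound to vesicles (sedimentation assay)
#'
#' From supernatant and pellet band intensities after
#' ultracentrifugation: `pellet / (pellet + supernatant)`.
#'
#' @param supernatant,pellet Non-negative band intensities (vectorized);
#'   a pair that is both zero is an error.
#' @return Fraction bound in \[0, 1\].
#' @export
fraction_bound <- function(supernatant, pellet) {
  if (!is.numeric(supernatant) || !is.numeric(pellet) ||
      length(supernatant) != length(pellet) ||
      any(supernatant < 0) || any(pellet < 0)) {
    stop_input("band intensities must be non-negative, equal length")
  }
  tot <- supernatant + pellet
  if (any(tot == 0)) stop_input("supernatant and pellet are both zero")
  pellet / tot
}

#' Kinase activity as fold over the zero-protein baseline
#'
#' Normalizes a dose-response table of kinase activity so the value in
#' the absence of the titrated protein is 1.
#'
#' @param table data.frame with columns `conc_uM` (>= 0, exactly one row
#'   at 0) and `activity` (luminescence units).
#' @return The input with an added `fold` column.
#' @export
kinase_fold <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("conc_uM", "activity") %in% names(table))) {
    stop_input("`table` must have columns conc_uM, activity")
  }
  if (any(table$conc_uM < 0)) stop_input("concentrations must be >= 0")
  zero <- which(table$conc_uM == 0)
  if (length(zero) != 1L) {
    stop_input("exactly one zero-protein row is required (found %d)",
               length(zero))
  }
  baseline <- table$activity[zero]
  if (!is.finite(baseline) || baseline <= 0) {
    stop_compute("zero-protein activity must be > 0")
  }
  table$fold <- table$activity / baseline
  table
}
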