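#' Model parameters for the tumor-immune Y90/ICI system
#'
#' Builds the full parameter set of the four-compartment model with defaults
#' taken from the published calibration for hepatocellular carcinoma. All
#' rates are per day, doses in Gy, cell quantities in absolute counts.
#'
#' @param a Tumor growth rate (d^-1).
#' @param f Circulating-lymphocyte decay rate (d^-1).
#' @param r Inactivated-tumor-cell decay rate (d^-1).
#' @param omega1 Baseline efficiency of immune-mediated tumor kill (d^-1).
#' @param omega2 Tumor-to-lymphocyte recruitment constant (d^-1).
#' @param omega3 Inactivated-tumor-to-lymphocyte recruitment constant (d^-1).
#' @param g Geometric saturation constant (cells).
#' @param s Lymphocyte supply rate (cells d^-1).
#' @param ab_ratio Tumor alpha/beta ratio of the linear-quadratic model (Gy).
#' @param alphaT Tumor LQ alpha (Gy^-1); cohort-level draws override this.
#' @param alphaL Lymphocyte LQ alpha (Gy^-1), linear survival model.
#' @param Cmax Checkpoint-inhibitor maximum concentration scale (mg/kg).
#' @param t_half_ici Checkpoint-inhibitor (durvalumab) half-life (d).
#' @param delta_durva Checkpoint-inhibitor effectiveness (dimensionless,
#'   in \[0, 1\]).
#' @param t_half_y90 Physical (= effective) half-life of yttrium-90 (d).
#' @param q Y90 effectiveness scaling physical to effective dose
#'   (dimensionless, in \[0, 1\]); cohort-level draws override this.
#' @param k Unit-conversion constant, J/MeV (used with GBq and day factors in
#'   [dose_from_activity()]).
#' @param E_mean Mean energy emitted per nuclear transition of Y90 (MeV).
#' @param tumor_density Tumor cell density (cells per cc).
#'
#' @return An object of class `y90_params` (a validated named list).
#' @examples
#' p <- model_parameters()
#' p$s / p$f # tumor-free lymphocyte steady state
#' @export
model_parameters <- function(a = 0.01, f = 0.033, r = 0.14,
                             omega1 = 0.119, omega2 = 0.003, omega3 = 0.009,
                             g = 7.33e10, s = 1.47e8,
                             ab_ratio = 10, alphaT = 0.148, alphaL = 0.737,
                             Cmax = 10, t_half_ici = 21, delta_durva = 0.12,
                             t_half_y90 = 2.6, q = 0.12,
                             k = 1.6022e-13, E_mean = 0.9267,
                             tumor_density = 1e9) {
  p <- list(a = a, f = f, r = r, omega1 = omega1, omega2 = omega2,
            omega3 = omega3, g = g, s = s, ab_ratio = ab_ratio,
            alphaT = alphaT, alphaL = alphaL, Cmax = Cmax,
            t_half_ici = t_half_ici, delta_durva = delta_durva,
            t_half_y90 = t_half_y90, q = q, k = k, E_mean = E_mean,
            tumor_density = tumor_density)
  validate_params(p)
  structure(p, class = "y90_params")
}

validate_params <- function(p) {
  pos <- c("a", "f", "r", "omega1", "g", "s", "ab_ratio", "alphaT", "alphaL",
           "Cmax", "t_half_ici", "t_half_y90", "k", "E_mean", "tumor_density")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  for (nm in c("omega2", "omega3")) {
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  }
  for (nm in c("delta_durva", "q")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.y90_params <- function(x, ...) {
  cat("Tumor-immune Y90/ICI model parameters\n")
  df <- data.frame(value = unlist(x))
  print(df, ...)
  cat("derived: betaT = alphaT/ab_ratio =", x$alphaT / x$ab_ratio, "Gy^-2\n")
  invisible(x)
}

# average calendar month used to report event times in months
DAYS_PER_MONTH <- 30.4375
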