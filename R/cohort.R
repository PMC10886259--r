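# Truncated-normal sampling via quantile mapping (equivalent in distribution
# to resample-on-reject, but deterministic given the uniform draws, which the
# calibration search exploits as common random numbers).
qtnorm <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, length(u)), lower), upper))
  a <- stats::pnorm(lower, mean, sd)
  b <- stats::pnorm(upper, mean, sd)
  stats::qnorm(a + u * (b - a), mean, sd)
}

rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  qtnorm(stats::runif(n), mean, sd, lower, upper)
}

#' Lymphocyte baseline from a blood count
#'
#' Converts a lymphocyte count per cubic millimetre and a blood volume in
#' litres to an absolute cell number (1 L = 1e6 mm^3).
#'
#' @param count_per_mm3 Lymphocyte count (cells/mm^3).
#' @param blood_volume_L Total blood volume (litres), default 5.
#' @return Cells.
#' @examples
#' baseline_from_counts(1122, 5) # 5.61e9
#' @export
baseline_from_counts <- function(count_per_mm3, blood_volume_L = 5) {
  if (any(count_per_mm3 < 0) || any(blood_volume_L < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  count_per_mm3 * blood_volume_L * 1e6
}

#' Tumor volume to cell number
#'
#' @param volume_cc Volume (cc).
#' @param density Cells per cc (default 1e9).
#' @return Cells.
#' @examples
#' volume_cells(107) # 1.07e11, the mean targeted baseline
#' volume_cells(0.1) # 1e8, the distant-metastasis detection threshold
#' @export
volume_cells <- function(volume_cc, density = 1e9) {
  if (any(volume_cc < 0) || any(density < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  volume_cc * density
}

#' Virtual cohort specification
#'
#' Distributions of the patient-level quantities: targeted tumor baseline
#' `T0` (normal, mean 1.07e11 cells = 107 cc at 1e9 cells/cc, spread given as
#' a coefficient of variation), circulating lymphocytes `L0` (normal, mean
#' 1122/mm^3 x 5 L = 5.61e9, sd 469/mm^3 x 5 L = 2.345e9), tumor
#' radiosensitivity `alphaT` (normal 0.148 +/- 0.024 Gy^-1), Y90
#' effectiveness `q` and ICI effectiveness `delta_durva` (both normal
#' 0.12 +/- 0.04, truncated to \[0, 1\]). The non-targeted baseline is always
#' 0.1% of `T0`. All normals are truncated to their physical support
#' (positivity; `T0` additionally at +/- 3 sd and a 1e9-cell floor; `L0` at
#' a 1e8-cell floor).
#'
#' @param n Number of patients.
#' @param T0_mean,T0_cv Targeted-tumor baseline mean (cells) and coefficient
#'   of variation.
#' @param L0_mean,L0_sd Lymphocyte baseline mean and sd (cells).
#' @param alphaT_mean,alphaT_sd Tumor LQ alpha distribution (Gy^-1).
#' @param q_mean,q_sd Y90 effectiveness distribution.
#' @param delta_mean,delta_sd ICI effectiveness distribution.
#' @param seed Integer seed making the cohort reproducible.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n = 10000,
                        T0_mean = 1.07e11, T0_cv = 0.30,
                        L0_mean = baseline_from_counts(1122),
                        L0_sd = baseline_from_counts(469),
                        alphaT_mean = 0.148, alphaT_sd = 0.024,
                        q_mean = 0.12, q_sd = 0.04,
                        delta_mean = 0.12, delta_sd = 0.04,
                        seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  sds <- c(T0_cv = T0_cv, L0_sd = L0_sd, alphaT_sd = alphaT_sd,
           q_sd = q_sd, delta_sd = delta_sd)
  if (any(sds < 0)) stop("spreads must be >= 0", call. = FALSE)
  structure(list(n = as.integer(n), T0_mean = T0_mean, T0_cv = T0_cv,
                 L0_mean = L0_mean, L0_sd = L0_sd,
                 alphaT_mean = alphaT_mean, alphaT_sd = alphaT_sd,
                 q_mean = q_mean, q_sd = q_sd,
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a virtual patient cohort
#'
#' Draws `spec$n` patients from the truncated normal distributions of the
#' specification, reproducibly for a fixed seed. The same cohort is reused
#' across all treatment arms (common random numbers), so arm contrasts are
#' within-patient.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `id`, `T0`, `TNI0`, `L0`, `alphaT`, `q`,
#'   `delta_durva`.
#' @examples
#' coh <- sample_cohort(cohort_spec(n = 100, seed = 7))
#' stopifnot(all(coh$TNI0 == 0.001 * coh$T0))
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  T0_sd <- spec$T0_cv * spec$T0_mean
  T0 <- rtnorm(n, spec$T0_mean, T0_sd,
               lower = max(1e9, spec$T0_mean - 3 * T0_sd),
               upper = spec$T0_mean + 3 * T0_sd)
  L0 <- rtnorm(n, spec$L0_mean, spec$L0_sd, lower = 1e8)
  alphaT <- rtnorm(n, spec$alphaT_mean, spec$alphaT_sd, lower = 1e-6)
  q <- rtnorm(n, spec$q_mean, spec$q_sd, lower = 0, upper = 1)
  delta <- rtnorm(n, spec$delta_mean, spec$delta_sd, lower = 0, upper = 1)
  out <- data.frame(id = seq_len(n), T0 = T0, TNI0 = 0.001 * T0, L0 = L0,
                    alphaT = alphaT, q = q, delta_durva = delta)
  attr(out, "seed") <- spec$seed
  out
}

# save/restore the global RNG state so sampling does not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Write / read a cohort as CSV
#'
#' One row per patient; the seed provenance is kept in a `#` header comment.
#'
#' @param cohort Data frame from [sample_cohort()].
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @return `path` (writer) or the cohort data frame (reader).
#' @export
write_cohort_csv <- function(cohort, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# y90ici cohort; n=", nrow(cohort), "; seed=", seed),
             con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
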