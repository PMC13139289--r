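#' Descriptive summary: median, IQR, minimum
#'
#' The summary used for reporting calcification surface area and
#' thickness by age group.  Quartiles use the linear-interpolation
#' quantile dialect (`type = 7`), the same dialect the weighted
#' representative-thickness quantile reduces to under uniform weights.
#'
#' @param x numeric vector (at least one value; NAs dropped).
#' @return one-row tibble: `n`, `median`, `iqr`, `minimum`.
#' @examples
#' describe_values(c(1, 2, 3, 4, 5))
#' @export
describe_values <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values to describe", call. = FALSE)
  tibble::tibble(
    n = length(x),
    median = stats::median(x),
    iqr = stats::IQR(x, type = 7),
    minimum = min(x)
  )
}

#' Spearman rank correlation
#'
#' The Pearson correlation of mid-ranks (ties averaged); used for the
#' age associations of S and T and for their mutual correlation.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Z-score a numeric column
#'
#' Centres to mean 0 and scales to unit standard deviation using the
#' sample (n - 1) convention.  Idempotent, and invariant to affine
#' rescaling of the input.
#'
#' @param x numeric vector with positive standard deviation.
#' @return standardized vector.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a zero-variance column", call. = FALSE)
  (x - mean(x)) / s
}

#' Synthetic cohort specification
#'
#' Parameters for [synthesize_cohort()].  Defaults emulate the published
#' cohort scale: n = 1232 participants from two populations, ages 40-92,
#' right-skewed log-normal S (median 62.75 mm^2, IQR 193.35 mm^2) and T
#' (median 1.07 mm, IQR 0.60 mm) linked to age and to each other through
#' a Gaussian copula (Spearman targets 0.64, 0.55, and 0.862), and a
#' 35/1232 no-calcification fraction.
#'
#' @param n cohort size (>= 10).
#' @param regions tibble with columns `region`, `beta_S`, `beta_T`: true
#'   standardized effects of S and T on each regional brain volume.
#' @param beta_age,beta_sex,beta_pop,beta_ticv true standardized covariate
#'   effects shared across regions (sex and population act through their
#'   0/1 indicators).
#' @param noise_sd residual SD of the standardized regional volume; `NULL`
#'   (default) chooses it so the outcome has approximately unit variance.
#' @param s_median,s_iqr,t_median,t_iqr marginal targets for S (mm^2) and
#'   T (mm).
#' @param rho_age_s,rho_age_t,rho_s_t Spearman correlation targets.
#' @param zero_fraction fraction of participants with no calcification
#'   (S = T = 0).
#' @param female_fraction,tsimane_fraction demographic mix.
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(n = 1232,
                                  regions = tibble::tibble(
                                    region = c("subcortical", "frontal", "occipital"),
                                    beta_S = c(-0.14, -0.08, 0),
                                    beta_T = c(0, 0, 0)),
                                  beta_age = -0.30, beta_sex = -0.05,
                                  beta_pop = 0.03, beta_ticv = 0.55,
                                  noise_sd = NULL,
                                  s_median = 62.75, s_iqr = 193.35,
                                  t_median = 1.07, t_iqr = 0.60,
                                  rho_age_s = 0.64, rho_age_t = 0.55,
                                  rho_s_t = 0.862,
                                  zero_fraction = 35 / 1232,
                                  female_fraction = 0.481,
                                  tsimane_fraction = 794 / 1232,
                                  seed = 1L) {
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  if (any(abs(c(rho_age_s, rho_age_t, rho_s_t)) >= 1))
    stop("Spearman targets must lie strictly inside (-1, 1)", call. = FALSE)
  if (!is.null(noise_sd) && noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

# log-normal sigma matching a median/IQR pair:
# IQR = 2 * median * sinh(z75 * sigma)  with z75 = qnorm(0.75)
lnorm_sigma <- function(median, iqr) asinh(iqr / (2 * median)) / stats::qnorm(0.75)

#' Generate a synthetic cohort table
#'
#' Draws a deterministic cohort from a [synthetic_cohort_spec()]: ages
#' from a shifted gamma on 40-92 years, S and T from log-normal marginals
#' coupled to age through a Gaussian copula (latent correlations set by
#' the inverse of the Gaussian-copula Spearman map, r = 2 sin(pi rho / 6)),
#' a no-calcification subset (lowest latent S), TICV larger in males, and
#' regional brain volumes built as the specified linear combination of
#' z-scored predictors plus Gaussian noise.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return tibble with columns `id`, `age`, `sex` (1 = female),
#'   `population` (1 = Tsimane), `ticv_mm3`, `S_mm2`, `T_mm`,
#'   `no_calcification`, and one `bv_<region>` column per region.
#' @export
synthesize_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  set.seed(spec$seed)
  # latent Gaussian copula over (age, S, T)
  r <- function(rho) 2 * sin(pi * rho / 6)
  Sig <- rbind(c(1, r(spec$rho_age_s), r(spec$rho_age_t)),
               c(r(spec$rho_age_s), 1, r(spec$rho_s_t)),
               c(r(spec$rho_age_t), r(spec$rho_s_t), 1))
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("correlation targets give a non-positive-definite copula", call. = FALSE)
  Z <- matrix(rnorm(3 * n), n, 3) %*% chol(Sig)
  U <- pnorm(Z)
  age <- pmin(92, 40 + qgamma(U[, 1], shape = 3, scale = 6.2))
  S <- stats::qlnorm(U[, 2], log(spec$s_median), lnorm_sigma(spec$s_median, spec$s_iqr))
  Tt <- stats::qlnorm(U[, 3], log(spec$t_median), lnorm_sigma(spec$t_median, spec$t_iqr))
  nz <- round(spec$zero_fraction * n)
  no_calc <- rank(S, ties.method = "first") <= nz
  S[no_calc] <- 0
  Tt[no_calc] <- 0
  sex <- rbinom(n, 1, spec$female_fraction)           # 1 = female
  population <- rbinom(n, 1, spec$tsimane_fraction)   # 1 = Tsimane
  ticv <- 1.25e6 + 1.2e5 * (1 - sex) + rnorm(n, 0, 1.1e5)

  out <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    age = age, sex = sex, population = population,
    ticv_mm3 = ticv, S_mm2 = S, T_mm = Tt,
    no_calcification = no_calc
  )
  zs <- zscore(S); zt <- zscore(Tt); za <- zscore(age); zv <- zscore(ticv)
  for (j in seq_len(nrow(spec$regions))) {
    bS <- spec$regions$beta_S[j]
    bT <- spec$regions$beta_T[j]
    lin <- bS * zs + bT * zt + spec$beta_age * za +
      spec$beta_sex * sex + spec$beta_pop * population + spec$beta_ticv * zv
    ns <- spec$noise_sd
    if (is.null(ns)) ns <- sqrt(max(0.05, 1 - stats::var(lin)))
    out[[paste0("bv_", spec$regions$region[j])]] <- lin + rnorm(n, 0, ns)
  }
  out
}
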