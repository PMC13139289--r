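#' Standardised regression of a regional brain volume on S and/or T
#'
#' Fits the three model forms used to relate calcification morphometry
#' to regional brain volume (BV), in Wilkinson notation:
#' \itemize{
#'   \item Model 1: `BV ~ S + age + sex + population + TICV`
#'   \item Model 2: `BV ~ T + age + sex + population + TICV`
#'   \item Model 3: `BV ~ S + T + age + sex + population + TICV`
#' }
#' All continuous variables (BV, S, T, age, TICV) are z-scored before
#' fitting (n - 1 convention); the categorical covariates sex and
#' population enter as unstandardised 0/1 indicators.  The coefficient
#' on this scale is the standardized estimate beta*: the mean difference
#' in BV standard deviations per standard-deviation difference in the
#' predictor.  Coefficients are also reported back on the raw scale
#' (`beta = beta* * sd(BV) / sd(X)` for continuous predictors,
#' `beta* * sd(BV)` for indicators).  Two-sided p-values come from the t
#' distribution with the residual degrees of freedom, and each
#' predictor's variance inflation factor is attached.
#'
#' @param cohort a cohort tibble such as from [synthesize_cohort()] or
#'   read from CSV; must contain `age`, `sex`, `population`, `ticv_mm3`,
#'   `S_mm2`, `T_mm`, and the regional volume column.
#' @param region name of the region; the outcome column is
#'   `paste0("bv_", region)` unless `outcome` is given.
#' @param model 1, 2, or 3.
#' @param outcome optional explicit outcome column name.
#' @return a `bv_model_fit`: list with `model`, `region`, `terms` (tibble:
#'   `term`, `beta`, `beta_std`, `se_std`, `se`, `statistic`, `p_value`,
#'   `vif`), `n`, `r_squared`, and the underlying `lm` fit.
#' @export
fit_bv_model <- function(cohort, region, model = 1, outcome = NULL) {
  stopifnot(model %in% 1:3)
  outcome <- outcome %||% paste0("bv_", region)
  for (col in c(outcome, "age", "sex", "population", "ticv_mm3", "S_mm2", "T_mm"))
    if (!col %in% names(cohort))
      stop("cohort table lacks column `", col, "`", call. = FALSE)
  exposures <- switch(model, `1` = "S_mm2", `2` = "T_mm",
                      `3` = c("S_mm2", "T_mm"))
  continuous <- c(outcome, exposures, "age", "ticv_mm3")
  d <- tibble::tibble(
    .bv = zscore(cohort[[outcome]]),
    sex = cohort$sex, population = cohort$population
  )
  sds <- c()
  for (col in c(exposures, "age", "ticv_mm3")) {
    d[[col]] <- zscore(cohort[[col]])
    sds[col] <- stats::sd(cohort[[col]])
  }
  k <- length(exposures) + 4L
  if (nrow(d) <= k + 1L)
    stop("too few rows for ", k, " predictors", call. = FALSE)
  form <- stats::as.formula(paste(
    ".bv ~", paste(c(exposures, "age", "sex", "population", "ticv_mm3"),
                   collapse = " + ")))
  fit <- stats::lm(form, data = d)
  if (fit$df.residual <= 0 || qr(fit)$rank < length(coef(fit)))
    stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  sd_bv <- stats::sd(cohort[[outcome]])
  sd_x <- vapply(terms, function(t) if (t %in% names(sds)) sds[[t]] else 1,
                 numeric(1))
  vifs <- vif(stats::model.matrix(fit)[, -1, drop = FALSE])
  res <- list(
    model = as.integer(model),
    region = region,
    terms = tibble::tibble(
      term = terms,
      beta = unname(sm[terms, "Estimate"] * sd_bv / sd_x),
      beta_std = unname(sm[terms, "Estimate"]),
      se_std = unname(sm[terms, "Std. Error"]),
      se = unname(sm[terms, "Std. Error"] * sd_bv / sd_x),
      statistic = unname(sm[terms, "t value"]),
      p_value = unname(sm[terms, "Pr(>|t|)"]),
      vif = unname(vifs[terms])
    ),
    n = nrow(d),
    r_squared = summary(fit)$r.squared,
    fit = fit
  )
  class(res) <- "bv_model_fit"
  res
}

#' @export
print.bv_model_fit <- function(x, ...) {
  cat(sprintf("<bv_model_fit> model %d, region %s (n = %d, R^2 = %.3f)\n",
              x$model, x$region, x$n, x$r_squared))
  print(x$terms)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing predictor j
#' on all other predictors (with intercept).  Values near 1 indicate no
#' collinearity; perfect collinearity is an error.
#'
#' @param x a numeric design matrix (columns are predictors, no
#'   intercept column) with at least two columns.
#' @return named numeric vector of VIFs.
#' @examples
#' vif(cbind(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 predictors", call. = FALSE)
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-12)
      stop("perfect collinearity: VIF is infinite for predictor ",
           colnames(x)[j] %||% j, call. = FALSE)
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (`min` over ranks `>= k` of `m p_(k) / k`,
#' capped at 1) with the rejection set at level `alpha`.
#'
#' @param p p-values in \[0, 1\].
#' @param alpha FDR level for the rejection set (default 0.05).
#' @return tibble with `p`, `p_adj`, `rejected`, in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = adj, rejected = adj <= alpha)
}

#' Fit all models across regions with FDR control
#'
#' Fits the requested model forms for every region and applies
#' Benjamini-Hochberg adjustment to the exposure (S, T) p-values.  The
#' default family is per model across regions (each model's exposure
#' tests across the analysed region set are one family); `family =
#' "pooled"` adjusts all exposure tests together.
#'
#' @inheritParams fit_bv_model
#' @param regions character vector of region names.
#' @param models subset of 1:3 (default all).
#' @param alpha FDR level.
#' @param family `"per_model"` (default) or `"pooled"`.
#' @return a `bv_model_fits` tibble: one row per model x region x term
#'   with the [fit_bv_model()] columns plus `p_adj` and `significant`
#'   for exposure terms.
#' @export
fit_bv_models <- function(cohort, regions, models = 1:3, alpha = 0.05,
                          family = c("per_model", "pooled")) {
  family <- match.arg(family)
  rows <- purrr::map_dfr(models, function(m) {
    purrr::map_dfr(regions, function(rg) {
      f <- fit_bv_model(cohort, rg, m)
      dplyr::mutate(f$terms, model = f$model, region = f$region,
                    n = f$n, .before = 1)
    })
  })
  rows$p_adj <- NA_real_
  expo <- rows$term %in% c("S_mm2", "T_mm")
  groups <- if (family == "per_model") rows$model[expo] else rep(1L, sum(expo))
  for (g in unique(groups)) {
    idx <- which(expo)[groups == g]
    rows$p_adj[idx] <- bh_adjust(rows$p_value[idx], alpha)$p_adj
  }
  rows$significant <- !is.na(rows$p_adj) & rows$p_adj <= alpha
  class(rows) <- c("bv_model_fits", class(rows))
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a
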