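#' Tidy a fitted brain-volume model
#'
#' @param x a `bv_model_fit` from [fit_bv_model()].
#' @param ... unused.
#' @return tibble with one row per term: `term`, `estimate` (standardized
#'   beta*), `std.error`, `statistic`, `p.value`, `vif`, plus the raw-scale
#'   `beta`.
#' @importFrom generics tidy
#' @export
#' @export tidy.bv_model_fit
tidy.bv_model_fit <- function(x, ...) {
  tibble::tibble(
    term = x$terms$term,
    estimate = x$terms$beta_std,
    std.error = x$terms$se_std,
    statistic = x$terms$statistic,
    p.value = x$terms$p_value,
    vif = x$terms$vif,
    beta = x$terms$beta
  )
}

#' Glance at a fitted brain-volume model
#'
#' @param x a `bv_model_fit`.
#' @param ... unused.
#' @return one-row tibble: `model`, `region`, `r.squared`, `nobs`,
#'   `max.vif`.
#' @importFrom generics glance
#' @export
#' @export glance.bv_model_fit
glance.bv_model_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    region = x$region,
    r.squared = x$r_squared,
    nobs = x$n,
    max.vif = max(x$terms$vif)
  )
}

#' @rdname tidy.bv_model_fit
#' @export
#' @export tidy.morphometry_result
tidy.morphometry_result <- function(x, ...) x$summary

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
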