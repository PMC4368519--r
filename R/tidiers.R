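#' Tidy a maximum-likelihood neutral fit
#'
#' @param x A `neutral_fit` from [fit_neutral()].
#' @param ... Unused.
#' @return A one-row tibble with `theta`, `m`, `logL`, `converged`,
#'   `boundary`, `n_starts`.
#' @export
tidy.neutral_fit <- function(x, ...) {
  tibble::tibble(theta = x$theta, m = x$m, logL = x$logL,
                 converged = x$converged, boundary = x$boundary,
                 n_starts = x$n_starts)
}

#' @rdname tidy.neutral_fit
#' @export
glance.neutral_fit <- function(x, ...) tidy.neutral_fit(x, ...)

#' Tidy a neutrality test result
#'
#' @param x A `neutrality_test` result.
#' @param ... Unused.
#' @return A one-row tibble with `p_value`, `rejected`, `alpha`, `u`,
#'   `theta`, `m`, `logL`, `n_failed`.
#' @export
tidy.neutrality_test <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, rejected = x$rejected, alpha = x$alpha,
                 u = x$u, theta = x$fit$theta, m = x$fit$m, logL = x$fit$logL,
                 n_failed = x$n_failed)
}

#' @rdname tidy.neutrality_test
#' @export
glance.neutrality_test <- function(x, ...) tidy.neutrality_test(x, ...)

#' Tidy a power estimate
#'
#' @param x A `power_estimate` from [estimate_power()].
#' @param ... Unused.
#' @return A one-row tibble with `n`, `x`, `power`, `ci_low`, `ci_high`,
#'   `level`, `alpha`, `u`, `n_failed`.
#' @export
tidy.power_estimate <- function(x, ...) {
  pe <- x  # the column literally named `x` would shadow the object below
  tibble::tibble(n = pe$n_datasets, x = pe$n_rejected, power = pe$power,
                 ci_low = pe$ci_low, ci_high = pe$ci_high, level = pe$level,
                 alpha = pe$alpha, u = pe$u, n_failed = pe$n_failed)
}

#' @rdname tidy.power_estimate
#' @export
glance.power_estimate <- function(x, ...) tidy.power_estimate(x, ...)
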