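#' Parametric-bootstrap test of the neutral null hypothesis
#'
#' Tests whether an abundance sample is statistically consistent with the
#' standard neutral model, using the maximized neutral likelihood as test
#' statistic:
#'
#' 1. fit \eqn{(\hat\theta, \hat m)} to the sample by [fit_neutral()];
#' 2. draw `u` null samples from the urn algorithm at the fitted parameters;
#' 3. fit each null sample by the identical procedure;
#' 4. the p-value is the fraction of null samples whose maximized
#'    log-likelihood is lower than the sample's (poorly fitting data have
#'    atypically low maximized likelihood, so small `p` is evidence against
#'    neutrality; exact ties, possible at tiny `J`, count one half);
#' 5. the null model is rejected when `p < alpha`.
#'
#' A null replicate whose fit errors is retried once and then dropped with a
#' warning (the count is recorded in the result).
#'
#' @param d An [abundance_sample()] (or counts vector / data frame).
#' @param u Number of bootstrap null samples (default 1000).
#' @param alpha Significance threshold (default 0.05).
#' @param fit_args List of extra arguments passed to [fit_neutral()] for
#'   both the observed and the null fits.
#' @return An object of class `neutrality_test`: list with `p_value`,
#'   `rejected`, `alpha`, `u`, `fit` (the observed [fit_neutral()] result),
#'   `null_logL` (vector of null maximized log-likelihoods) and
#'   `n_failed`. Use [tidy()] for a one-row tibble.
#' @examples
#' set.seed(1)
#' d <- urn_sample(theta = 20, m = 0.3, J = 100)
#' neutrality_test(d, u = 20)
#' @export
neutrality_test <- function(d, u = 1000, alpha = 0.05, fit_args = list()) {
  if (!is.numeric(u) || u < 1 || u != round(u)) abort("'u' must be a positive integer")
  fit <- do.call(fit_neutral, c(list(d), fit_args))
  J <- fit$J
  null_logL <- rep(NA_real_, u)
  n_failed <- 0L
  for (i in seq_len(u)) {
    for (attempt in 1:2) {
      res <- tryCatch({
        di <- urn_sample(fit$theta, fit$m, J)
        do.call(fit_neutral, c(list(di), fit_args))$logL
      }, error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) n_failed <- n_failed + 1L else null_logL[i] <- res
  }
  if (n_failed > 0) {
    warn(sprintf("%d of %d bootstrap replicates failed and were excluded",
                 n_failed, as.integer(u)))
  }
  ok <- null_logL[!is.na(null_logL)]
  p <- (sum(ok < fit$logL) + 0.5 * sum(ok == fit$logL)) / length(ok)
  structure(list(p_value = p, rejected = p < alpha, alpha = alpha,
                 u = as.integer(u), fit = fit, null_logL = ok,
                 n_failed = n_failed),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  cat(sprintf(paste0("<neutrality_test>  p = %.4g (%s at alpha = %g)\n",
                     "  fitted neutral parameters: theta = %.4g, m = %.4g, logL = %.4f\n",
                     "  bootstrap null samples: %d%s\n"),
              x$p_value, if (x$rejected) "neutrality REJECTED" else "not rejected",
              x$alpha, x$fit$theta, x$fit$m, x$fit$logL, length(x$null_logL),
              if (x$n_failed) sprintf(" (%d failed)", x$n_failed) else ""))
  invisible(x)
}
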