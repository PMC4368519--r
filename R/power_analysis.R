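#' Jeffreys binomial confidence interval
#'
#' Equal-tailed interval from the Beta(`x + 1/2`, `n - x + 1/2`) posterior
#' under the Jeffreys prior, the standard interval for a binomial proportion
#' such as an estimated rejection rate. By convention the lower endpoint is
#' 0 when `x = 0` and the upper endpoint is 1 when `x = n`.
#'
#' @param x Number of successes (vectorized).
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `x`, `n`, `estimate`, `low`, `high`,
#'   `level`.
#' @examples
#' jeffreys_interval(5, 100)
#' @export
jeffreys_interval <- function(x, n, level = 0.95) {
  if (any(x < 0) || any(x > n)) abort("'x' must lie in [0, n]")
  if (level <= 0 || level >= 1) abort("'level' must be in (0, 1)")
  k <- max(length(x), length(n))
  x <- rep_len(x, k); n <- rep_len(n, k)
  a <- (1 - level) / 2
  low <- ifelse(x == 0, 0, qbeta(a, x + 0.5, n - x + 0.5))
  high <- ifelse(x == n, 1, qbeta(1 - a, x + 0.5, n - x + 0.5))
  tibble::tibble(x = x, n = n, estimate = x / n, low = low, high = high,
                 level = level)
}

#' Estimate the power of the neutrality test for a generating model
#'
#' Simulates `n_datasets` equilibrium abundance samples from the generating
#' model, applies the parametric-bootstrap [neutrality_test()] to each, and
#' returns the rejection fraction with its Jeffreys confidence interval.
#' When the generating model is the standard neutral model itself the
#' rejection fraction estimates the type-I error rate and should match
#' `alpha`; for a non-neutral generating model it estimates the power
#' \eqn{1 - \beta}.
#'
#' Datasets whose simulation fails to equilibrate are dropped and counted in
#' the result (`n_failed`).
#'
#' @param spec A [community_model()] describing the generating model.
#' @param n_datasets Number of simulated datasets (the study default is 400;
#'   100 with `u = 200` is a useful desk-scale profile).
#' @param u Bootstrap null samples per test (study default 1000).
#' @param alpha Significance threshold.
#' @param level Confidence level of the Jeffreys interval.
#' @param sim_args,fit_args Extra arguments for [sim_community()] /
#'   [fit_neutral()].
#' @return An object of class `power_estimate`; [tidy()] gives a one-row
#'   tibble with `n`, `x`, `power`, `ci_low`, `ci_high`.
#' @examples
#' set.seed(1)
#' spec <- community_model("snm", J = 50, m = 0.3, theta = 10)
#' estimate_power(spec, n_datasets = 4, u = 20)
#' @export
estimate_power <- function(spec, n_datasets = 400, u = 1000, alpha = 0.05,
                           level = 0.95, sim_args = list(), fit_args = list()) {
  stopifnot(inherits(spec, "community_model"))
  if (n_datasets < 1) abort("'n_datasets' must be >= 1")
  x <- 0L; n_ok <- 0L; n_failed <- 0L
  p_values <- numeric(0)
  for (i in seq_len(n_datasets)) {
    d <- tryCatch(do.call(sim_community, c(list(spec), sim_args)),
                  sadpower_convergence_error = function(e) NULL)
    if (is.null(d)) { n_failed <- n_failed + 1L; next }
    tt <- neutrality_test(d, u = u, alpha = alpha, fit_args = fit_args)
    n_ok <- n_ok + 1L
    p_values <- c(p_values, tt$p_value)
    if (tt$rejected) x <- x + 1L
  }
  if (n_ok == 0) abort("no dataset could be simulated", class = "sadpower_convergence_error")
  ci <- jeffreys_interval(x, n_ok, level)
  structure(list(n_datasets = n_ok, n_rejected = x, power = x / n_ok,
                 ci_low = ci$low, ci_high = ci$high, level = level,
                 alpha = alpha, u = as.integer(u), p_values = p_values,
                 n_failed = n_failed, spec = spec),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate>  %d/%d rejected: power = %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$n_rejected, x$n_datasets, x$power, 100 * x$level,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Run a declarative grid of power calculations
#'
#' Takes a tibble with one row per experimental cell (columns are the
#' arguments of [community_model()]: `model`, `meta`, `J`, `m`, plus any of
#' `gamma`, `c`, `k`, `theta`, `S_T`) and estimates the power of the
#' neutrality test in each cell. Cells are validated up front, run
#' sequentially, and optionally checkpointed to a TSV so an interrupted
#' sweep resumes where it stopped.
#'
#' @param grid A data frame of cells (see above).
#' @param n_datasets,u,alpha Passed to [estimate_power()].
#' @param checkpoint Optional path to a TSV checkpoint file.
#' @param ... Further arguments for [estimate_power()].
#' @return A tibble with one row per cell: the cell parameters plus `n`,
#'   `x`, `power`, `ci_low`, `ci_high`, `u`, `alpha`.
#' @export
power_sweep <- function(grid, n_datasets = 400, u = 1000, alpha = 0.05,
                        checkpoint = NULL, ...) {
  grid <- tibble::as_tibble(grid)
  if (!all(c("model", "J", "m") %in% names(grid))) {
    abort("'grid' needs at least columns model, J, m")
  }
  specs <- purrr::pmap(grid, function(...) {
    args <- list(...)
    args <- args[!vapply(args, function(v) length(v) == 1 && is.na(v), logical(1))]
    do.call(community_model, args)
  })

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- tibble::as_tibble(utils::read.delim(checkpoint))
  }
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    if (!is.null(done) && i <= nrow(done)) { rows[[i]] <- done[i, ]; next }
    pe <- estimate_power(specs[[i]], n_datasets = n_datasets, u = u,
                         alpha = alpha, ...)
    rows[[i]] <- dplyr::bind_cols(grid[i, ],
                                  tibble::tibble(n = pe$n_datasets,
                                                 x = pe$n_rejected,
                                                 power = pe$power,
                                                 ci_low = pe$ci_low,
                                                 ci_high = pe$ci_high,
                                                 u = pe$u, alpha = alpha))
    if (!is.null(checkpoint)) {
      utils::write.table(dplyr::bind_rows(rows[seq_len(i)]), checkpoint,
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_sweep", class(out))
  out
}
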