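#' Exact log-likelihood of an abundance sample under the standard neutral
#' model
#'
#' Computes the exact sampling probability of the abundance configuration
#' `D = (n_1, ..., n_S)` under Hubbell's standard neutral model with
#' biodiversity parameter \eqn{\theta} and immigration parameter `m`, using
#' the sampling formula
#' \deqn{P(D \mid \theta, m, J) = \frac{J!}{\prod_i n_i \prod_j \Phi_j!}
#'   \frac{\theta^S}{(I)_J} \sum_{A=S}^{J} K(D, A) \frac{I^A}{(\theta)_A},}
#' where \eqn{I = m(J-1)/(1-m)}, \eqn{(x)_N} is the rising factorial,
#' \eqn{\Phi_j} is the number of species with abundance `j`, and
#' \eqn{K(D, A)} collects products of unsigned Stirling numbers of the first
#' kind over ancestral configurations. The `K(D, A)` terms span hundreds of
#' orders of magnitude, so the per-species coefficient arrays are convolved
#' entirely in log space; the result is finite for all valid inputs.
#'
#' At `m = 1` the local community is a pure metacommunity sample and the
#' likelihood reduces to the Ewens sampling formula
#' \eqn{P(D) = \frac{J!}{\prod_i n_i \prod_j \Phi_j!}
#' \frac{\theta^S}{(\theta)_J}}.
#'
#' @param d An [abundance_sample()] (or counts vector / data frame).
#' @param theta Positive biodiversity parameter (vectorized).
#' @param m Immigration parameter in `(0, 1]` (vectorized with `theta`).
#' @param logK Optional precomputed result of [sample_logkda()] for `d`;
#'   supply it when evaluating many parameter values for one sample.
#' @return Numeric vector of natural-log probabilities.
#' @examples
#' d <- abundance_sample(c(3, 1, 1))
#' etienne_loglik(d, theta = 2, m = 0.3)
#' @export
etienne_loglik <- function(d, theta, m, logK = NULL) {
  n <- sample_counts(d)
  if (any(theta <= 0)) abort("'theta' must be positive")
  if (any(m <= 0 | m > 1)) abort("'m' must be in (0, 1]")
  f <- make_loglik(n, logK)
  k <- max(length(theta), length(m))
  theta <- rep_len(theta, k); m <- rep_len(m, k)
  vapply(seq_len(k), function(i) f(theta[i], m[i]), numeric(1))
}

# closure evaluating the sampling-formula log-likelihood with the
# parameter-independent pieces (prefactor, K array) computed once
make_loglik <- function(n, logK = NULL) {
  J <- sum(n); S <- length(n)
  phi <- abundance_phi(n)
  lpre <- lgamma(J + 1) - sum(log(n)) - sum(lgamma(phi + 1))
  if (is.null(logK)) logK <- .logkda_cpp(n)
  A <- seq.int(S, J)
  function(th, mm) {
    if (mm == 1 || J == 1) {
      # Ewens limit: the dispersal stage is bypassed (and at J = 1 every
      # parameter set gives probability 1, which this reduces to)
      lpre + S * log(th) - (lgamma(th + J) - lgamma(th))
    } else {
      I <- mm * (J - 1) / (1 - mm)
      terms <- logK + A * log(I) - lgamma(th + A)
      mx <- max(terms)
      lse <- mx + log(sum(exp(terms - mx)))
      lpre + S * log(th) + lgamma(th) - (lgamma(I + J) - lgamma(I)) + lse
    }
  }
}

#' Sampling-formula coefficient array of an abundance sample
#'
#' Returns `log K(D, A)` for `A = S, ..., J`, the log-space convolution of
#' the per-species unsigned-Stirling coefficient arrays. This is the
#' expensive, parameter-independent part of [etienne_loglik()]; compute it
#' once per sample when scanning many `(theta, m)` values.
#'
#' @inheritParams etienne_loglik
#' @return Numeric vector of length `J - S + 1`.
#' @export
sample_logkda <- function(d) {
  .logkda_cpp(sample_counts(d))
}

#' Sample the standard neutral model by the urn algorithm
#'
#' Draws one abundance sample of size `J` from the standard neutral model at
#' `(theta, m)` using the sequential two-stage urn: individual `j` founds a
#' new immigrant ancestor with probability \eqn{I/(I + j - 1)} (with
#' \eqn{I = m(J-1)/(1-m)}) and otherwise copies the species of a uniformly
#' chosen earlier individual; the `a`-th ancestor founds a new species with
#' probability \eqn{\theta/(\theta + a - 1)} and otherwise takes the species
#' of a uniformly chosen earlier ancestor. The marginal law of the counts is
#' exactly [etienne_loglik()].
#'
#' @param theta Positive biodiversity parameter.
#' @param m Immigration parameter in `(0, 1]`; `m = 1` samples the Ewens
#'   (pure metacommunity) limit.
#' @param J Community size, `>= 1`.
#' @return An [abundance_sample()].
#' @examples
#' set.seed(1)
#' urn_sample(theta = 10, m = 0.5, J = 50)
#' @export
urn_sample <- function(theta, m, J) {
  if (!is.numeric(theta) || theta <= 0) abort("'theta' must be positive")
  if (!is.numeric(m) || m <= 0 || m > 1) abort("'m' must be in (0, 1]")
  if (!is.numeric(J) || J < 1 || J != round(J)) abort("'J' must be a positive integer")
  J <- as.integer(J)
  counts <- if (J == 1L) {
    1L
  } else if (m == 1) {
    ewens_urn(theta, J)
  } else {
    .urn_cpp(theta, m * (J - 1) / (1 - m), J)
  }
  abundance_sample(counts, metadata = list(model = "snm", theta = theta, m = m))
}

# single-stage Hoppe urn: every individual is its own ancestor
ewens_urn <- function(theta, J) {
  sp <- integer(J); n_sp <- 0L
  for (j in seq_len(J)) {
    if (runif(1) * (theta + j - 1) < theta) {
      n_sp <- n_sp + 1L
      sp[j] <- n_sp
    } else {
      sp[j] <- sp[sample.int(j - 1L, 1L)]
    }
  }
  tabulate(sp, nbins = n_sp)
}

#' Maximum-likelihood fit of the standard neutral model
#'
#' Maximizes [etienne_loglik()] over \eqn{(\log \theta, \mathrm{logit}\, m)}
#' using a coarse log-spaced grid of starting values followed by
#' derivative-free (Nelder-Mead) refinement of the best starts. The surface
#' can be bimodal (a low-`theta`/high-`m` and a high-`theta`/low-`m` optimum
#' can coexist), which the multi-start scheme is designed to catch. For
#' monodominant samples the likelihood increases monotonically toward the
#' small-`m` boundary; the fit then reports the boundary and
#' `converged = FALSE`.
#'
#' @param d An [abundance_sample()] (or counts vector / data frame).
#' @param grid_theta,grid_m Number of grid points for `theta` (log-spaced on
#'   `[1, J]`) and `m` (logit-spaced on `[1e-4, 0.99]`).
#' @param refine_top How many of the best grid points to refine.
#' @param reltol Relative convergence tolerance of the refinement.
#' @param maxit Iteration cap per refinement.
#' @return An object of class `neutral_fit`: a list with elements `theta`,
#'   `m`, `logL`, `converged`, `boundary`, `n_starts` and `starts` (a tibble
#'   of all grid starts and refined optima). Use [tidy()] / [glance()] to
#'   extract tibbles.
#' @examples
#' set.seed(1)
#' fit_neutral(urn_sample(20, 0.3, 200))
#' @export
fit_neutral <- function(d, grid_theta = 5, grid_m = 5, refine_top = 3,
                        reltol = 1e-6, maxit = 300) {
  n <- sample_counts(d)
  J <- sum(n)

  if (length(n) == 1L && J == 1L) {
    # single individual: likelihood is 1 everywhere
    return(new_neutral_fit(theta = 1, m = 0.5, logL = 0, converged = TRUE,
                           boundary = FALSE,
                           starts = tibble::tibble(theta = 1, m = 0.5, logL = 0,
                                                   refined = FALSE), J = J))
  }

  llfun <- make_loglik(n)
  nll <- function(par) {
    th <- exp(par[1]); mm <- stats::plogis(par[2])
    if (!is.finite(th) || th <= 0 || th > 1e8 || mm <= 0 || mm >= 1) return(1e10)
    ll <- llfun(th, mm)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  thetas <- exp(seq(log(1), log(max(J, 2)), length.out = grid_theta))
  ms <- stats::plogis(seq(stats::qlogis(1e-4), stats::qlogis(0.99), length.out = grid_m))
  grid <- expand.grid(theta = thetas, m = ms)
  grid$logL <- vapply(seq_len(nrow(grid)),
                      function(i) llfun(grid$theta[i], grid$m[i]), numeric(1))
  grid$refined <- FALSE

  ord <- order(grid$logL, decreasing = TRUE)
  top <- ord[seq_len(min(refine_top, nrow(grid)))]

  best <- list(par = c(log(grid$theta[top[1]]), stats::qlogis(grid$m[top[1]])),
               value = -grid$logL[top[1]], convergence = 1L)
  refined <- list()
  for (i in top) {
    p0 <- c(log(grid$theta[i]), stats::qlogis(grid$m[i]))
    opt <- tryCatch(
      optim(p0, nll, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(opt)) next
    refined[[length(refined) + 1L]] <-
      tibble::tibble(theta = exp(opt$par[1]), m = stats::plogis(opt$par[2]),
                     logL = -opt$value, refined = TRUE)
    if (opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    abort("all optimizer starts failed", class = "sadpower_fit_error")
  }
  starts <- dplyr::bind_rows(tibble::as_tibble(grid), dplyr::bind_rows(refined))

  theta_hat <- exp(best$par[1]); m_hat <- stats::plogis(best$par[2])
  boundary <- m_hat < 2e-4 || m_hat > 0.9985 || theta_hat > 1e7 || theta_hat < 1e-3
  new_neutral_fit(theta = theta_hat, m = m_hat, logL = -best$value,
                  converged = isTRUE(best$convergence == 0L) && !boundary,
                  boundary = boundary, starts = starts, J = J)
}

new_neutral_fit <- function(theta, m, logL, converged, boundary, starts, J) {
  structure(list(theta = theta, m = m, logL = logL, converged = converged,
                 boundary = boundary, n_starts = nrow(starts), starts = starts,
                 J = J),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("<neutral_fit>  theta = %.4g, m = %.4g, logL = %.4f%s\n",
              x$theta, x$m, x$logL,
              if (x$boundary) " (boundary)" else if (!x$converged) " (not converged)" else ""))
  invisible(x)
}
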