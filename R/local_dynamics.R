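#' Per-species mortality weights of the density-dependent mortality model
#'
#' In the HL model the probability that the next death is of species `i` is
#' proportional to \eqn{[(1-\gamma) + \gamma n_i/J] \, n_i/J}. At
#' \eqn{\gamma = 0} every individual is equally likely to die (the neutral
#' limit); as \eqn{\gamma \to 1} per-capita mortality rises with abundance,
#' which promotes coexistence. Values of \eqn{\gamma > 1} would make the
#' weights negative and are rejected.
#'
#' @param d An [abundance_sample()], data frame with a `count` column, or
#'   vector of counts.
#' @param gamma Relative strength of inter- vs intra-specific density
#'   dependence, in `[0, 1]`.
#' @return A tibble with columns `species`, `count` and `weight`; weights
#'   sum to 1.
#' @examples
#' hl_mortality_weights(abundance_sample(c(7, 3)), gamma = 0)
#' @export
hl_mortality_weights <- function(d, gamma) {
  check_unit("gamma", gamma, lo = 0, hi = 1)
  df <- if (inherits(d, "abundance_sample")) d else abundance_sample(d)
  J <- sum(df$count)
  w <- ((1 - gamma) + gamma * df$count / J) * (df$count / J)
  tibble::tibble(species = df$species, count = df$count, weight = w / sum(w))
}

#' Map stochastic Lotka-Volterra rates onto the HL parameters
#'
#' The HL model can be derived from a multispecies stochastic Lotka-Volterra
#' competition model with density-independent birth rate `r_plus`, mortality
#' rate `r_minus`, carrying capacity `K_prime`, interaction-neutrality
#' parameter `alpha` (1 = neutral, 0..1 = competition, negative =
#' mutualism), and per-species immigration rate `mu` from a pool of `S_T`
#' species. Conditioning those rates on a fixed community size `J` yields
#' the two HL parameters
#' \deqn{\gamma = \frac{1}{1 + \frac{r_- K' + (r_+ - r_-) J \alpha}
#'   {(r_+ - r_-) J (1-\alpha)}}, \qquad
#'   m = \frac{1}{1 + r_+ J / (\mu S_T)}.}
#' A non-trivial equilibrium requires `r_plus > r_minus`, and strongly
#' mutualistic interactions (`alpha` below `-r_minus*K_prime/((r_plus -
#' r_minus)*J)`) fall outside the admissible range.
#'
#' @param r_plus,r_minus Density-independent birth and death rates.
#' @param K_prime Carrying capacity scale.
#' @param alpha Interaction neutrality (`alpha = 1` gives `gamma = 0`).
#' @param mu Per-species immigration rate.
#' @param J Local community size.
#' @param S_T Number of species in the pool.
#' @return A one-row tibble with columns `gamma` and `m`.
#' @export
hl_params_from_rates <- function(r_plus, r_minus, K_prime, alpha, mu, J, S_T) {
  if (r_plus <= r_minus) abort("'r_plus' must exceed 'r_minus'")
  lo <- -r_minus * K_prime / ((r_plus - r_minus) * J)
  if (alpha < lo || alpha > 1) {
    abort(sprintf("'alpha' must lie in [%.6g, 1]", lo))
  }
  gamma <- if (alpha == 1) 0 else {
    1 / (1 + (r_minus * K_prime + (r_plus - r_minus) * J * alpha) /
           ((r_plus - r_minus) * J * (1 - alpha)))
  }
  m <- 1 / (1 + r_plus * J / (mu * S_T))
  if (gamma < 0 || gamma > 1 || m <= 0 || m > 1) abort("mapped parameters out of range")
  tibble::tibble(gamma = gamma, m = m)
}

#' Propagule fractions of the Ricker fecundity-competition model
#'
#' In the PC model the local propagule pool of species `i` is proportional
#' to \eqn{n_i e^{-c n_i / J}}: fecundity is penalized Ricker-style, more
#' strongly for conspecifics than heterospecifics, with `c = J(a - b)`
#' measuring the excess of intra- over inter-specific density dependence.
#' `c = 0` is the neutral limit.
#'
#' @inheritParams hl_mortality_weights
#' @param c Non-negative competition strength.
#' @return A tibble with columns `species`, `count` and `fraction`
#'   (fractions sum to 1).
#' @export
pc_propagule_fractions <- function(d, c) {
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c < 0) {
    abort("'c' must be a non-negative number")
  }
  df <- if (inherits(d, "abundance_sample")) d else abundance_sample(d)
  J <- sum(df$count)
  w <- df$count * exp(-c * df$count / J)
  tibble::tibble(species = df$species, count = df$count, fraction = w / sum(w))
}

#' Draw intrinsic species fitnesses for the IF model
#'
#' Fitnesses are i.i.d. Gamma with shape `1/k` and scale `k` (mean 1), so
#' `sqrt(k)` is their coefficient of variation. `k = 0` returns equal
#' fitnesses (the neutral limit); `k = Inf` is the strong-selection limit in
#' which a single species out-competes all others, represented here by
#' i.i.d. heavy-rank draws whose only role is their ordering.
#'
#' @param species Species labels (or a single integer, meaning `1:n`).
#' @param k Squared coefficient of variation of fitness, `>= 0`.
#' @return A tibble with columns `species` and `fitness`.
#' @export
if_fitnesses <- function(species, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0) {
    abort("'k' must be a non-negative number (Inf allowed)")
  }
  if (length(species) == 1 && is.numeric(species) && species >= 1) {
    species <- seq_len(species)
  }
  n <- length(species)
  f <- if (k == 0) {
    rep(1, n)
  } else if (is.infinite(k)) {
    # only the ranking matters in the strong-selection limit
    rexp(n)
  } else {
    rgamma(n, shape = 1 / k, scale = k)
  }
  f <- pmax(f, .Machine$double.xmin)
  tibble::tibble(species = species, fitness = f)
}

# fraction of local propagules per species under intrinsic fitness
# differences: L_i = f_i n_i / sum_k f_k n_k (scale-free in f)
if_propagule_fractions <- function(counts, fitness, strong_selection = FALSE) {
  if (strong_selection) {
    L <- numeric(length(counts))
    L[which.max(fitness)] <- 1
    return(L)
  }
  w <- fitness * counts
  w / sum(w)
}

check_unit <- function(name, x, lo, hi) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("'%s' must be a number in [%g, %g]", name, lo, hi))
  }
}

# ---------------------------------------------------------------------------
# model specification and one-generation updates
# ---------------------------------------------------------------------------

#' Specify a generating community model
#'
#' Bundles a local dynamics model, its non-neutrality strength, the
#' metacommunity, and the community size into a single specification used by
#' [sim_community()], [estimate_power()] and [fit_to_targets()].
#'
#' Models: `"hl"` (sequential density-dependent mortality, strength
#' `gamma`), `"pc"` (synchronous Ricker fecundity competition, strength
#' `c`), `"if"` (synchronous intrinsic fitness differences, strength `k`),
#' and `"snm"` (the standard neutral model itself, sampled exactly by the
#' urn algorithm — only valid with a logseries metacommunity).
#'
#' @param model One of `"hl"`, `"pc"`, `"if"`, `"snm"`.
#' @param meta A metacommunity from [meta_logseries()], [meta_even()] or
#'   [meta_infinite()], or one of the strings `"logseries"`, `"even"`,
#'   `"infinite_even"` (built per replicate from `theta`/`S_T`).
#' @param J Local community size (number of individuals).
#' @param m Immigration probability per recruit, in `(0, 1]`.
#' @param gamma,c,k Non-neutrality strengths (only the one matching `model`
#'   is used; `k = Inf` is allowed).
#' @param theta,S_T Metacommunity parameters when `meta` is given as a
#'   string.
#' @param redraw_meta Draw a fresh metacommunity for every replicate dataset
#'   (the default, matching per-realisation pools); `FALSE` shares one pool.
#' @return A list of class `community_model`.
#' @export
community_model <- function(model = c("hl", "pc", "if", "snm"),
                            meta = "logseries", J, m,
                            gamma = 0, c = 0, k = 0,
                            theta = NULL, S_T = 2000,
                            redraw_meta = TRUE) {
  model <- match.arg(model)
  if (!is.numeric(J) || length(J) != 1 || J < 1 || J != round(J)) {
    abort("'J' must be a positive integer")
  }
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m > 1) {
    abort("'m' must be in (0, 1]")
  }
  if (model == "hl") check_unit("gamma", gamma, 0, 1)
  if (model == "pc" && (!is.finite(c) || c < 0)) abort("'c' must be >= 0")
  if (model == "if" && (is.na(k) || k < 0)) abort("'k' must be >= 0 (Inf allowed)")
  if (is.character(meta)) {
    meta <- match.arg(meta, c("logseries", "even", "infinite_even"))
    if (meta == "logseries" && is.null(theta)) abort("'theta' required for a logseries pool")
  }
  if (model == "snm") {
    kind <- if (is.character(meta)) meta else meta_kind(meta)
    if (kind != "logseries") abort("the standard neutral model uses a logseries metacommunity")
    if (is.null(theta)) theta <- attr(meta, "theta")
  }
  if (model == "pc" && (is.character(meta) && meta == "even" || !is.character(meta) &&
                        meta_kind(meta) == "even")) {
    ST_eff <- if (is.character(meta)) S_T else attr(meta, "S_T")
    if (is.finite(ST_eff) && c >= 2 * ST_eff) {
      warn(sprintf(paste0("c = %g is at or beyond the stability boundary ",
                          "c = 2*S_T = %g of the even fixed point; ",
                          "dynamics may cycle or be chaotic"), c, 2 * ST_eff))
    }
  }
  structure(list(model = model, meta = meta, J = as.integer(J), m = m,
                 gamma = gamma, c = c, k = k, theta = theta, S_T = S_T,
                 redraw_meta = isTRUE(redraw_meta)),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  strength <- switch(x$model, hl = sprintf("gamma = %g", x$gamma),
                     pc = sprintf("c = %g", x$c),
                     "if" = sprintf("k = %g", x$k), snm = "neutral")
  kind <- if (is.character(x$meta)) x$meta else meta_kind(x$meta)
  cat(sprintf("<community_model> %s/%s  J = %d, m = %g, %s\n",
              toupper(x$model), toupper(kind), x$J, x$m, strength))
  invisible(x)
}

# materialize the metacommunity for one replicate
realize_meta <- function(spec) {
  if (!is.character(spec$meta)) return(spec$meta)
  switch(spec$meta,
         logseries = meta_logseries(spec$theta, spec$S_T),
         even = meta_even(spec$S_T),
         infinite_even = meta_infinite())
}

# internal simulation state: named integer count vector plus bookkeeping
init_state <- function(meta, J) {
  if (meta_kind(meta) == "infinite_even") {
    # i.i.d. draws from an infinitely diverse pool are J distinct species
    list(counts = rep(1L, J), labels = seq_len(J), next_label = J + 1L)
  } else {
    idx <- sample.int(nrow(meta), J, replace = TRUE, prob = meta$p)
    tab <- tabulate(idx, nbins = nrow(meta))
    keep <- which(tab > 0)
    list(counts = tab[keep], labels = meta$species[keep], next_label = NA_integer_)
  }
}

state_stats <- function(counts, J) {
  p <- counts / J
  c(S = length(counts), H = -sum(p * log(p)))
}

# one synchronous multinomial generation for models PC and IF with an
# infinitely diverse even pool: the immigrant count is binomial and every
# immigrant founds a fresh species
sync_generation_infinite <- function(state, spec, fitness_env = NULL) {
  J <- spec$J; m <- spec$m
  counts <- state$counts; labels <- state$labels
  strong <- spec$model == "if" && is.infinite(spec$k)
  L <- if (spec$model == "pc") {
    w <- counts * exp(-spec$c * counts / J)
    w / sum(w)
  } else {
    f <- fitness_env$fitness[as.character(labels)]
    if_propagule_fractions(counts, f, strong_selection = strong)
  }
  n_imm <- rbinom(1, J, m)
  new_counts <- integer(0); new_labels <- integer(0)
  if (n_imm < J) {
    loc <- as.integer(rmultinom(1, J - n_imm, L))
    keep <- which(loc > 0)
    new_counts <- loc[keep]; new_labels <- labels[keep]
  }
  nl <- state$next_label
  if (n_imm > 0) {
    imm_labels <- seq.int(nl, length.out = n_imm)
    nl <- nl + n_imm
    if (!is.null(fitness_env)) assign_new_fitness(fitness_env, imm_labels, spec$k)
    new_counts <- c(new_counts, rep(1L, n_imm))
    new_labels <- c(new_labels, imm_labels)
  }
  list(counts = new_counts, labels = new_labels, next_label = nl)
}

assign_new_fitness <- function(env, labels, k) {
  f <- if_fitnesses(labels, k)$fitness
  env$fitness[as.character(labels)] <- f
}

# advance the state by ngen generations, returning per-generation (S, H).
# Finite pools use a dense count vector indexed by pool species (recruitment
# weights R_i = m P_i + (1-m) L_i over all S_T species, one multinomial per
# generation); the infinite pool keeps a sparse labelled state.
advance <- function(state, spec, meta, ngen, fitness_env = NULL) {
  kind <- meta_kind(meta)
  if (spec$model == "hl") {
    Pcum <- if (kind == "infinite_even") numeric(0) else cumsum(meta$p)
    res <- .hl_run_cpp(as.integer(state$labels), as.integer(state$counts), Pcum,
                       spec$gamma, spec$m, spec$J, as.integer(ngen),
                       kind == "infinite_even",
                       if (is.na(state$next_label)) 0L else as.integer(state$next_label))
    state <- list(counts = res$counts, labels = res$labels,
                  next_label = if (kind == "infinite_even") res$next_label else NA_integer_)
    return(list(state = state, S = res$S, H = res$H))
  }
  Sv <- numeric(ngen); Hv <- numeric(ngen)
  if (kind == "infinite_even") {
    for (g in seq_len(ngen)) {
      state <- sync_generation_infinite(state, spec, fitness_env)
      st <- state_stats(state$counts, spec$J)
      Sv[g] <- st["S"]; Hv[g] <- st["H"]
    }
    return(list(state = state, S = Sv, H = Hv))
  }
  J <- spec$J
  S_T <- nrow(meta)
  cnt <- integer(S_T)
  cnt[state$labels] <- state$counts
  mP <- spec$m * meta$p
  one_m <- 1 - spec$m
  strong <- spec$model == "if" && is.infinite(spec$k)
  fvec <- if (spec$model == "if") fitness_env$fitness[as.character(meta$species)] else NULL
  cfac <- -spec$c / J
  for (g in seq_len(ngen)) {
    idx <- which(cnt > 0L)
    n <- cnt[idx]
    w <- if (spec$model == "pc") {
      n * exp(cfac * n)
    } else if (strong) {
      z <- numeric(length(idx)); z[which.max(fvec[idx])] <- 1; z
    } else {
      fvec[idx] * n
    }
    R <- mP
    R[idx] <- R[idx] + one_m * (w / sum(w))
    cnt <- as.integer(rmultinom(1, J, R))
    nz <- cnt[cnt > 0L]
    p <- nz / J
    Sv[g] <- length(nz)
    Hv[g] <- -sum(p * log(p))
  }
  keep <- which(cnt > 0L)
  list(state = list(counts = cnt[keep], labels = meta$species[keep],
                    next_label = state$next_label),
       S = Sv, H = Hv)
}

# Mann-Kendall-style no-trend check on bin means of the second half of a
# trajectory; returns TRUE when neither richness nor Shannon index shows a
# trend at level alpha
no_trend <- function(S, H, bins = 8, alpha = 0.05) {
  t <- length(S)
  if (t < 2 * bins) return(FALSE)
  half <- seq.int(floor(t / 2) + 1, t)
  grp <- cut(seq_along(half), bins, labels = FALSE)
  flat <- function(x) {
    mx <- tapply(x, grp, mean)
    if (stats::sd(mx) == 0) return(TRUE)
    suppressWarnings(cor.test(seq_along(mx), mx, method = "kendall")$p.value) > alpha
  }
  flat(S[half]) && flat(H[half])
}

#' Simulate a community model to equilibrium
#'
#' Initializes a local community of `J` individuals drawn i.i.d. from the
#' metacommunity, runs the specified dynamics until the species richness and
#' Shannon index trajectories show no trend (Mann-Kendall test on window
#' means of the most recent half of the trajectory, at level
#' `trend_alpha`), records that time `T`, then continues to `burn_factor *
#' T` generations before returning the final configuration. For the `"snm"`
#' model the exact urn sampler is used instead of time-stepping.
#'
#' @param spec A [community_model()].
#' @param burn_factor Safety multiplier applied to the detected
#'   equilibration time (default 10).
#' @param min_gen,max_gen Minimum and maximum number of generations; the
#'   burn-in detector failing to converge before `max_gen` is an error of
#'   class `sadpower_convergence_error`.
#' @param check_every Generations between trend checks.
#' @param window Number of window means used by the trend test.
#' @param trend_alpha Significance level of the trend test.
#' @return An [abundance_sample()] whose metadata records the model,
#'   parameters, the detected equilibration time and generations run.
#' @examples
#' set.seed(1)
#' spec <- community_model("pc", meta = "even", J = 100, m = 0.1, c = 1, S_T = 20)
#' sim_community(spec)
#' @export
sim_community <- function(spec, burn_factor = 10, min_gen = 40, max_gen = 5e4,
                          check_every = 20, window = 8, trend_alpha = 0.05) {
  stopifnot(inherits(spec, "community_model"))
  if (spec$model == "snm") {
    d <- urn_sample(spec$theta, spec$m, spec$J)
    attr(d, "metadata") <- c(attr(d, "metadata"),
                             list(model = "snm", theta = spec$theta, m = spec$m))
    return(d)
  }
  meta <- realize_meta(spec)
  state <- init_state(meta, spec$J)
  fitness_env <- NULL
  if (spec$model == "if") {
    fitness_env <- new.env(parent = emptyenv())
    fitness_env$fitness <- numeric(0)
    seed_labels <- if (meta_kind(meta) == "infinite_even") state$labels else meta$species
    assign_new_fitness(fitness_env, seed_labels, spec$k)
  }

  Sh <- numeric(0); Hh <- numeric(0)
  T_eq <- NA_integer_
  while (length(Sh) < max_gen) {
    res <- advance(state, spec, meta, check_every, fitness_env)
    state <- res$state
    Sh <- c(Sh, res$S); Hh <- c(Hh, res$H)
    if (length(Sh) >= min_gen && no_trend(Sh, Hh, bins = window, alpha = trend_alpha)) {
      T_eq <- length(Sh)
      break
    }
  }
  if (is.na(T_eq)) {
    abort(sprintf(paste0("burn-in detector did not converge within %d generations ",
                         "(final richness %d, Shannon %.3f)"),
                  as.integer(max_gen), length(state$counts),
                  state_stats(state$counts, spec$J)[["H"]]),
          class = "sadpower_convergence_error")
  }
  extra <- (burn_factor - 1) * T_eq
  while (extra > 0) {
    chunk <- min(extra, 500L)
    res <- advance(state, spec, meta, chunk, fitness_env)
    state <- res$state
    extra <- extra - chunk
  }
  abundance_sample(state$counts, species = state$labels,
                   metadata = list(model = spec$model, meta = meta_kind(meta),
                                   J = spec$J, m = spec$m, gamma = spec$gamma,
                                   c = spec$c, k = spec$k,
                                   theta = attr(meta, "theta"),
                                   S_T = attr(meta, "S_T"),
                                   T_equilibrium = T_eq,
                                   generations = burn_factor * T_eq,
                                   redraw_meta = spec$redraw_meta))
}

# ---------------------------------------------------------------------------
# deterministic large-J mean map of the PC model and its stability
# ---------------------------------------------------------------------------

#' Deterministic mean map of the PC model and its stability boundary
#'
#' For large `J` and vanishing immigration the PC dynamics of the relative
#' abundances follow the deterministic map
#' \eqn{r_i(t+1) = r_i e^{-c r_i} / \sum_k r_k e^{-c r_k}}. With an even
#' pool of `S_T` species the uniform point \eqn{r_i = 1/S_T} is a fixed
#' point; linearization gives multiplier \eqn{\lambda = 1 - c/S_T} for every
#' perturbation mode, so the fixed point is stable for \eqn{c < 2 S_T} and
#' gives way to period-2 cycles (and, further, chaos) beyond. The critical
#' value of the dimensionless ratio \eqn{c/S_T} is therefore 2, independent
#' of `S_T`.
#'
#' `pc_mean_map()` applies one iteration; `pc_uniform_stable()` decides
#' stability empirically by iterating a perturbed uniform start;
#' `pc_stability_boundary()` locates the critical ratio `c/S_T` by
#' bisection on the empirical criterion.
#'
#' @param r Vector of relative abundances (summing to 1).
#' @param c Competition strength.
#' @param S_T Number of species.
#' @param perturb Size of the initial perturbation.
#' @param iter Iterations used by the empirical criterion.
#' @param tol Bisection tolerance on the ratio `c/S_T`.
#' @param lo,hi Initial bisection bracket for the ratio `c/S_T`.
#' @return `pc_mean_map()` a numeric vector; `pc_uniform_stable()` a
#'   logical; `pc_stability_boundary()` a one-row tibble with columns `S_T`,
#'   `critical_ratio` (critical `c/S_T`) and `critical_c`.
#' @examples
#' pc_stability_boundary(S_T = 10)
#' @export
pc_mean_map <- function(r, c) {
  w <- r * exp(-c * r)
  w / sum(w)
}

#' @rdname pc_mean_map
#' @export
pc_uniform_stable <- function(c, S_T, perturb = 1e-4, iter = 4000) {
  r0 <- rep(1 / S_T, S_T)
  d <- sin(seq_len(S_T))          # deterministic zero-mean-ish perturbation
  d <- d - mean(d)
  d <- d / sqrt(sum(d^2)) * perturb
  r <- r0 + d
  dev0 <- sqrt(sum((r - r0)^2))
  for (i in seq_len(iter)) r <- pc_mean_map(r, c)
  sqrt(sum((r - r0)^2)) < dev0
}

#' @rdname pc_mean_map
#' @export
pc_stability_boundary <- function(S_T, tol = 1e-4, lo = 0.5, hi = 4) {
  if (!pc_uniform_stable(lo * S_T, S_T) || pc_uniform_stable(hi * S_T, S_T)) {
    abort("bisection bracket does not straddle the boundary")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pc_uniform_stable(mid * S_T, S_T)) lo <- mid else hi <- mid
  }
  ratio <- (lo + hi) / 2
  tibble::tibble(S_T = S_T, critical_ratio = ratio, critical_c = ratio * S_T)
}
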