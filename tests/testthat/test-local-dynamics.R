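test_that("HL mortality weights match the density-dependence formula", {
  d <- abundance_sample(c(7, 3), species = c("B", "A"))
  # neutral limit: weights proportional to abundance
  w0 <- hl_mortality_weights(d, gamma = 0)
  expect_equal(w0$weight[w0$species == "A"], 0.3)
  expect_equal(w0$weight[w0$species == "B"], 0.7)
  # full density dependence: weights proportional to (n/J)^2
  w1 <- hl_mortality_weights(d, gamma = 1)
  expect_equal(w1$weight[w1$species == "A"], 9 / 58)
  expect_equal(w1$weight[w1$species == "B"], 49 / 58)
  # single species always dies
  expect_equal(hl_mortality_weights(abundance_sample(12), gamma = 0.7)$weight, 1)
  expect_error(hl_mortality_weights(d, gamma = 1.5), "gamma")
})

test_that("Lotka-Volterra rates map onto (gamma, m) as the closed forms say", {
  # direct hand evaluation: r+=2, r-=1, K'=100, alpha=0.5, J=100, S_T=10, mu=5
  # gamma = 1/(1 + (1*100 + 1*100*0.5)/(1*100*0.5)) = 1/4
  # m     = 1/(1 + 2*100/(5*10))                    = 1/5
  p <- hl_params_from_rates(r_plus = 2, r_minus = 1, K_prime = 100,
                            alpha = 0.5, mu = 5, J = 100, S_T = 10)
  expect_equal(p$gamma, 0.25)
  expect_equal(p$m, 0.2)

  # alpha = 1 is the neutral case
  expect_equal(hl_params_from_rates(2, 1, 100, 1, 5, 100, 10)$gamma, 0)
  # huge immigration rate drives m to 1
  expect_equal(hl_params_from_rates(2, 1, 100, 0.5, 1e12, 100, 10)$m, 1,
               tolerance = 1e-9)
  expect_error(hl_params_from_rates(1, 2, 100, 0.5, 5, 100, 10), "r_plus")
  expect_error(hl_params_from_rates(2, 1, 100, -50, 5, 100, 10), "alpha")
})

test_that("PC propagule fractions follow the Ricker fecundity form", {
  d <- abundance_sample(c(90, 10), species = c("B", "A"))
  # neutral limit c = 0
  f0 <- pc_propagule_fractions(d, c = 0)
  expect_equal(f0$fraction, c(0.9, 0.1))
  # equal abundances: common factor cancels for any c
  f_even <- pc_propagule_fractions(abundance_sample(rep(20, 5)), c = 3)
  expect_equal(f_even$fraction, rep(0.2, 5))
  # direct evaluation at c = 1
  f1 <- pc_propagule_fractions(d, c = 1)
  la <- 10 * exp(-0.1); lb <- 90 * exp(-0.9)
  expect_equal(f1$fraction[f1$species == "A"], la / (la + lb))
  expect_error(pc_propagule_fractions(d, c = -1), "'c'")
})

test_that("intrinsic fitnesses have the Gamma moments and are scale-free", {
  expect_equal(if_fitnesses(5, k = 0)$fitness, rep(1, 5))
  set.seed(10)
  f <- if_fitnesses(1e5, k = 0.25)$fitness
  cv <- stats::sd(f) / mean(f)
  expect_lt(abs(cv - 0.5), 0.02)
  expect_lt(abs(mean(f) - 1), 0.02)
  # propagule fractions depend only on fitness ratios
  counts <- c(4, 3, 2)
  fit <- c(0.2, 1.1, 3.0)
  expect_equal(sadpower:::if_propagule_fractions(counts, fit),
               sadpower:::if_propagule_fractions(counts, 7 * fit))
  expect_error(if_fitnesses(5, k = -1), "k")
})

test_that("community size J is conserved by every model and pool", {
  set.seed(11)
  cases <- list(
    community_model("hl", meta = "even", J = 80, m = 0.2, gamma = 0.6, S_T = 20),
    community_model("pc", meta = "logseries", J = 80, m = 0.2, c = 1, theta = 10, S_T = 300),
    community_model("if", meta = "even", J = 80, m = 0.2, k = 0.5, S_T = 20),
    community_model("pc", meta = "infinite_even", J = 80, m = 0.2, c = 0.5),
    community_model("if", meta = "infinite_even", J = 80, m = 0.2, k = Inf),
    community_model("hl", meta = "infinite_even", J = 80, m = 0.3, gamma = 1)
  )
  for (spec in cases) {
    d <- sim_community(spec)
    expect_identical(sum(d$count), 80L)
    expect_true(all(d$count > 0))
  }
})

test_that("HL stationary law at J = 3 matches the exact Markov chain", {
  gamma <- 0.5; m <- 0.5
  P <- hl3_transition_matrix(gamma, m)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  pi_exact <- stationary_distribution(P)

  set.seed(12)
  meta <- meta_even(2)
  nrep <- 3000
  n1 <- replicate(nrep, {
    init <- sadpower:::init_state(meta, 3)
    res <- sadpower:::.hl_run_cpp(as.integer(init$labels), as.integer(init$counts),
                                  cumsum(meta$p), gamma, m, 3L, 60L, FALSE, 0L)
    s <- res$counts[res$labels == 1L]
    if (length(s)) s else 0L
  })
  obs <- tabulate(n1 + 1L, nbins = 4)
  expect_gt(stats::chisq.test(obs, p = pi_exact)$p.value, 0.01)
})

test_that("the uniform fixed point of the PC mean map is stable iff c < 2 S_T", {
  for (S_T in c(2, 10, 50)) {
    expect_true(pc_uniform_stable(1.9 * S_T, S_T))
    expect_false(pc_uniform_stable(2.1 * S_T, S_T))
  }
})

test_that("stronger intrinsic fitness variation lowers equilibrium richness", {
  set.seed(13)
  mean_S <- vapply(c(0, 0.5, 5), function(k) {
    spec <- community_model("if", meta = "even", J = 200, m = 0.05, k = k, S_T = 50)
    mean(replicate(30, nrow(sim_community(spec))))
  }, numeric(1))
  # non-increasing within Monte-Carlo error (~0.5 species at this budget)
  expect_true(all(diff(mean_S) < 1))
  expect_gt(mean_S[1] - mean_S[3], 2)
})

test_that("at m = 1 the equilibrium is a multinomial sample of the pool", {
  set.seed(14)
  meta <- meta_logseries(10, 200)
  spec <- community_model("pc", meta = meta, J = 100, m = 1, c = 2)
  S_sim <- replicate(40, nrow(sim_community(spec)))
  S_exp <- sum(1 - (1 - meta$p)^100)
  se <- stats::sd(S_sim) / sqrt(length(S_sim))
  expect_lt(abs(mean(S_sim) - S_exp), 4 * se + 0.2)
})

test_that("burn-in failure raises a convergence error with diagnostics", {
  set.seed(15)
  spec <- community_model("hl", meta = "logseries", J = 100, m = 0.01, theta = 20)
  expect_error(sim_community(spec, max_gen = 10, min_gen = 5, check_every = 5),
               class = "sadpower_convergence_error")
})
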