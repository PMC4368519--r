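test_that("summary statistics are exact on hand-checked samples", {
  u <- summary_stats(abundance_sample(rep(10, 100)))
  expect_identical(u$S, 100L)
  expect_equal(u$shannon, log(100))
  expect_identical(u$J, 1000L)

  mono <- summary_stats(abundance_sample(500))
  expect_identical(mono$S, 1L)
  expect_equal(mono$shannon, 0)

  d <- summary_stats(abundance_sample(c(2, 1, 1)))
  expect_identical(d$S, 3L)
  expect_equal(d$shannon, -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
})

test_that("summary targets validate their invariants", {
  expect_s3_class(summary_targets(21058, 232, 4.275), "summary_targets")
  expect_error(summary_targets(100, 200, 1), "S")
  expect_error(summary_targets(100, 50, 5), "H")
})

test_that("neutral closure: fitting the c = 0 model recovers urn-derived targets", {
  set.seed(50)
  st <- t(replicate(200, {
    s <- summary_stats(urn_sample(10, 0.3, 100))
    c(s$S, s$shannon)
  }))
  tg <- summary_targets(100, mean(st[, 1]), mean(st[, 2]))

  sol <- fit_to_targets("pc", meta = "logseries", strength = 0, targets = tg,
                        n_rep = 20, tol_H = 0.02, eval_seed = 7, S_T_pool = 500,
                        diversity_grid = exp(seq(log(2), log(40), length.out = 5)))
  expect_gte(nrow(sol), 1)

  # reported solutions reproduce the targets when re-simulated with a fresh
  # seed, within twice the Monte-Carlo standard error
  best <- sol[which.min(abs(sol$resid_S)), ]
  spec <- community_model("pc", meta = "logseries", J = 100, m = best$m,
                          c = 0, theta = best$diversity, S_T = 500)
  set.seed(51)
  re <- t(replicate(40, {
    s <- summary_stats(sim_community(spec))
    c(s$S, s$shannon)
  }))
  se_S <- stats::sd(re[, 1]) / sqrt(nrow(re))
  se_H <- stats::sd(re[, 2]) / sqrt(nrow(re))
  expect_lt(abs(mean(re[, 1]) - tg$S), 2 * se_S + 1)
  expect_lt(abs(mean(re[, 2]) - tg$H), 2 * se_H + 0.05)
})

test_that("stronger competition requires more immigration to match the same targets", {
  # On the immigration-dominated branch (H decreasing in m), the Ricker
  # penalty raises evenness at every m, so matching a fixed Shannon index
  # forces the fitted m upward as c grows.  Targets come from a mid-strength
  # synthetic community on that branch.
  set.seed(52)
  st <- t(replicate(80, {
    spec <- community_model("pc", meta = "logseries", J = 300, m = 0.5,
                            c = 4, theta = 5, S_T = 500)
    s <- summary_stats(sim_community(spec))
    c(s$S, s$shannon)
  }))
  tg <- summary_targets(300, mean(st[, 1]), mean(st[, 2]))
  grid <- exp(seq(log(2), log(12), length.out = 4))
  fit_m <- vapply(c(2, 6), function(cc) {
    sol <- fit_to_targets("pc", meta = "logseries", strength = cc, targets = tg,
                          n_rep = 12, tol_H = 0.02, eval_seed = 9,
                          S_T_pool = 500, diversity_grid = grid)
    if (!nrow(sol)) return(NA_real_)
    sol$m[which.min(abs(sol$resid_S))]
  }, numeric(1))
  expect_false(any(is.na(fit_m)))
  expect_gt(fit_m[2], fit_m[1])
})

test_that("unreachable targets give a no-solution report with an envelope", {
  # near-maximal evenness at high richness is far above anything the
  # neutral logseries model produces at these diversities
  tg <- summary_targets(60, 45, 0.98 * log(45))
  sol <- fit_to_targets("pc", meta = "logseries", strength = 0, targets = tg,
                        n_rep = 10, eval_seed = 11, S_T_pool = 300,
                        diversity_grid = c(2, 8, 30))
  expect_identical(nrow(sol), 0L)
  env <- attr(sol, "envelope")
  expect_lt(env[["H_high"]], tg$H)  # model H always below the target
})
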