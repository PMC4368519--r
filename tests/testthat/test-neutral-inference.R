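test_that("likelihood matches hand-computed values at J <= 2", {
  # single individual: probability 1 for any parameters
  expect_equal(etienne_loglik(1, 7, 0.3), 0, tolerance = 1e-12)
  expect_equal(etienne_loglik(1, 0.1, 0.99), 0, tolerance = 1e-12)
  # J = 2, theta = 1, m = 0.5 (I = 1): brute-force urn enumeration gives
  # P(one species of 2) = 3/4, P(two singletons) = 1/4
  expect_equal(exp(etienne_loglik(2, 1, 0.5)), 0.75, tolerance = 1e-12)
  expect_equal(exp(etienne_loglik(c(1, 1), 1, 0.5)), 0.25, tolerance = 1e-12)
  expect_error(etienne_loglik(c(2, 1), -1, 0.5), "theta")
  expect_error(etienne_loglik(c(2, 1), 1, 1.2), "m")
})

partitions5 <- list(5, c(4, 1), c(3, 2), c(3, 1, 1), c(2, 2, 1),
                    c(2, 1, 1, 1), rep(1, 5))

test_that("likelihood equals the exhaustive two-stage enumeration at J = 5", {
  for (pars in list(c(2, 0.3), c(0.7, 0.9), c(10, 0.05))) {
    oracle <- exact_snm_probs(pars[1], pars[2], 5)
    for (p in partitions5) {
      key <- paste(sort(p, decreasing = TRUE), collapse = " ")
      expect_equal(exp(etienne_loglik(p, pars[1], pars[2])),
                   unname(oracle[key]), tolerance = 1e-10)
    }
    expect_lt(abs(sum(oracle) - 1), 1e-12)  # oracle itself normalizes
  }
})

test_that("m = 1 reduces to the Ewens sampling formula", {
  oracle <- exact_snm_probs(2.5, 1, 5)
  for (p in partitions5) {
    key <- paste(sort(p, decreasing = TRUE), collapse = " ")
    expect_equal(exp(etienne_loglik(p, 2.5, 1)), unname(oracle[key]),
                 tolerance = 1e-12)
  }
})

test_that("likelihood depends only on the abundance multiset", {
  ll <- etienne_loglik(c(5, 3, 1, 1), 4, 0.2)
  expect_identical(etienne_loglik(c(1, 3, 5, 1), 4, 0.2), ll)
  expect_identical(etienne_loglik(abundance_sample(c(3, 1, 5, 1)), 4, 0.2), ll)
  df <- data.frame(species = letters[1:4], count = c(5, 3, 1, 1))
  expect_identical(etienne_loglik(df, 4, 0.2), ll)
})

test_that("urn sampler agrees with the likelihood law", {
  # J = 1 is always one singleton
  set.seed(20)
  d1 <- urn_sample(3, 0.4, 1)
  expect_identical(d1$count, 1L)

  # J = 2: two-species fraction approaches 1/4
  set.seed(21)
  two <- replicate(2e4, nrow(urn_sample(1, 0.5, 2)) == 2)
  expect_lt(abs(mean(two) - 0.25), 3 * sqrt(0.25 * 0.75 / 2e4))

  # J = 5: full configuration frequencies match exp(log-likelihood)
  set.seed(22)
  keys <- vapply(partitions5, paste, character(1), collapse = " ")
  probs <- vapply(partitions5, function(p) exp(etienne_loglik(p, 2, 0.3)),
                  numeric(1))
  obs <- urn_partition_freqs(2, 0.3, 5, 3e4, keys)
  expect_gt(stats::chisq.test(as.numeric(obs), p = probs)$p.value, 0.01)
})

test_that("a hypergeometric subsample keeps the urn law when I is held fixed", {
  # I is a property of the community, not the sample: subsampling J' < J
  # individuals keeps I and maps m to m' = I/(I + J' - 1)
  theta <- 2; m <- 0.5; J <- 6; Jp <- 3
  I <- m * (J - 1) / (1 - m)
  mp <- I / (I + Jp - 1)
  oracle <- exact_snm_probs(theta, mp, Jp)

  set.seed(23)
  keys <- names(oracle)
  sub_keys <- vapply(seq_len(2e4), function(i) {
    d <- urn_sample(theta, m, J)
    ind <- rep.int(seq_len(nrow(d)), d$count)
    sub <- tabulate(sample(ind, Jp))
    paste(sort(sub[sub > 0], decreasing = TRUE), collapse = " ")
  }, character(1))
  obs <- table(factor(sub_keys, levels = keys))
  expect_gt(stats::chisq.test(as.numeric(obs), p = oracle)$p.value, 0.01)
})

test_that("the optimizer never reports less than its best start", {
  set.seed(24)
  d <- urn_sample(20, 0.2, 150)
  f <- fit_neutral(d)
  expect_gte(f$logL + 1e-9, max(f$starts$logL))
  expect_equal(f$logL, etienne_loglik(d, f$theta, f$m), tolerance = 1e-9)
  expect_lte(f$logL, 0)
})

test_that("maximum likelihood recovers urn parameters across replicates", {
  set.seed(25)
  fits <- t(replicate(100, {
    f <- fit_neutral(urn_sample(50, 0.1, 1000))
    c(f$theta, f$m)
  }))
  expect_lt(abs(stats::median(fits[, 1]) - 50), 10)       # within 20%
  expect_gt(stats::median(fits[, 2]), 0.05)               # within factor 2
  expect_lt(stats::median(fits[, 2]), 0.2)
})

test_that("a monodominant sample drives the fit to the boundary", {
  f <- fit_neutral(abundance_sample(400))
  expect_true(f$boundary)
  # the likelihood keeps increasing toward small m: the reported optimum is
  # at the small-m edge of the search region
  expect_lt(f$m, 1e-3)
})
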