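test_that("Jeffreys intervals match the Beta posterior quantiles", {
  # independent quantile oracle: invert the Beta CDF by root finding
  beta_q <- function(p, a, b) {
    stats::uniroot(function(x) stats::pbeta(x, a, b) - p, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  }
  ci <- jeffreys_interval(5, 100)
  expect_equal(ci$low, beta_q(0.025, 5.5, 95.5), tolerance = 1e-8)
  expect_equal(ci$high, beta_q(0.975, 5.5, 95.5), tolerance = 1e-8)

  # endpoint conventions
  expect_identical(jeffreys_interval(0, 50)$low, 0)
  expect_identical(jeffreys_interval(50, 50)$high, 1)

  # contains the point estimate; width shrinks with n at fixed x/n
  for (xn in list(c(3, 10), c(30, 100), c(300, 1000))) {
    ci <- jeffreys_interval(xn[1], xn[2])
    expect_true(ci$low <= ci$estimate && ci$estimate <= ci$high)
  }
  w <- function(x, n) { ci <- jeffreys_interval(x, n); ci$high - ci$low }
  expect_gt(w(3, 10), w(30, 100))
  expect_gt(w(30, 100), w(300, 1000))
  expect_error(jeffreys_interval(5, 3), "x")
})

test_that("power estimates are reproducible under a shared seed", {
  spec <- community_model("snm", J = 50, m = 0.3, theta = 10)
  set.seed(40)
  p1 <- estimate_power(spec, n_datasets = 5, u = 20)
  set.seed(40)
  p2 <- estimate_power(spec, n_datasets = 5, u = 20)
  expect_identical(tidy(p1), tidy(p2))
  expect_equal(p1$power, p1$n_rejected / p1$n_datasets)
  expect_true(p1$ci_low <= p1$power && p1$power <= p1$ci_high)
})

test_that("power_sweep runs a declarative grid and resumes from a checkpoint", {
  grid <- tibble::tibble(model = c("snm", "pc"),
                         meta = c("logseries", "even"),
                         J = c(40, 40), m = c(0.3, 0.3),
                         theta = c(8, NA), S_T = c(NA, 10),
                         c = c(NA, 0.5))
  ck <- withr::local_tempfile(fileext = ".tsv")
  set.seed(41)
  sw <- power_sweep(grid, n_datasets = 3, u = 10, checkpoint = ck)
  expect_s3_class(sw, "power_sweep")
  expect_identical(nrow(sw), 2L)
  expect_true(all(c("power", "ci_low", "ci_high", "x", "n") %in% names(sw)))
  # resume: with the checkpoint complete, no new computation happens and the
  # stored rows are returned unchanged
  sw2 <- power_sweep(grid, n_datasets = 3, u = 10, checkpoint = ck)
  expect_equal(sw2$power, sw$power)

  # invalid cells are rejected up front
  bad <- tibble::tibble(model = "hl", meta = "even", J = 40, m = 0.3,
                        gamma = 1.5, S_T = 10)
  expect_error(power_sweep(bad, n_datasets = 1, u = 5), "gamma")
})

test_that("tidiers return one-row tibbles for every result type", {
  set.seed(42)
  d <- urn_sample(5, 0.5, 40)
  f <- fit_neutral(d)
  expect_identical(nrow(tidy(f)), 1L)
  expect_identical(tidy(f), glance(f))
  tt <- neutrality_test(d, u = 10)
  expect_identical(nrow(tidy(tt)), 1L)
  expect_named(tidy(tt), c("p_value", "rejected", "alpha", "u", "theta", "m",
                           "logL", "n_failed"))
  pe <- estimate_power(community_model("snm", J = 30, m = 0.4, theta = 5),
                       n_datasets = 2, u = 10)
  expect_identical(nrow(tidy(pe)), 1L)
})
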