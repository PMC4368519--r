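test_that("logseries pool normalizes, is positive and reproducible", {
  set.seed(1)
  m1 <- meta_logseries(theta = 50, S_T = 2000)
  expect_equal(sum(m1$p), 1, tolerance = 1e-12)
  expect_true(all(m1$p > 0))
  expect_equal(nrow(m1), 2000)

  set.seed(1)
  m2 <- meta_logseries(theta = 50, S_T = 2000)
  expect_identical(m1$p, m2$p)

  # theta -> 0 concentrates essentially all mass on one species
  set.seed(2)
  tiny <- meta_logseries(theta = 1e-6, S_T = 2000)
  expect_gt(max(tiny$p), 0.99)

  expect_error(meta_logseries(-1, 100), "theta")
  expect_error(meta_logseries(10, 0), "S_T")
})

test_that("logseries ensemble species-frequency counts match the continuum density", {
  # mean number of species with relative abundance in (0.01, 0.1) at theta = 10
  theta <- 10
  dens <- function(x) theta / x * (1 - x)^(theta - 1)
  expected <- stats::integrate(dens, 0.01, 0.1)$value
  set.seed(42)
  counts <- replicate(40, {
    p <- meta_logseries(theta, S_T = 2000)$p
    sum(p > 0.01 & p < 0.1)
  })
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("even pool is exactly uniform and maximizes entropy", {
  m <- meta_even(100)
  expect_true(all(m$p == 1 / 100))
  expect_equal(nrow(meta_even(1)), 1)
  expect_equal(meta_even(1)$p, 1)
  p200 <- meta_even(200)$p
  expect_equal(-sum(p200 * log(p200)), log(200), tolerance = 1e-12)
  expect_error(meta_even(0), "S_T")
})

test_that("infinite even pool makes every immigrant a new species", {
  # with m = 1 every recruit is an immigrant, so each generation is all
  # fresh singletons
  set.seed(3)
  spec <- community_model("pc", meta = "infinite_even", J = 30, m = 1)
  d <- sim_community(spec)
  expect_equal(nrow(d), 30)
  expect_true(all(d$count == 1))

  # under weak immigration, the species-label counter keeps advancing:
  # labels observed late in a run exceed the initial J labels
  set.seed(4)
  spec2 <- community_model("pc", meta = "infinite_even", J = 50, m = 0.3)
  d2 <- sim_community(spec2)
  expect_gt(max(d2$species), 50)
})

test_that("metacommunity tables round-trip through TSV", {
  set.seed(5)
  m <- meta_logseries(20, 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metacommunity(m, path)
  m2 <- read_metacommunity(path)
  expect_equal(m2$p, m$p, tolerance = 1e-14)
  expect_equal(attr(m2, "kind"), "logseries")
  expect_equal(attr(m2, "theta"), 20)

  write_metacommunity(meta_infinite(), path)
  expect_equal(attr(read_metacommunity(path), "kind"), "infinite_even")
})
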