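# Storey pi0/pi1 estimation and the replication true-positive rate.

test_that("pi1 hits the limits: all-alternative and pure-null collections", {
  expect_gte(estimate_pi0(rep(1e-9, 1000))$pi1, 0.99)
  expect_lte(estimate_pi0((1:1000) / 1000)$pi1, 0.02)
  expect_error(estimate_pi0(numeric(0)), "empty")
  expect_error(estimate_pi0(c(0.5, 0)), "0, 1")
  expect_error(estimate_pi0(c(0.5, 1.2)), "0, 1")
})

test_that("a 70/30 uniform-alternative mixture is recovered", {
  set.seed(11)
  z <- abs(rnorm(3000, 3, 1))
  p <- c(runif(7000), 2 * pnorm(-z))
  est <- estimate_pi0(p)
  expect_gte(est$pi1, 0.25)
  expect_lte(est$pi1, 0.35)
  expect_identical(est$n_pvalues, 10000L)
})

test_that("pi1 is monotone in the alternative fraction and unbiased under the null", {
  set.seed(12)
  pi1_at <- vapply(c(0.6, 0.3, 0.1, 0), function(frac) {
    m <- 4000
    m1 <- round(m * frac)
    p <- c(runif(m - m1), 2 * pnorm(-abs(rnorm(m1, 3, 1))))
    estimate_pi0(p)$pi1
  }, 0)
  expect_true(all(diff(pi1_at) <= 0.02))  # nonincreasing up to noise

  null_pi1 <- vapply(seq_len(50), function(i) {
    set.seed(100 + i)
    estimate_pi0(runif(10000))$pi1
  }, 0)
  expect_lte(abs(mean(null_pi1)), 0.02)
})

test_that("small collections fall back to the fixed-lambda estimator", {
  set.seed(13)
  est <- estimate_pi0(runif(40))
  expect_match(est$method, "fixed")
  expect_equal(est$lambda_used, 0.5)
  expect_equal(est$pi0 + est$pi1, 1)
})

test_that("replication pi1 restricts to discovery-passing shared units", {
  set.seed(14)
  m <- 4000
  units <- paste0("u", seq_len(m))
  strong <- seq_len(2000)
  disc <- tibble::tibble(
    unit = units,
    fdr = ifelse(seq_len(m) %in% strong, 0.001, 0.5)
  )
  # self-replication: the same signal replicates
  repl_same <- tibble::tibble(unit = units,
                              p_value = ifelse(seq_len(m) %in% strong,
                                               runif(m, 1e-12, 1e-6), runif(m)))
  est <- replication_pi1(disc, repl_same, 0.05)
  expect_gte(est$pi1, 0.95)
  expect_identical(est$n_overlap, 2000L)

  # broken replication: permuted phenotypes give uniform p-values
  repl_null <- tibble::tibble(unit = units, p_value = runif(m))
  expect_lte(replication_pi1(disc, repl_null, 0.05)$pi1, 0.05)

  # no overlap
  repl_other <- tibble::tibble(unit = paste0("x", 1:10), p_value = runif(10))
  expect_error(replication_pi1(disc, repl_other, 0.05), "no shared units")
})
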