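test_that("log-likelihood evaluates the stated generative model", {
  # point mass: adduct always at L, no drop-off -> probability 1
  m <- dropoff_model(theta = c(0, 0, 1), gamma = rep(0, 3), p_mod = 1)
  expect_equal(dropoff_loglik(m, plus = c(0, 0, 0, 5), minus = c(5, 0, 0, 0)),
               0)
  # no modification and no drop-off: any (+) stop at k >= 1 is impossible
  m0 <- dropoff_model(theta = rep(1 / 3, 3), gamma = rep(0, 3), p_mod = 0)
  ll <- dropoff_loglik(m0, plus = c(0, 1, 0, 0), minus = c(1, 0, 0, 0))
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "impossible")$channel, "plus")
  expect_equal(attr(ll, "impossible")$index, 1L)
  # direct evaluation: one (-) read at k = 2 with gamma = (0.1, 0.2, 0.1)
  m1 <- dropoff_model(theta = c(0.2, 0.3, 0.5), gamma = c(0.1, 0.2, 0.1),
                      p_mod = 0.5)
  expect_equal(dropoff_loglik(m1, plus = rep(0, 4), minus = c(0, 0, 1, 0)),
               log(0.18))
})

test_that("model stop probabilities agree with enumeration and sum to 1", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      L <- sample(2:6, 1)
      theta <- as.numeric(rgamma(L, 1)); theta <- theta / sum(theta)
      gamma <- runif(L, 0, 0.3)
      p <- runif(1)
      m <- dropoff_model(theta, gamma, p)
      pr <- shapeseqr:::dropoff_stop_probs(m)
      orc <- oracle_stop_probs(theta, gamma, p)
      expect_equal(pr$plus, orc$plus, tolerance = 1e-12)
      expect_equal(pr$minus, orc$minus, tolerance = 1e-12)
      expect_equal(sum(pr$plus), 1, tolerance = 1e-12)
      expect_equal(sum(pr$minus), 1, tolerance = 1e-12)
    }
  })
})

test_that("equal channels carry no modification signal (degenerate profile)", {
  cnt <- tibble::tibble(index = 0:3, plus_count = c(50, 10, 20, 5),
                        minus_count = c(50, 10, 20, 5))
  p <- estimate_theta(cnt, exclude_3prime = FALSE)
  expect_true(p$degenerate)
  expect_equal(p$data$theta, rep(0, 3))
  expect_error(theta_to_rho(p), "degenerate")
})

test_that("small two-position instance matches the numeric likelihood oracle", {
  # frozen from the oracle: grid + optim maximization of the stated
  # likelihood with gamma profiled from the (-) channel gives (0.4, 0.6)
  # and p_mod 5/9
  cnt <- tibble::tibble(index = 0:2, plus_count = c(40, 20, 40),
                        minus_count = c(90, 0, 10))
  p <- estimate_theta(cnt, exclude_3prime = FALSE)
  expect_equal(p$data$theta, c(0.4, 0.6), tolerance = 1e-12)
  expect_equal(p$p_mod_hat, 5 / 9, tolerance = 1e-12)
  expect_equal(p$data$beta, c(0, 0.1))
  expect_equal(p$data$alpha, c(1 / 3, 0.4))
  expect_equal(p$data$r_raw, c(1 / 3, 1 / 3), tolerance = 1e-12)
  # and the oracle agrees at run time
  th <- oracle_mle_theta(cnt$plus_count, cnt$minus_count)
  expect_equal(p$data$theta, th, tolerance = 1e-3)
})

test_that("closed-form estimate maximizes the likelihood on random instances", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      cnt <- random_count_instance(sample(2:4, 1))
      est <- estimate_theta(cnt, exclude_3prime = FALSE)
      if (est$degenerate) next
      orc <- oracle_mle_theta(cnt$plus_count, cnt$minus_count)
      expect_equal(est$data$theta, orc, tolerance = 1e-3)
    }
  })
})

test_that("theta normalization holds on every non-degenerate call", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      L <- sample(2:30, 1)
      cnt <- tibble::tibble(
        index = 0:L,
        plus_count = as.integer(rpois(L + 1, 8)),
        minus_count = as.integer(rpois(L + 1, 6))
      )
      cnt$plus_count[1] <- cnt$plus_count[1] + 5L
      cnt$minus_count[1] <- cnt$minus_count[1] + 5L
      p <- estimate_theta(cnt)
      if (p$degenerate) {
        expect_equal(p$data$theta, rep(0, L))
      } else {
        expect_equal(sum(p$data$theta[p$data$scored]), 1, tolerance = 1e-9)
        expect_true(all(p$data$theta >= 0))
      }
    }
  })
})

test_that("estimates are invariant to integer scaling of both channels", {
  withr::with_seed(41, {
    cnt <- random_count_instance(4)
  })
  a <- estimate_theta(cnt, exclude_3prime = FALSE)
  cnt2 <- dplyr::mutate(cnt, plus_count = plus_count * 7L,
                        minus_count = minus_count * 7L)
  b <- estimate_theta(cnt2, exclude_3prime = FALSE)
  expect_identical(a$data$theta, b$data$theta)
})

test_that("more (+) stops at a position cannot lower its raw weight", {
  withr::with_seed(51, {
    cnt <- random_count_instance(4)
  })
  raw_weight <- function(cnt, k) {
    d <- tidy(estimate_theta(cnt, exclude_3prime = FALSE))
    r <- d$r_clamped
    r[k] * prod(1 - r[d$index > k])
  }
  for (k in 1:4) {
    bumped <- cnt
    bumped$plus_count[k + 1] <- bumped$plus_count[k + 1] + 10L
    expect_gte(raw_weight(bumped, k), raw_weight(cnt, k) - 1e-12)
  }
})

test_that("positions never reached in a channel are flagged, not imputed", {
  # (+) channel has no molecules reaching position 1
  cnt <- tibble::tibble(index = 0:3, plus_count = c(0, 0, 10, 10),
                        minus_count = c(20, 2, 2, 2))
  p <- estimate_theta(cnt, exclude_3prime = FALSE)
  d <- tidy(p)
  expect_equal(d$flag[1], "unestimable")
  expect_equal(d$theta[1], 0)
  expect_true(is.na(d$alpha[1]))
  expect_equal(sum(d$theta), 1, tolerance = 1e-9)
  # a control channel that saturates (beta = 1) is flagged and excluded
  cnt2 <- tibble::tibble(index = 0:2, plus_count = c(10, 5, 10),
                         minus_count = c(0, 5, 10))
  d2 <- tidy(estimate_theta(cnt2, exclude_3prime = FALSE))
  expect_true("saturated_control" %in% d2$flag)
})

test_that("3'-terminal exclusion shortens the scored range by one", {
  withr::with_seed(61, {
    cnt <- random_count_instance(5)
  })
  incl <- estimate_theta(cnt, exclude_3prime = FALSE)
  excl <- estimate_theta(cnt, exclude_3prime = TRUE)
  expect_equal(incl$scored, 1:5)
  expect_equal(excl$scored, 1:4)
  expect_equal(sum(excl$data$theta[1:4]), 1, tolerance = 1e-9)
  expect_equal(excl$data$theta[5], 0)
})

test_that("profile accessors and table round-trip behave", {
  tg <- demo_target(L = 12, seed = 8)
  sim <- simulate_stop_counts(sim_params(tg, n_plus = 5000, n_minus = 5000,
                                         seed = 3))
  p <- estimate_theta(sim$counts, target = tg)
  expect_s3_class(tidy(p), "tbl_df")
  g <- glance(p)
  expect_equal(g$L, 12L)
  expect_equal(g$n_scored, 11L)
  expect_false(g$degenerate)
  expect_s3_class(autoplot(p), "ggplot")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reactivity(p, f)
  back <- read_reactivity(f)
  expect_equal(back$theta, p$data$theta, tolerance = 1e-12)
  expect_equal(back$nucleotide, p$data$nucleotide)
})
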