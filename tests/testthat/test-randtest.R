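# Small parameter set used for toy instances throughout this file; the
# high-peak cap leaves the low search room on every input, so the toy null
# has no degenerate atom at zero
toy_params <- function() list(Cz = peak_params(0, 200, 40, high_limit = 120))

test_that("per-resample p-values are rank-based with strict inequality", {
  expect_equal(as.vector(per_resample_pvalues(cbind(c(1, 2, 3, 4)))),
               c(3, 2, 1, 0) / 4)
  # all-equal column: nothing is strictly greater
  expect_equal(as.vector(per_resample_pvalues(cbind(rep(5, 6)))), rep(0, 6))
  # distinct values: p-values are a permutation of {0, ..., (B-1)/B}
  set.seed(12)
  x <- rnorm(40)
  expect_setequal(as.vector(per_resample_pvalues(cbind(x))), (0:39) / 40)
  # columns are ranked independently
  P <- per_resample_pvalues(cbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(P[, 1], c(2, 1, 0) / 3)
  expect_equal(P[, 2], c(0, 1, 2) / 3)
})

test_that("Fisher scores follow -2*sum(log p) with 1/B zero replacement", {
  expect_equal(fisher_score(c(1, 1, 1)), 0)
  expect_equal(fisher_score(c(0.05, 0.05, 0.05)), -6 * log(0.05))
  expect_equal(fisher_score(c(0.05, 0.05, 0.05)), 17.9744, tolerance = 1e-4)
  # exact zeros become the smallest legitimate p-value 1/B
  expect_equal(fisher_score(c(0, 0, 0), B = 1000), -6 * log(0.001))
  expect_equal(fisher_score(c(0, 0, 0), B = 1000), 41.4465, tolerance = 1e-4)
  expect_equal(fisher_score(c(0, 0.5), B = 200), -2 * (log(1 / 200) + log(0.5)))
  expect_error(fisher_score(c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(fisher_score(c(1.1)), "\\[0, 1\\]")
})

test_that("combined p locates the observed Fisher score in the null", {
  fl <- structure(list(null_matrix = cbind(Cz = c(1, 2, 3, 4)),
                       p_per_channel = c(Cz = 0.5), B = 4,
                       channels = "Cz"), class = "first_level")
  cmb <- combined_p(fl)
  # null p's are {3/4, 2/4, 1/4, 0->1/4 replaced? no: 0 stays 0 then ->1/B}
  expect_equal(sort(cmb$fisher_null),
               sort(-2 * log(c(3 / 4, 2 / 4, 1 / 4, 1 / 4))))
  expect_equal(cmb$fisher_observed, -2 * log(0.5))
  expect_equal(cmb$fisher_p, mean(cmb$fisher_null > -2 * log(0.5)))

  # hand count: null scores {1,2,3,4}, observed 2.5 -> p = 0.5
  expect_equal(mean(c(1, 2, 3, 4) > 2.5), 0.5)
})

test_that("an injected noiseless component drives every p to the floor", {
  times_n <- 24
  probe <- const_array(6, 1, times_n, 0)
  probe[, 1, 9:12] <- 8   # strong square deflection at 80-120 ms
  probe[, 1, 17:20] <- -6
  irrel <- const_array(6, 1, times_n, 0)
  # tiny per-trial perturbation so surrogate groups differ
  set.seed(2)
  probe <- probe + noise_array(6, 1, times_n, 0.01)
  irrel <- irrel + noise_array(6, 1, times_n, 0.01)
  es <- make_es(list(Probe = probe, Irrelevant1 = irrel), "Cz",
                fs = 100, start = 0, end = 240)
  fl <- first_level(es, es, "Probe", "Irrelevant1", B = 100, channels = "Cz",
                    params = list(Cz = peak_params(0, 240, 40)))
  expect_equal(unname(fl$p_per_channel), 0)
  expect_equal(fl$m, 6)
})

test_that("randomisation p matches the exhaustive-permutation oracle", {
  # 3 + 3 trials: the null over all C(6,3) = 20 equal-size splits is exact.
  # The identity relabelling reproduces the observed statistic exactly, and
  # at floating-point resolution that tie may be counted on either side of
  # the strict inequality, so the exact p is a [ties-out, ties-in] band.
  set.seed(91)
  n_samp <- 20
  probe <- noise_array(3, 1, n_samp, 3); probe[, 1, 5:9] <- probe[, 1, 5:9] + 2
  irrel <- noise_array(3, 1, n_samp, 3)
  es <- make_es(list(Probe = probe, Irrelevant1 = irrel), "Cz",
                fs = 100, start = 0, end = 200)
  prm <- toy_params()

  # oracle: enumerate every split of the 6 pooled trials into two 3-sets
  pool <- rbind(matrix(probe, 3), matrix(irrel, 3))
  times <- es$times
  obs_dw <- colMeans(pool[1:3, ]) - colMeans(pool[4:6, ])
  obs <- p2p_oracle(obs_dw, times, 0, 200, 40, high_limit = 120)$p2p
  combs <- utils::combn(6, 3)
  null_stats <- apply(combs, 2, function(g1) {
    d <- colMeans(pool[g1, , drop = FALSE]) -
      colMeans(pool[setdiff(1:6, g1), , drop = FALSE])
    p2p_oracle(d, times, 0, 200, 40, high_limit = 120)$p2p
  })
  tol <- 1e-9
  p_lo <- mean(null_stats > obs + tol)
  p_hi <- mean(null_stats >= obs - tol)

  B <- 10000
  fl <- first_level(es, es, "Probe", "Irrelevant1", B = B,
                    channels = "Cz", params = prm)
  expect_equal(unname(fl$observed["Cz"]), obs)
  p_hat <- unname(fl$p_per_channel)
  expect_gte(p_hat, p_lo - 3 * sqrt(p_lo * (1 - p_lo) / B) - 1e-12)
  expect_lte(p_hat, p_hi + 3 * sqrt(p_hi * (1 - p_hi) / B) + 1e-12)
  # the resampled null reproduces the exact 20-point distribution
  expect_setequal(round(unique(as.vector(fl$null_matrix)), 6),
                  round(unique(null_stats), 6))
})

test_that("null first-level p-values are calibrated near 0.5", {
  set.seed(14)
  prm <- toy_params()
  ps <- replicate(400, {
    es <- make_es(list(Probe = noise_array(8, 1, 20, 2),
                       Irrelevant1 = noise_array(8, 1, 20, 2)),
                  "Cz", fs = 100, start = 0, end = 200)
    unname(first_level(es, es, "Probe", "Irrelevant1", B = 40,
                       channels = "Cz", params = prm)$p_per_channel)
  })
  # strict ">" counting biases E[p] down by about 1/(2B)
  expect_gt(mean(ps), 0.5 - 0.05)
  expect_lt(mean(ps), 0.5 + 0.05)
})

test_that("single-channel Fisher p agrees with the first-level p within 1/B", {
  set.seed(15)
  es <- make_es(list(Probe = noise_array(10, 1, 20, 2),
                     Irrelevant1 = noise_array(10, 1, 20, 2)),
                "Cz", fs = 100, start = 0, end = 200)
  fl <- first_level(es, es, "Probe", "Irrelevant1", B = 200,
                    channels = "Cz", params = toy_params())
  cmb <- combined_p(fl)
  # Fisher is monotone in a single p, so the combined rank reproduces it
  expect_lt(abs(cmb$fisher_p - unname(fl$p_per_channel)), 1 / 200 + 1e-12)
})

test_that("channel order does not change the combined p under a fixed seed", {
  cfg <- synth_profile("guilty", trials_per_condition = 15, seed = 77)
  es <- simulate_subject(cfg)
  d1 <- cit_detect(es, B = 100, channels = c("Fz", "Cz", "Pz"), seed = 5)
  d2 <- cit_detect(es, B = 100, channels = c("Pz", "Fz", "Cz"), seed = 5)
  expect_equal(d1$fisher_p, d2$fisher_p)
  expect_equal(d1$p_per_channel[c("Fz", "Cz", "Pz")],
               d2$p_per_channel[c("Fz", "Cz", "Pz")])
})

test_that("monotonicity: a larger observed statistic never raises its p", {
  set.seed(16)
  null_col <- rnorm(100)
  obs <- seq(-3, 3, length.out = 25)
  p <- vapply(obs, function(o) mean(null_col > o), numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("detection reports are reproducible under a fixed seed", {
  cfg <- synth_profile("guilty", trials_per_condition = 10, seed = 31)
  es <- simulate_subject(cfg)
  d1 <- cit_detect(es, B = 50, seed = 99)
  d2 <- cit_detect(es, B = 50, seed = 99)
  p1 <- tempfile(); p2 <- tempfile()
  write_report(d1, p1); write_report(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
  # decision contract
  expect_identical(d1$decision, d1$fisher_p < d1$alpha)
})

test_that("Fisher's gain over p-averaging shrinks as dimensions correlate", {
  # two correlated test statistics with a genuine shift: as the correlation
  # rises the two p-values carry the same information and combining helps less
  set.seed(17)
  adv <- vapply(c(0, 0.4, 0.8), function(rho) {
    n <- 4000
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    p1 <- stats::pnorm(z1 + 1.8, lower.tail = FALSE)
    p2 <- stats::pnorm(z2 + 1.8, lower.tail = FALSE)
    fisher_p <- stats::pchisq(-2 * (log(p1) + log(p2)), df = 4,
                              lower.tail = FALSE)
    mean((p1 + p2) / 2 - fisher_p)
  }, numeric(1))
  expect_true(all(diff(adv) < 0))
  expect_true(all(adv > 0))
})
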