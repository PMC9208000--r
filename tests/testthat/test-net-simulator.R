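# Generative simulation: moments, presence/strength draws, network assembly,
# and observed-vs-simulated summaries.

test_that("simulation moments reduce correctly in degenerate settings", {
  d <- tiny_design()
  spec <- attr(d, "model_spec")
  mats <- dynetmm:::.build_matrices(d, spec)
  zero <- stats::setNames(rep(0, ncol(mats$X)), colnames(mats$X))
  par0 <- list(coef = zero, tau_b = c(b_intercept = 0),
               tau_d = c(d_s1 = 0, d_s2 = 0), sigma2 = 0.04)
  mom <- compute_moments(par0, par0, d)
  expect_true(all(mom$p == 0.5))              # logistic(0)
  expect_true(all(mom$mu_sim == 0))
  expect_true(all(mom$sigma2_sim == 0.04))    # zero variance components
  # hand-built linear predictor on one row
  par1 <- par0
  par1$coef[c("(Intercept)", "Q", "coi")] <- c(0.2, -0.5, 0.1)
  par1$tau_b <- c(b_intercept = 0.09)
  mom1 <- compute_moments(par1, par1, d)
  i <- 17L
  eta <- 0.2 - 0.5 * d$Q[i] + 0.1 * d$coi[i]
  expect_equal(mom1$mu_sim[i], eta, tolerance = 1e-12)
  expect_equal(mom1$p[i], stats::plogis(eta), tolerance = 1e-12)
  expect_equal(mom1$sigma2_sim[i], 0.04 + 0.09, tolerance = 1e-12)
})

test_that("presence draws are calibrated and reproducible", {
  mom <- data.frame(p = rep(0.3, 500))
  R_draws <- 2000L
  freq <- rowMeans(vapply(seq_len(R_draws),
                          function(k) simulate_presence(mom, seed = k),
                          integer(500)))
  bound <- 3 * sqrt(0.3 * 0.7 / R_draws)
  expect_gte(mean(abs(freq - 0.3) < bound), 0.99)
  expect_identical(simulate_presence(mom, seed = 99),
                   simulate_presence(mom, seed = 99))
  edge <- data.frame(p = rep(1 - 1e-13, 100))
  expect_true(all(simulate_presence(edge, seed = 1) == 1L))
})

test_that("strength draws are masked, truncated, and mean-calibrated", {
  mom <- data.frame(p = 0.5, mu_sim = rep(0.4, 10000),
                    sigma2_sim = rep(0.04, 10000))
  none <- simulate_strength(mom, presence = rep(0L, 10000), seed = 1)
  expect_true(all(none == 0))
  all_present <- rep(1L, 10000)
  w <- simulate_strength(mom, all_present, seed = 2)
  expect_true(all(w >= 0 & w < 1))
  # calibration on the untruncated scale (truncation biases retained draws)
  w_raw <- simulate_strength(mom, all_present, seed = 2,
                             truncate_negative = FALSE)
  z <- atanh(w_raw)
  expect_lt(abs(mean(z) - 0.4), 3 * 0.2 / sqrt(10000))
  expect_lt(abs(stats::var(z) - 0.04), 3 * 0.04 * sqrt(2 / 10000))
  # degenerate variance: weight = tanh(mu) exactly
  mom0 <- data.frame(p = 0.5, mu_sim = 0.3, sigma2_sim = 1e-24)
  expect_equal(simulate_strength(mom0, 1L, seed = 3), tanh(0.3),
               tolerance = 1e-8, ignore_attr = TRUE)
  # negative draws on present edges are truncated and the rate reported
  momn <- data.frame(p = 0.5, mu_sim = rep(-0.5, 5000),
                     sigma2_sim = rep(0.01, 5000))
  wn <- simulate_strength(momn, rep(1L, 5000), seed = 4)
  expect_true(all(wn == 0 | wn > 0))
  expect_gt(attr(wn, "truncation_rate"), 0.99)
  wkeep <- simulate_strength(momn, rep(1L, 5000), seed = 4,
                             truncate_negative = FALSE)
  expect_lt(min(wkeep), 0)
})

test_that("simulated network sets have the declared size and structure", {
  gt <- tiny_ground_truth()
  d <- tiny_design()
  par <- ground_truth_params(gt)
  sims <- simulate_dynamic_networks(par, d,
                                    participants = unique(d$participant)[1:3],
                                    windows = 1:2, n_realizations = 4,
                                    seed = 21)
  expect_length(sims$networks, 3L * 2L * 4L)
  for (nn in sims$networks[c(1L, 9L, 24L)]) {
    M <- nn$matrix
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 0))
    expect_true(all(M >= 0 & M < 1))
  }
  # fixed seed: bit-identical output
  sims2 <- simulate_dynamic_networks(par, d,
                                     participants = unique(d$participant)[1:3],
                                     windows = 1:2, n_realizations = 4,
                                     seed = 21)
  expect_identical(sims, sims2)
  # single smallest case
  one <- simulate_dynamic_networks(par, d,
                                   participants = unique(d$participant)[1L],
                                   windows = 1L, n_realizations = 1,
                                   seed = 5)
  expect_length(one$networks, 1L)
  expect_error(simulate_dynamic_networks(par, d, participants = "nope"),
               "unknown participant")
  expect_error(simulate_dynamic_networks(par, d, windows = 99L),
               "unknown window")
})

test_that("network summaries degenerate correctly", {
  M <- random_weight_matrix(6, seed = 2)
  s <- summarize_networks(list(M, M, M))
  expect_equal(s$sd, rep(0, 3))
  expect_equal(s$metric, c("C", "Eglob", "K"))
  empty <- matrix(0, 5, 5)
  s0 <- summarize_networks(list(empty, empty))
  expect_equal(s0$mean, rep(0, 3))
  expect_error(summarize_networks(list()), "empty")
})
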