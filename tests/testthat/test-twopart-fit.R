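# Estimation machinery: weighted REML core, restricted pseudo-likelihood,
# Wald F inference, adaptive FDR, GOF, degree selection.

test_that("REML core equals the balanced one-way ANOVA closed form", {
  withr::with_seed(42, {
    m <- 30L; r <- 8L
    g <- factor(rep(seq_len(m), each = r))
    b <- rnorm(m, 0, sqrt(0.5))
    y <- 2 + b[as.integer(g)] + rnorm(m * r)
  })
  X <- matrix(1, m * r, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_weighted_lmm(y, X, random = list(b0 = rep(1, m * r)), group = g)
  gm <- tapply(y, g, mean)
  MSB <- r * sum((gm - mean(y))^2) / (m - 1)
  MSW <- sum((y - gm[as.integer(g)])^2) / (m * (r - 1))
  expect_equal(unname(fit$varcomp["b0"]), (MSB - MSW) / r, tolerance = 1e-8)
  expect_equal(unname(fit$varcomp["sigma2"]), MSW, tolerance = 1e-8)
  expect_equal(unname(fit$beta), mean(y), tolerance = 1e-10)
})

test_that("REML core agrees with lme4 on an unbalanced weighted problem", {
  withr::with_seed(9, {
    n <- 600L
    g <- factor(rep(1:20, each = 30))
    x1 <- rnorm(n); zs <- rnorm(n)
    y <- 1 + 0.5 * x1 + rnorm(20, 0, 0.7)[g] + rnorm(20, 0, 0.4)[g] * zs +
      rnorm(n)
    w <- runif(n, 0.5, 2)
  })
  X <- cbind(`(Intercept)` = 1, x1 = x1)
  fit <- fit_weighted_lmm(y, X, random = list(b0 = rep(1, n), b1 = zs),
                          group = g, weights = w)
  ref <- lme4::lmer(y ~ x1 + (1 | g) + (0 + zs | g), weights = w,
                    REML = TRUE,
                    data = data.frame(y, x1, zs, g, w))
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("zero random variance collapses to weighted least squares", {
  withr::with_seed(1, {
    n <- 200L
    g <- factor(rep(1:10, each = 20))
    x <- rnorm(n)
  })
  X <- cbind(`(Intercept)` = 1, x = x)
  y <- as.vector(X %*% c(2, -1)) + withr::with_seed(2, rnorm(n))
  fit <- fit_weighted_lmm(y, X, random = list(b0 = rep(1, n)), group = g)
  ols <- stats::lm.fit(X, y)$coefficients
  expect_equal(unname(fit$varcomp["b0"]), 0)
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-8)
  # noiseless response: exact beta, all variance at the boundary
  y0 <- as.vector(X %*% c(2, -1))
  fit0 <- fit_weighted_lmm(y0, X, random = list(b0 = rep(1, n)), group = g)
  expect_equal(unname(fit0$beta), c(2, -1), tolerance = 1e-10)
  expect_equal(unname(fit0$varcomp["b0"]), 0)
})

test_that("REML core recovers known variance components in simulation", {
  withr::with_seed(12, {
    m <- 80L; r <- 15L
    g <- factor(rep(seq_len(m), each = r))
    x <- rnorm(m * r)
    y <- 1 + 0.4 * x + rnorm(m, 0, sqrt(0.5))[g] + rnorm(m * r, 0, 1)
  })
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_weighted_lmm(y, X, random = list(b0 = rep(1, m * r)), group = g)
  # MC SE of tau-hat for balanced design ~ sqrt(2/m)*(tau + s2/r)
  expect_lt(abs(fit$varcomp["b0"] - 0.5), 3 * sqrt(2 / m) * (0.5 + 1 / r))
  expect_lt(abs(fit$varcomp["sigma2"] - 1), 3 * sqrt(2 / (m * (r - 1))))
})

test_that("singular fixed-effect designs are rejected with the column named", {
  X <- cbind(`(Intercept)` = 1, a = 1:10, dup = 1:10)
  expect_error(fit_weighted_lmm(rnorm(10), X), "dup")
})

test_that("presence RPL without random effects equals the logistic MLE", {
  d <- tiny_design()
  spec0 <- attr(d, "model_spec")
  spec0$random_terms <- character(0)
  spec0$include_poly_random <- FALSE
  fit <- fit_presence_model(d, spec0)
  mats <- dynetmm:::.build_matrices(d, spec0)
  ref <- suppressWarnings(
    stats::glm.fit(mats$X, d$R, family = stats::binomial()))
  expect_equal(unname(fit$coef_all), unname(ref$coefficients),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("presence model rejects degenerate responses", {
  d <- tiny_design()
  d$R <- 1L
  expect_error(fit_presence_model(d), "degenerate")
})

test_that("strength fit is exact in the noiseless zero-variance limit", {
  d <- tiny_design()
  spec <- attr(d, "model_spec")
  mats <- dynetmm:::.build_matrices(d, spec)
  truth <- withr::with_seed(3, rnorm(ncol(mats$X), 0, 0.1))
  d$R <- 1L
  d$S <- as.vector(mats$X %*% truth)
  d$Y <- tanh(d$S)
  fit <- fit_strength_model(d, spec)
  expect_equal(unname(fit$coef_all), truth, tolerance = 1e-10)
  expect_equal(unname(fit$varcomp$tau_b), 0)
  expect_lt(fit$varcomp$sigma2, 1e-16)
})

test_that("dropping polynomial columns reproduces a static fit on time-constant data", {
  d <- tiny_design()
  spec0 <- attr(d, "model_spec")
  spec0$poly_degree <- 0L
  spec0$include_poly_random <- FALSE
  spec0$random_terms <- character(0)
  # replicate window 1 across all windows: data carry no temporal signal
  d1 <- d[d$window == 1L, ]
  dd <- do.call(rbind, lapply(1:3, function(w) { x <- d1; x$window <- w; x }))
  dd$s1 <- NULL; dd$s2 <- NULL
  attr(dd, "model_spec") <- spec0
  fit_dyn <- fit_strength_model(dd, spec0)
  fit_static <- fit_strength_model(d1[, setdiff(names(d1), c("s1", "s2"))],
                                   spec0)
  expect_equal(fit_dyn$coef_all, fit_static$coef_all, tolerance = 1e-8)
})

test_that("Wald F equals squared t for single contrasts and guards rank", {
  d <- tiny_design()
  fit <- fit_strength_model(d)
  k <- which(names(fit$coef_all) == "Q")
  L <- rep(0, length(fit$coef_all)); L[k] <- 1
  res <- wald_f_test(fit, L)
  tval <- fit$coef_all[k] / sqrt(diag(fit$cov_all))[k]
  expect_equal(res$F, unname(tval^2), tolerance = 1e-10)
  expect_equal(res$df_num, 1L)
  expect_equal(res$df_den, fit$n_obs - fit$rank_X)
  expect_equal(res$p, 2 * stats::pt(-abs(tval), res$df_den),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(wald_f_test(fit, rep(0, length(fit$coef_all))), "rank 0")
})

test_that("joint contrast on true-null parameters gives small F", {
  d <- tiny_design()
  spec <- attr(d, "model_spec")
  mats <- dynetmm:::.build_matrices(d, spec)
  truth <- stats::setNames(rep(0, ncol(mats$X)), colnames(mats$X))
  truth["(Intercept)"] <- 0.4
  d$R <- 1L
  d$S <- as.vector(mats$X %*% truth)
  fit <- fit_strength_model(d, spec)
  L <- matrix(0, 2, length(fit$coef_all))
  L[1, which(names(fit$coef_all) == "coi")] <- 1
  L[2, which(names(fit$coef_all) == "coi_x_Q")] <- 1
  res <- wald_f_test(fit, L)
  expect_lt(res$F, 1e-6)
  expect_gt(res$p, 0.999)
})

test_that("adaptive FDR behaves like BH when m0 = m and stays in [0,1]", {
  expect_equal(adaptive_fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.01, 0.02, 0.03, 0.04)
  # increasing slopes here, so m0 = m and the result is plain BH
  expect_identical(estimate_m0_lsl(p), 4L)
  expect_equal(adaptive_fdr_adjust(p), stats::p.adjust(p, "BH"))
  withr::with_seed(5, p2 <- runif(40)^2)
  adj <- adaptive_fdr_adjust(p2)
  expect_true(all(adj >= 0 & adj <= 1))
  # permutation equivariance
  perm <- withr::with_seed(6, sample(40))
  expect_equal(adaptive_fdr_adjust(p2[perm]), adj[perm])
  expect_identical(adaptive_fdr_adjust(numeric(0)), numeric(0))
  # hand-evaluated lowest-slope example: slopes rise through rank 10
  # (0.05 ... 0.0909), first fall at rank 11 where s = 0.8/10 = 0.08,
  # so m0 = floor(1/0.08) + 1 = 13
  p3 <- c(rep(1e-4, 10), 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.85, 0.9, 0.95,
          0.99)
  expect_identical(estimate_m0_lsl(p3), 13L)
  expect_true(all(adaptive_fdr_adjust(p3) <=
                    stats::p.adjust(p3, "BH") + 1e-12))
})

test_that("GOF formulas match hand arithmetic and penalize parameters", {
  f <- list(loglik = -100, n_params = 5, n_obs = 100)
  g <- gof_measures(f)
  expect_equal(unname(g["AIC"]), 210)
  expect_equal(unname(g["BIC"]), 223.0259, tolerance = 1e-4)
  expect_equal(unname(g["AICc"]), 210.6383, tolerance = 1e-4)
  expect_equal(unname(g["HQIC"]), 215.2718, tolerance = 1e-4)
  expect_equal(unname(g["CAIC"]), 228.0259, tolerance = 1e-4)
  g2 <- gof_measures(list(loglik = -100, n_params = 7, n_obs = 100))
  expect_true(all(g2 > g, na.rm = TRUE))
  expect_true(is.na(gof_measures(list(loglik = -1, n_params = 10,
                                      n_obs = 11))["AICc"]))
})

test_that("degree selection enumerates the grid and picks the stable run", {
  expect_length(degree_grid(3, 18), 16L)
  d <- tiny_design()
  sel <- degree_selection(d, degrees = degree_grid(1, 3))
  expect_equal(sort(unique(sel$gof$degree)), 1:3)
  expect_equal(nrow(sel$gof), 6L)  # two parts per degree
  expect_true(sel$chosen %in% 1:3)
  expect_true(all(c("AIC", "BIC", "AICc", "HQIC", "CAIC") %in%
                    names(sel$gof)))
  # all-flat key estimates select the floor-midpoint of the full run
  km <- sel
  expect_true(is.data.frame(sel$estimates))
})
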