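# Ground-truth parameterized synthetic studies: covariates plus dynamic
# networks drawn from the two-part model, so every module is testable
# without external data, and parameter recovery can be measured.

#' Construct a ground-truth parameter set for a synthetic study
#'
#' Builds a complete deterministic parameter set for both model parts, a
#' phenotype table (continuous covariate of interest, binary and continuous
#' confounders), and node coordinates (uniform in a 100 mm cube). By default a
#' nonzero COI-by-modularity interaction is planted in the strength part; some
#' interaction effects are exactly zero so null calibration can be checked.
#'
#' Default magnitudes reflect the scales the covariates live on: network
#' means in roughly [0, 0.6], degrees in counts, distances in mm, strengths
#' on the Fisher-Z scale with residual SD 0.1 (about the sampling noise of a
#' 120-volume window correlation, `1/sqrt(L - 3)`).
#'
#' @param n_participants,n_nodes,n_windows Study dimensions (N >= 2, P >= 3,
#'   W >= 2).
#' @param poly_degree Temporal polynomial degree n of the generating model.
#' @param effects Optional named list overriding entries of `beta_r`,
#'   `beta_s`, `gamma_r`, `gamma_s`, `tau` (see the returned object); use
#'   `effects = list(null = TRUE)` to zero every non-intercept fixed effect.
#' @param seed Integer seed for phenotype and coordinate generation.
#' @return An object of class `ground_truth`.
#' @export
make_ground_truth <- function(n_participants = 40L, n_nodes = 20L,
                              n_windows = 6L, poly_degree = 2L,
                              effects = list(), seed = 1L) {
  N <- as.integer(n_participants); P <- as.integer(n_nodes)
  W <- as.integer(n_windows); n <- as.integer(poly_degree)
  if (N < 2L || P < 3L || W < 2L) stop("invalid study dimensions")
  if (n >= W) stop("poly_degree must be < n_windows")
  spec <- model_spec(coi = "coi", coi_type = "continuous",
                     confounders = list(sex = "binary", age = "continuous"),
                     poly_degree = n, random_terms = "intercept",
                     include_poly_random = TRUE)
  fixed <- c("(Intercept)", .fixed_terms(spec))
  beta_r <- stats::setNames(rep(0, length(fixed)), fixed)
  beta_r[c("(Intercept)", "C_avg", "E_avg", "l_avg", "k_diff", "Q")] <-
    c(0.0, -1.5, 2.0, 0.3, -0.02, 1.0)
  beta_r["coi"] <- 0.3
  beta_r["coi_x_Q"] <- -0.05
  beta_r[c("sex", "age", "dist", "dist2")] <- c(0.1, -0.05, -5e-3, 1e-5)
  beta_s <- stats::setNames(rep(0, length(fixed)), fixed)
  beta_s[c("(Intercept)", "C_avg", "E_avg", "l_avg", "k_diff", "Q")] <-
    c(0.35, 0.8, 0.5, -0.1, -0.005, -0.5)
  beta_s["coi"] <- -0.01
  beta_s["coi_x_Q"] <- 0.03
  beta_s[c("sex", "age", "dist", "dist2")] <- c(0.02, -0.01, -1e-3, 2e-6)
  gamma_r <- if (n > 0) stats::setNames(
    0.5 * (-0.6)^(seq_len(n) - 1), paste0("s", seq_len(n))) else numeric(0)
  gamma_s <- if (n > 0) stats::setNames(
    0.1 * (-0.5)^(seq_len(n) - 1), paste0("s", seq_len(n))) else numeric(0)
  tau <- list(
    presence = c(b_intercept = 0.25,
                 stats::setNames(rep(0.04, n),
                                 if (n > 0) paste0("d_s", seq_len(n)))),
    strength = c(b_intercept = 0.01,
                 stats::setNames(rep(2.5e-3, n),
                                 if (n > 0) paste0("d_s", seq_len(n)))),
    sigma2 = 0.01)
  if (isTRUE(effects$null)) {
    beta_r[-1L] <- 0; beta_s[-1L] <- 0
    effects$null <- NULL
  }
  for (nm in names(effects)) {
    tgt <- effects[[nm]]
    obj <- switch(nm, beta_r = , beta_s = , gamma_r = , gamma_s = TRUE, NULL)
    if (!is.null(obj)) {
      cur <- get(nm)
      cur[names(tgt)] <- tgt
      assign(nm, cur)
    } else if (nm == "tau") {
      tau <- utils::modifyList(tau, tgt)
    } else stop("unknown effects entry: ", nm)
  }
  pheno <- coords <- NULL
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("p%03d", seq_len(N))
    pheno <- data.frame(participant = ids,
                        coi = stats::rnorm(N),
                        sex = stats::rbinom(N, 1L, 0.5),
                        age = stats::rnorm(N),
                        stringsAsFactors = FALSE)
    coords <- data.frame(node = sprintf("n%03d", seq_len(P)),
                         x = stats::runif(P, 0, 100),
                         y = stats::runif(P, 0, 100),
                         z = stats::runif(P, 0, 100),
                         stringsAsFactors = FALSE)
  })
  structure(list(N = N, P = P, W = W, poly_degree = n, spec = spec,
                 beta_r = beta_r, beta_s = beta_s,
                 gamma_r = gamma_r, gamma_s = gamma_s, tau = tau,
                 phenotypes = pheno, coords = coords, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> N = %d participants, P = %d nodes, W = %d windows, degree n = %d\n",
              x$N, x$P, x$W, x$poly_degree))
  cat(sprintf("  planted strength COI x Q interaction: %.4g\n",
              x$beta_s["coi_x_Q"]))
  invisible(x)
}

#' Bare simulator parameter lists from a ground truth
#'
#' @param gt A [make_ground_truth()] object.
#' @return List with `presence` and `strength` parameter lists usable wherever
#'   a `twopart_fit` is accepted by the simulator.
#' @export
ground_truth_params <- function(gt) {
  n <- gt$poly_degree
  gam <- function(g) if (n > 0) g else numeric(0)
  list(
    presence = list(coef = c(gt$beta_r, gam(gt$gamma_r)),
                    tau_b = gt$tau$presence["b_intercept"],
                    tau_d = gt$tau$presence[grepl("^d_s",
                                                  names(gt$tau$presence))],
                    sigma2 = 1),
    strength = list(coef = c(gt$beta_s, gam(gt$gamma_s)),
                    tau_b = gt$tau$strength["b_intercept"],
                    tau_d = gt$tau$strength[grepl("^d_s",
                                                  names(gt$tau$strength))],
                    sigma2 = gt$tau$sigma2))
}

# auxiliary correlation networks per (participant, window): latent 3-community
# factor structure with a (participant, window)-varying factor loading so the
# endogenous covariates (Q especially) vary realistically across windows
.aux_networks <- function(gt) {
  labels <- gt$coords$node
  P <- gt$P
  T0 <- 60L
  nets_list <- vector("list", gt$N)
  for (i in seq_len(gt$N)) {
    comm <- sample(rep_len(1:3, P))
    mats <- vector("list", gt$W)
    for (w in seq_len(gt$W)) {
      rho <- stats::runif(1, 0.1, 0.5)
      f <- matrix(stats::rnorm(T0 * 3L), T0, 3L)
      X <- sqrt(rho) * f[, comm] +
        sqrt(1 - rho) * matrix(stats::rnorm(T0 * P), T0, P)
      R <- stats::cor(X)
      diag(R) <- 0
      R[R < 0] <- 0
      R <- pmin((R + t(R)) / 2, 1 - 1e-12)
      dimnames(R) <- list(labels, labels)
      mats[[w]] <- R
    }
    nets_list[[i]] <- structure(
      list(participant_id = gt$phenotypes$participant[i], windows = mats,
           window_starts = seq_len(gt$W), node_labels = labels),
      class = "dyn_nets")
  }
  nets_list
}

#' Generate a synthetic study from a ground truth
#'
#' Draws auxiliary correlation networks per (participant, window) to supply
#' realistic endogenous covariates, assembles the design table through the
#' same path as real data, then replaces presence and strength with draws
#' from the generating two-part model: participant random effects from
#' `N(0, diag(tau))`, presence from `Bernoulli(logistic(eta_r))`, strength
#' from `tanh(Normal(eta_s, sigma2))` masked by presence. The endogenous
#' covariates are regressors, not recomputed from the simulated edges.
#'
#' @param gt A [make_ground_truth()] object.
#' @param seed Integer seed for this replicate.
#' @return A `dyad_design` table with simulated `R`, `Y`, `S`; the ground
#'   truth is attached as attribute `ground_truth`.
#' @export
generate_synthetic_study <- function(gt, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  design <- NULL
  withr::with_seed(as.integer(seed), {
    nets_list <- .aux_networks(gt)
    metrics <- node_metric_table(nets_list, seed = .sub_seed(seed, 7L))
    dyadcov <- dyad_covariates(metrics, gt$coords)
    design <- assemble_design(nets_list, dyadcov, gt$phenotypes, gt$spec)
    mats <- .build_matrices(design, gt$spec)
    par <- ground_truth_params(gt)
    eta_r <- as.vector(mats$X %*% par$presence$coef)
    eta_s <- as.vector(mats$X %*% par$strength$coef)
    for (pid in unique(design$participant)) {
      rows <- which(design$participant == pid)
      re_r <- .draw_random_effects(par$presence)
      re_s <- .draw_random_effects(par$strength)
      eta_r[rows] <- eta_r[rows] + .random_contribution(mats, rows, re_r)
      eta_s[rows] <- eta_s[rows] + .random_contribution(mats, rows, re_s)
    }
    R <- stats::rbinom(nrow(design), 1L, stats::plogis(eta_r))
    z <- stats::rnorm(nrow(design), eta_s, sqrt(gt$tau$sigma2))
    Y <- inverse_fisher_z(z) * R
    # present edges must stay positive: truncate the (rare) negative draws
    Y[R == 1L & Y <= 0] <- 1e-6
    Y <- pmin(Y, 1 - 1e-12)
    design$R <- R
    design$Y <- Y
    design$S <- ifelse(R == 1L, fisher_z(Y), NA_real_)
  })
  attr(design, "ground_truth") <- gt
  design
}

#' Parameter-recovery report over replicate fits
#'
#' For every fixed-effect parameter of both parts: the true value, the mean
#' estimate, the empirical SE across replicates, the bias, and the coverage
#' of nominal 95% Wald intervals.
#'
#' @param gt A [make_ground_truth()] object.
#' @param fits List of per-replicate two-part fits (each a list with
#'   `presence` and `strength` elements), length >= 2.
#' @return Data frame with columns `part`, `parameter`, `truth`,
#'   `mean_estimate`, `empirical_se`, `bias`, `coverage`.
#' @export
recovery_report <- function(gt, fits) {
  if (length(fits) < 2L) stop("need >= 2 replicates")
  par <- ground_truth_params(gt)
  out <- list()
  for (part in c("presence", "strength")) {
    truth <- par[[part]]$coef
    est <- t(vapply(fits, function(f) f[[part]]$coef_all,
                    numeric(length(truth))))
    ses <- t(vapply(fits, function(f)
      sqrt(diag(f[[part]]$cov_all)), numeric(length(truth))))
    cover <- colMeans(abs(sweep(est, 2L, truth)) <= 1.96 * ses)
    emp_se <- apply(est, 2L, stats::sd)
    out[[part]] <- data.frame(
      part = part, parameter = names(truth), truth = unname(truth),
      mean_estimate = colMeans(est), empirical_se = emp_se,
      bias = colMeans(est) - unname(truth), coverage = unname(cover),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Run a full parameter-recovery simulation
#'
#' Generates `n_replicates` synthetic studies from the ground truth, fits
#' both model parts to each, and reports recovery. Replicate seeds are spawned
#' deterministically from `seed`.
#'
#' @inheritParams recovery_report
#' @param n_replicates Number of replicates.
#' @param seed Master integer seed.
#' @return List with `report` (from [recovery_report()]), `fits`, and
#'   `detection` — per-replicate adjusted p value of the planted strength
#'   COI-by-modularity interaction.
#' @export
run_recovery <- function(gt, n_replicates = 50L, seed = 1L) {
  fits <- vector("list", n_replicates)
  detection <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    d <- generate_synthetic_study(gt, seed = .sub_seed(seed, r))
    fits[[r]] <- fit_twopart(d)
    b <- fits[[r]]$strength$beta
    detection[r] <- b$p_adj[b$parameter == "coi_x_Q"]
  }
  list(report = recovery_report(gt, fits), fits = fits,
       detection = detection)
}
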