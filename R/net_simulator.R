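# Generative simulation of dynamic weighted networks from a fitted (or
# user-specified) two-part model, plus observed-vs-simulated summaries.

# accept either a twopart_fit or a bare parameter list
.part_params <- function(fit) {
  if (inherits(fit, "twopart_fit"))
    return(list(coef = fit$coef_all, tau_b = fit$varcomp$tau_b,
                tau_d = fit$varcomp$tau_d, sigma2 = fit$varcomp$sigma2))
  if (!all(c("coef", "tau_b", "tau_d", "sigma2") %in% names(fit)))
    stop("expected a twopart_fit or a list with coef, tau_b, tau_d, sigma2")
  fit
}

#' Per-row simulation moments from the two model parts
#'
#' Population-level moments for each design row: presence probability
#' `p = logistic(X' beta_r + sum_o gamma_ro s_(o))`, strength mean
#' `mu_sim = X' beta_s + sum_o gamma_so s_(o)` on the Fisher-Z scale, and
#' marginal strength variance
#' `sigma2_sim = sum_k tau_bs[k] z_k^2 + sum_o tau_ds[o] s_(o)^2 + sigma2`.
#'
#' @param fit_presence,fit_strength `twopart_fit` objects (or bare parameter
#'   lists with elements `coef`, `tau_b`, `tau_d`, `sigma2`).
#' @param design A `dyad_design` table (rows to simulate).
#' @param spec A [model_spec()]; defaults to the one attached to `design`.
#' @return Data frame with columns `p`, `mu_sim`, `sigma2_sim`, one row per
#'   design row.
#' @export
compute_moments <- function(fit_presence, fit_strength, design,
                            spec = attr(design, "model_spec")) {
  pr <- .part_params(fit_presence)
  st <- .part_params(fit_strength)
  mats <- .build_matrices(design, spec)
  if (!identical(colnames(mats$X), names(pr$coef)) ||
      !identical(colnames(mats$X), names(st$coef)))
    stop("fit coefficients do not match the design's fixed-effect columns")
  eta_r <- as.vector(mats$X %*% pr$coef)
  mu <- as.vector(mats$X %*% st$coef)
  s2 <- rep(st$sigma2, nrow(mats$X))
  for (nm in names(st$tau_b))
    s2 <- s2 + st$tau_b[[nm]] * mats$random[[nm]]^2
  for (nm in names(st$tau_d))
    s2 <- s2 + st$tau_d[[nm]] * mats$random[[nm]]^2
  data.frame(p = stats::plogis(eta_r), mu_sim = mu, sigma2_sim = s2)
}

#' Simulate edge presence
#'
#' Independent Bernoulli draw per dyad-window row.
#'
#' @param moments Data frame from [compute_moments()] (column `p`).
#' @param seed Optional integer seed (uses the current RNG state when NULL).
#' @return Integer 0/1 vector.
#' @export
simulate_presence <- function(moments, seed = NULL) {
  p <- moments$p
  if (any(p < 0 | p > 1)) stop("presence probabilities must lie in [0, 1]")
  draw <- function() stats::rbinom(length(p), 1L, p)
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Simulate edge strengths given presence
#'
#' Draws `z ~ Normal(mu_sim, sigma2_sim)` per row, back-transforms with the
#' inverse Fisher Z (tanh), and masks by the presence draw. Negative
#' back-transformed draws on present edges are truncated to 0 (observed
#' networks are nonnegative by thresholding); the truncation rate is attached
#' as an attribute. Set `truncate_negative = FALSE` to keep negatives for
#' diagnostics.
#'
#' @inheritParams simulate_presence
#' @param presence 0/1 vector conformable with `moments`.
#' @param truncate_negative Truncate negative strengths on present edges?
#' @return Numeric weight vector in `[0, 1)` (attribute
#'   `truncation_rate` = fraction of present edges truncated).
#' @export
simulate_strength <- function(moments, presence, seed = NULL,
                              truncate_negative = TRUE) {
  if (length(presence) != nrow(moments))
    stop("presence not conformable with moments")
  draw <- function() stats::rnorm(nrow(moments), moments$mu_sim,
                                  sqrt(moments$sigma2_sim))
  z <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  w <- inverse_fisher_z(z) * presence
  trunc_rate <- 0
  if (truncate_negative) {
    neg <- w < 0
    n_present <- sum(presence == 1L)
    trunc_rate <- if (n_present > 0) sum(neg) / n_present else 0
    w[neg] <- 0
  }
  w <- pmin(w, 1 - 1e-12)
  attr(w, "truncation_rate") <- trunc_rate
  w
}

#' Simulate a set of dynamic weighted networks
#'
#' For each requested participant and realization, draws participant-level
#' random effects and polynomial deviations from `N(0, diag(tau))` for each
#' part independently, computes the conditional presence probability and
#' strength mean per dyad-window row, draws presence (Bernoulli) and strength
#' (Normal on the Fisher-Z scale, back-transformed and masked), and assembles
#' symmetric zero-diagonal weight matrices. A master seed spawns one
#' substream per (participant, replicate) so subsets reproduce exactly.
#'
#' @param fits List with elements `presence` and `strength` (each a
#'   `twopart_fit` or bare parameter list).
#' @param design A `dyad_design` carrying the covariates to condition on.
#' @param participants Participant ids to simulate (default: all in `design`).
#' @param windows Window indices to simulate (default: all in `design`).
#' @param n_realizations Realizations per (participant, window).
#' @param seed Master integer seed.
#' @param spec A [model_spec()]; defaults to the one attached to `design`.
#' @return An object of class `sim_net_set`: list with `networks` (list of
#'   records: `participant`, `window`, `replicate`, `matrix`), `node_labels`,
#'   `seed`, `truncation_rate`.
#' @export
simulate_dynamic_networks <- function(fits, design, participants = NULL,
                                      windows = NULL, n_realizations = 1L,
                                      seed = 1L,
                                      spec = attr(design, "model_spec")) {
  pr <- .part_params(fits$presence)
  st <- .part_params(fits$strength)
  all_p <- unique(design$participant)
  all_w <- sort(unique(design$window))
  if (is.null(participants)) participants <- all_p
  if (is.null(windows)) windows <- all_w
  if (length(bad <- setdiff(participants, all_p)))
    stop("unknown participant(s): ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(windows, all_w)))
    stop("unknown window(s): ", paste(bad, collapse = ", "))
  labels <- sort(unique(c(design$node_j, design$node_k)))
  P <- length(labels)
  mats <- .build_matrices(design, spec)
  eta_r_fix <- as.vector(mats$X %*% pr$coef)
  eta_s_fix <- as.vector(mats$X %*% st$coef)
  nets <- vector("list", length(participants) * length(windows) *
                   n_realizations)
  idx <- 1L
  n_trunc <- 0L; n_present_total <- 0L
  for (pi in seq_along(participants)) {
    pid <- participants[pi]
    prow <- which(design$participant == pid & design$window %in% windows)
    jj <- match(design$node_j[prow], labels)
    kk <- match(design$node_k[prow], labels)
    for (rep_i in seq_len(n_realizations)) {
      withr::with_seed(.sub_seed(seed, pi * 100003L + rep_i), {
        re_r <- .draw_random_effects(pr)
        re_s <- .draw_random_effects(st)
        zb_r <- .random_contribution(mats, prow, re_r)
        zb_s <- .random_contribution(mats, prow, re_s)
        p <- stats::plogis(eta_r_fix[prow] + zb_r)
        presence <- stats::rbinom(length(prow), 1L, p)
        z <- stats::rnorm(length(prow), eta_s_fix[prow] + zb_s,
                          sqrt(st$sigma2))
        w <- inverse_fisher_z(z) * presence
        neg <- w < 0
        n_trunc <- n_trunc + sum(neg)
        n_present_total <- n_present_total + sum(presence)
        w[neg] <- 0
        w <- pmin(w, 1 - 1e-12)
        for (wi in windows) {
          sel <- design$window[prow] == wi
          M <- matrix(0, P, P, dimnames = list(labels, labels))
          M[cbind(jj[sel], kk[sel])] <- w[sel]
          M[cbind(kk[sel], jj[sel])] <- w[sel]
          nets[[idx]] <- list(participant = pid, window = wi,
                              replicate = rep_i, matrix = M)
          idx <- idx + 1L
        }
      })
    }
  }
  structure(list(networks = nets, node_labels = labels, seed = seed,
                 truncation_rate = if (n_present_total > 0)
                   n_trunc / n_present_total else 0),
            class = "sim_net_set")
}

# one scalar draw per random-term family (participant level)
.draw_random_effects <- function(par) {
  tau <- c(par$tau_b, par$tau_d)
  stats::setNames(stats::rnorm(length(tau), 0, sqrt(as.numeric(tau))),
                  names(tau))
}

# per-row random-effect contribution Z b for the given rows
.random_contribution <- function(mats, rows, re) {
  out <- rep(0, length(rows))
  for (nm in names(re))
    out <- out + re[[nm]] * mats$random[[nm]][rows]
  out
}

#' @export
print.sim_net_set <- function(x, ...) {
  cat(sprintf("<sim_net_set> %d simulated networks (%d nodes), master seed %d\n",
              length(x$networks), length(x$node_labels), x$seed))
  cat(sprintf("  negative-strength truncation rate: %.4f\n",
              x$truncation_rate))
  invisible(x)
}

#' Summarize weighted network measures over a set of networks
#'
#' Mean and SD over all networks of the node-averaged weighted clustering
#' coefficient `C`, global efficiency `Eglob`, and node-averaged degree `K`.
#'
#' @param networks A `sim_net_set`, or a list of weight matrices.
#' @return Data frame with columns `metric`, `mean`, `sd`.
#' @export
summarize_networks <- function(networks) {
  mats <- if (inherits(networks, "sim_net_set"))
    lapply(networks$networks, `[[`, "matrix") else networks
  if (length(mats) == 0L) stop("empty network set")
  per_net <- t(vapply(mats, function(M) {
    c(C = mean(node_clustering(M)),
      Eglob = node_efficiency(M)$global,
      K = mean(node_degree(M)))
  }, numeric(3)))
  data.frame(metric = colnames(per_net),
             mean = apply(per_net, 2L, mean),
             sd = apply(per_net, 2L, stats::sd),
             row.names = NULL)
}
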