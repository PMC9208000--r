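# Two-part mixed-model estimation: a weighted REML linear mixed-model core
# (variance-components structure), a restricted pseudo-likelihood loop for
# the logistic presence part, Wald F inference, adaptive FDR, GOF measures,
# and polynomial degree selection.

# ---- profiled REML evaluation ---------------------------------------------
#
# For variance-components models whose random effects are scalar participant-
# level terms, V_i = W_i^{-1} + U_i diag(lambda) U_i' (sigma2 profiled out),
# every trace needed for the REML gradient and expected information reduces
# to scalar products via rank-1-per-block structure and the Woodbury
# identity. This powers a Fisher-scoring refinement of the variance
# components to near machine precision after the initial numeric fit.
.reml_prepare <- function(y, X, U, group, w) {
  blocks <- split(seq_along(y), group)
  list(n = length(y), p = ncol(X), q = ncol(U), nb = length(blocks),
       blocks = blocks,
       Xi = lapply(blocks, function(ix) X[ix, , drop = FALSE]),
       yi = lapply(blocks, function(ix) y[ix]),
       Ui = lapply(blocks, function(ix) U[ix, , drop = FALSE]),
       wi = lapply(blocks, function(ix) w[ix]))
}

.reml_eval <- function(prep, lambda, grad = TRUE) {
  n <- prep$n; p <- prep$p; q <- prep$q; nb <- prep$nb
  act <- which(lambda > 0)
  M <- matrix(0, p, p); r <- numeric(p)
  yVy <- 0; logdetV <- 0
  SzVz <- vector("list", nb); CzX <- vector("list", nb)
  zVy <- matrix(0, nb, q)
  VinvX_list <- vector("list", nb); Vinvy_list <- vector("list", nb)
  for (bi in seq_len(nb)) {
    Xi <- prep$Xi[[bi]]; yi <- prep$yi[[bi]]
    Ui <- prep$Ui[[bi]]; wi <- prep$wi[[bi]]
    # apply V_i^{-1} to [X_i, y_i, U_i] in one Woodbury pass
    B <- cbind(Xi, yi, if (grad) Ui)
    if (length(act)) {
      Ua <- Ui[, act, drop = FALSE]
      Au <- Ua * wi
      G <- diag(1 / lambda[act], nrow = length(act)) + crossprod(Ua, Au)
      cG <- chol(G)
      VB <- B * wi - Au %*% backsolve(cG, forwardsolve(t(cG),
                                                       crossprod(Au, B)))
      logdetV <- logdetV - sum(log(wi)) + sum(log(lambda[act])) +
        2 * sum(log(diag(cG)))
    } else {
      VB <- B * wi
      logdetV <- logdetV - sum(log(wi))
    }
    VX <- VB[, seq_len(p), drop = FALSE]
    Vy <- VB[, p + 1L]
    M <- M + crossprod(Xi, VX)
    r <- r + crossprod(Xi, Vy)
    yVy <- yVy + sum(yi * Vy)
    VinvX_list[[bi]] <- VX; Vinvy_list[[bi]] <- Vy
    if (grad) {
      Vz <- VB[, (p + 2L):(p + 1L + q), drop = FALSE]
      SzVz[[bi]] <- crossprod(Ui, Vz)
      CzX[[bi]] <- crossprod(Xi, Vz)
      zVy[bi, ] <- crossprod(Ui, Vy)
    }
  }
  cM <- chol(M)
  Minv <- chol2inv(cM)
  beta <- as.vector(Minv %*% r)
  ypy <- max(yVy - sum(r * (Minv %*% r)), .Machine$double.eps)
  sigma2 <- ypy / (n - p)
  logdetM <- 2 * sum(log(diag(cM)))
  loglik <- -0.5 * (logdetV + logdetM +
                      (n - p) * (log(2 * pi * sigma2) + 1))
  out <- list(beta = beta, Minv = Minv, r = r, sigma2 = sigma2,
              ypy = ypy, loglik = loglik, blocks = prep$blocks,
              VinvX = VinvX_list, Vinvy = Vinvy_list)
  if (grad && q > 0) {
    Mr <- Minv %*% r
    g <- numeric(q)
    zPy <- matrix(0, nb, q)
    trP <- numeric(q)
    for (bi in seq_len(nb)) {
      ck <- CzX[[bi]]                       # p x q
      trP <- trP + diag(SzVz[[bi]]) - colSums(ck * (Minv %*% ck))
      zPy[bi, ] <- zVy[bi, ] - as.vector(crossprod(ck, Mr))
    }
    g <- -0.5 * (trP - (n - p) * colSums(zPy^2) / ypy)
    # expected information: tr(P Z_k Z_k' P Z_l Z_l') via scalar products
    Call <- do.call(cbind, CzX)             # p x (nb*q)
    crossM <- crossprod(Call, Minv %*% Call)  # (nb*q) x (nb*q)
    term <- -crossM
    for (bi in seq_len(nb)) {
      sel <- ((bi - 1L) * q + 1L):(bi * q)
      term[sel, sel] <- term[sel, sel] + SzVz[[bi]]
    }
    FI <- matrix(0, q, q)
    for (k in seq_len(q)) {
      for (l in k:q) {
        ik <- seq.int(k, nb * q, by = q)
        il <- seq.int(l, nb * q, by = q)
        FI[k, l] <- FI[l, k] <- 0.5 * sum(term[ik, il]^2)
      }
    }
    out$grad <- g
    out$FI <- FI
  }
  out
}

# Fisher scoring on the profiled REML surface in the variance ratios
# lambda = tau / sigma2 (nonnegativity enforced by projection). One full
# evaluation per iteration: the scoring step is accepted optimistically and
# only halved (cheap likelihood-only evaluations) when the restricted
# likelihood decreases.
.reml_polish <- function(prep, lambda0, max_iter = 60L, gtol = 1e-9) {
  lambda <- pmax(lambda0, 0)
  ev <- .reml_eval(prep, lambda)
  for (it in seq_len(max_iter)) {
    g <- ev$grad
    free <- lambda > 0 | g > 0
    if (!any(free) || max(abs(g[free])) < gtol) break
    step <- numeric(length(lambda))
    FIf <- ev$FI[free, free, drop = FALSE]
    step[free] <- tryCatch(solve(FIf + diag(1e-12, sum(free)), g[free]),
                           error = function(e) g[free] / (diag(FIf) + 1e-12))
    cand <- pmax(lambda + step, 0)
    ev_new <- tryCatch(.reml_eval(prep, cand), error = function(e) NULL)
    if (is.null(ev_new) || ev_new$loglik < ev$loglik - 1e-10) {
      ok <- FALSE
      for (h in 1:30) {
        cand <- pmax(lambda + step / 2^h, 0)
        ll <- tryCatch(.reml_eval(prep, cand, grad = FALSE)$loglik,
                       error = function(e) -Inf)
        if (ll >= ev$loglik - 1e-12) { ok <- TRUE; break }
      }
      if (!ok || max(abs(cand - lambda)) < 1e-14) break
      ev_new <- .reml_eval(prep, cand)
    }
    if (max(abs(cand - lambda)) < 1e-14) break
    lambda <- cand
    ev <- ev_new
  }
  list(lambda = lambda, eval = ev)
}

# ---- weighted LMM core -----------------------------------------------------

#' Weighted linear mixed model with independent variance components
#'
#' REML fit of `y = X beta + Z b + e`, where the random effects are scalar
#' participant-level terms (one independent variance per term, shared across
#' participants) and `Var(e_i) = sigma2 / w_i`. This is the working-model core
#' of the restricted pseudo-likelihood iteration and the direct engine of the
#' strength part. Estimation is delegated to [lme4::lmer()]; the surrounding
#' two-part machinery (design, linearization loop, inference) is native.
#'
#' @param y Numeric response.
#' @param X Fixed-effects design matrix with column names (include an
#'   intercept column explicitly if wanted).
#' @param random Named list of numeric vectors (same length as `y`): the
#'   per-observation value of each scalar random term (a vector of ones for a
#'   random intercept). Empty list = weighted least squares.
#' @param group Grouping factor (participant) for the random terms.
#' @param weights Positive observation weights (default all 1).
#' @param start Optional starting values for the variance ratios
#'   `lambda = tau / sigma2` (warm start across pseudo-likelihood
#'   iterations); defaults to 0.1 per component.
#' @return List with `beta`, `se`, `cov_beta`, `varcomp` (named variances,
#'   last element `sigma2`), `loglik` (restricted log likelihood, or ML log
#'   likelihood for the fixed-only case), `blup` (per-observation random-part
#'   prediction `Z b`), `lambda` (variance ratios), `converged`.
#' @export
fit_weighted_lmm <- function(y, X, random = list(), group = NULL,
                             weights = NULL, start = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y dimensions differ")
  if (is.null(weights)) weights <- rep(1, n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  if (length(random) == 0L) {
    fit <- stats::lm.wfit(X, y, w = weights)
    rss <- sum(weights * fit$residuals^2)
    df <- n - ncol(X)
    sigma2 <- rss / df
    XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(weights))))
    cov_beta <- sigma2 * XtWX_inv
    dimnames(cov_beta) <- list(colnames(X), colnames(X))
    # Gaussian ML log likelihood of the weighted fit
    ll <- 0.5 * (sum(log(weights)) - n * (log(2 * pi) + 1 - log(n) +
                                            log(rss)))
    return(list(beta = stats::setNames(fit$coefficients, colnames(X)),
                se = sqrt(diag(cov_beta)), cov_beta = cov_beta,
                varcomp = c(sigma2 = sigma2), loglik = ll,
                blup = rep(0, n), lambda = numeric(0), converged = TRUE))
  }
  if (is.null(group)) stop("group required when random terms are present")
  group <- factor(group)
  U <- do.call(cbind, random)
  colnames(U) <- names(random)
  prep <- .reml_prepare(y, X, U, group, weights)
  # primary path: native Fisher scoring on the profiled REML surface from a
  # warm start (previous pseudo-likelihood iteration) or 0.1 per component
  lambda0 <- if (!is.null(start)) pmax(start, 0) else
    rep(0.1, length(random))
  pol <- .reml_polish(prep, lambda0 = lambda0)
  scaled_g <- max(abs(pol$eval$grad[pol$lambda > 0 | pol$eval$grad > 0]), 0)
  converged_native <- scaled_g < 1e-5 * max(1, n / 100)
  warn <- character(0)
  if (!converged_native) {
    # fall back to lme4 for a robust global start, then refine
    dat <- data.frame(.y = y, .w = weights, .g = group)
    fnames <- paste0("f", seq_len(ncol(X)))
    for (j in seq_len(ncol(X))) dat[[fnames[j]]] <- X[, j]
    znames <- paste0("z", seq_along(random))
    for (j in seq_along(random)) dat[[znames[j]]] <- random[[j]]
    fml <- stats::as.formula(paste(
      ".y ~ 0 +", paste(fnames, collapse = " + "), "+",
      paste(sprintf("(0 + %s | .g)", znames), collapse = " + ")))
    ctrl <- lme4::lmerControl(
      calc.derivs = FALSE,
      check.conv.singular = "ignore",
      optCtrl = list(xtol_rel = 1e-12, xtol_abs = 1e-14, ftol_abs = 1e-14,
                     maxeval = 20000L))
    m <- withCallingHandlers(
      lme4::lmer(fml, data = dat, weights = .w, REML = TRUE, control = ctrl),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    vc <- as.data.frame(lme4::VarCorr(m))
    tau0 <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                            names(random)[match(vc$var1[vc$grp != "Residual"],
                                                znames)])
    tau0 <- tau0[names(random)]
    pol2 <- .reml_polish(prep, lambda0 = tau0 / stats::sigma(m)^2)
    if (pol2$eval$loglik >= pol$eval$loglik) pol <- pol2
  }
  ev <- pol$eval
  beta <- stats::setNames(ev$beta, colnames(X))
  sigma2 <- ev$sigma2
  tau <- stats::setNames(sigma2 * pol$lambda, names(random))
  cov_beta <- sigma2 * ev$Minv
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  blup <- numeric(n)
  for (bi in seq_along(prep$blocks)) {
    ix <- prep$blocks[[bi]]
    vr <- ev$Vinvy[[bi]] - as.vector(ev$VinvX[[bi]] %*% ev$beta)
    Ui <- prep$Ui[[bi]]
    blup[ix] <- Ui %*% (pol$lambda * as.vector(crossprod(Ui, vr)))
  }
  final_g <- max(abs(ev$grad[pol$lambda > 0 | ev$grad > 0]), 0)
  list(beta = beta, se = sqrt(diag(cov_beta)), cov_beta = cov_beta,
       varcomp = c(tau, sigma2 = sigma2),
       loglik = ev$loglik,
       blup = blup, lambda = pol$lambda,
       converged = final_g < 1e-4 * max(1, n / 100) &&
         !any(grepl("failed to converge", warn)))
}

# ---- design-matrix assembly ------------------------------------------------

# Fixed-effect matrix (intercept + covariates + population polynomials) and
# the random-term list implied by a model_spec, for a subset of design rows.
.build_matrices <- function(design, spec, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(design))
  d <- design[rows, , drop = FALSE]
  terms <- .fixed_terms(spec)
  missing_cols <- setdiff(terms, names(d))
  if (length(missing_cols))
    stop("design table lacks column(s): ", paste(missing_cols, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[, terms, drop = FALSE]))
  poly_names <- character(0)
  Smat <- NULL
  if (spec$poly_degree > 0L) {
    poly_names <- paste0("s", seq_len(spec$poly_degree))
    if (all(poly_names %in% names(d))) {
      Smat <- as.matrix(d[, poly_names, drop = FALSE])
    } else {
      # degree differs from the stored design (e.g. degree selection):
      # rebuild the basis over the design's full window range
      basis <- orthonormal_basis(max(design$window), spec$poly_degree)
      Smat <- basis$S[d$window, , drop = FALSE]
      colnames(Smat) <- poly_names
    }
    X <- cbind(X, Smat)
  }
  if (isTRUE(spec$standardize)) {
    for (nm in setdiff(terms, character(0))) {
      v <- X[, nm]
      if (length(unique(v)) > 2L) X[, nm] <- as.numeric(scale(v))
    }
  }
  random <- list()
  if ("intercept" %in% spec$random_terms)
    random$b_intercept <- rep(1, nrow(d))
  if ("net" %in% spec$random_terms)
    for (nt in spec$net_terms) random[[paste0("b_", nt)]] <- d[[nt]]
  if ("dist" %in% spec$random_terms) {
    random$b_dist <- d$dist
    random$b_dist2 <- d$dist2
  }
  if ("nodal" %in% spec$random_terms) {
    labels <- sort(unique(c(d$node_j, d$node_k)))
    for (lb in labels)
      random[[paste0("delta_", lb)]] <-
        as.numeric(d$node_j == lb | d$node_k == lb)
  }
  if (isTRUE(spec$include_poly_random) && spec$poly_degree > 0L)
    for (o in seq_len(spec$poly_degree))
      random[[paste0("d_s", o)]] <- Smat[, o]
  list(X = X, random = random, group = d$participant,
       fixed_names = colnames(X), poly_names = poly_names)
}

# package a fitted part into a twopart_fit object
.make_fit <- function(part, core, mats, n_obs, iterations = NA_integer_,
                      converged = TRUE) {
  est <- core$beta
  se <- core$se
  rankX <- ncol(mats$X)
  df_den <- n_obs - rankX
  tval <- est / se
  p_raw <- 2 * stats::pt(-abs(tval), df = df_den)
  p_adj <- adaptive_fdr_adjust(p_raw)
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    se = unname(se), p_raw = unname(p_raw),
                    p_adj = unname(p_adj), stringsAsFactors = FALSE)
  is_gamma <- tab$parameter %in% mats$poly_names
  vc <- core$varcomp
  tau_d <- vc[grepl("^d_s", names(vc))]
  tau_b <- vc[!grepl("^d_s", names(vc)) & names(vc) != "sigma2"]
  K <- length(est) + length(vc)
  fit <- list(part = part,
              beta = tab[!is_gamma, , drop = FALSE],
              gamma = tab[is_gamma, , drop = FALSE],
              coef_all = est, cov_all = core$cov_beta,
              varcomp = list(tau_b = tau_b, tau_d = tau_d,
                             sigma2 = unname(vc["sigma2"])),
              loglik = core$loglik, n_obs = n_obs, n_params = K,
              rank_X = rankX, df_den = df_den,
              converged = converged && core$converged,
              iterations = iterations,
              fixed_names = mats$fixed_names,
              poly_names = mats$poly_names)
  fit$gof <- gof_measures(fit)
  class(fit) <- "twopart_fit"
  fit
}

#' @export
print.twopart_fit <- function(x, ...) {
  cat(sprintf("<twopart_fit> %s part: %d obs, %d fixed effects, %d variance parameters\n",
              x$part, x$n_obs, length(x$coef_all),
              length(x$varcomp$tau_b) + length(x$varcomp$tau_d) + 1L))
  cat(sprintf("  converged: %s%s; restricted log-likelihood %.2f\n",
              x$converged,
              if (!is.na(x$iterations)) sprintf(" (%d iterations)", x$iterations) else "",
              x$loglik))
  print(utils::head(rbind(x$beta, x$gamma), 12), row.names = FALSE)
  invisible(x)
}

# ---- model parts -----------------------------------------------------------

#' Fit the strength part (Gaussian mixed model on Fisher-Z weights)
#'
#' Fits the linear mixed model on the rows with a present connection
#' (`R = 1`) only, with response `FZT(Y)`, fixed effects = intercept,
#' endogenous network terms, covariate of interest and its interactions,
#' confounders, distance terms and population polynomial columns, and the
#' random-effect families declared in the model spec.
#'
#' @param design A `dyad_design` table from [assemble_design()] (or the
#'   synthetic-study generator).
#' @param spec A [model_spec()]; defaults to the spec attached to `design`.
#' @return A `twopart_fit` object with `part = "strength"`.
#' @export
fit_strength_model <- function(design, spec = attr(design, "model_spec")) {
  rows <- which(design$R == 1L)
  if (length(rows) == 0L) stop("no rows with a present connection (R = 1)")
  mats <- .build_matrices(design, spec, rows)
  if (length(rows) <= ncol(mats$X))
    stop("fewer strength-part rows than fixed parameters")
  y <- design$S[rows]
  core <- fit_weighted_lmm(y, mats$X, random = mats$random,
                           group = mats$group)
  .make_fit("strength", core, mats, n_obs = length(rows))
}

#' Fit the presence part (logistic mixed model via restricted pseudo-likelihood)
#'
#' Iteratively linearizes the logistic link: starting from a fixed-effects
#' logistic fit, forms the working response
#' `nu = eta + (R - mu) / (mu (1 - mu))` and weights `mu (1 - mu)`, fits the
#' weighted REML linear mixed model, updates `eta` with the predicted random
#' effects, and repeats until the joint relative change in the fixed effects
#' and variance components falls below `tol`.
#'
#' @inheritParams fit_strength_model
#' @param tol Joint relative-change convergence tolerance (default 1e-6).
#' @param max_iter Maximum outer iterations (default 100).
#' @return A `twopart_fit` object with `part = "presence"`; `converged` is
#'   `FALSE` (with a warning) when the loop hits `max_iter`.
#' @export
fit_presence_model <- function(design, spec = attr(design, "model_spec"),
                               tol = 1e-6, max_iter = 100L) {
  mats <- .build_matrices(design, spec)
  R <- design$R
  if (all(R == 1L) || all(R == 0L))
    stop("degenerate presence response: R is constant (all ",
         R[1L], ")")
  X <- mats$X
  init <- suppressWarnings(
    stats::glm.fit(X, R, family = stats::binomial()))
  beta <- init$coefficients
  eta <- as.vector(X %*% beta)
  blup <- rep(0, length(R))
  old <- NULL
  lambda <- NULL
  core <- NULL
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    nu <- eta + (R - mu) / w
    core <- fit_weighted_lmm(nu, X, random = mats$random,
                             group = mats$group, weights = w,
                             start = lambda)
    lambda <- core$lambda
    beta <- core$beta
    blup <- core$blup
    eta_fixed <- as.vector(X %*% beta)
    if (max(abs(eta_fixed)) > 30)
      stop("complete separation suspected: diverging linear predictor ",
           "in the presence model")
    eta <- eta_fixed + blup
    cur <- c(beta, core$varcomp)
    if (!is.null(old)) {
      rel <- max(abs(cur - old) / pmax(abs(old), 1e-4))
      if (rel < tol) { converged <- TRUE; break }
    }
    old <- cur
    if (it >= max_iter) break
  }
  if (!converged)
    warning("restricted pseudo-likelihood did not converge in ",
            max_iter, " iterations")
  .make_fit("presence", core, mats, n_obs = length(R),
            iterations = it, converged = converged)
}

#' Fit both parts of the two-part model
#'
#' @inheritParams fit_presence_model
#' @return List with elements `presence` and `strength`, each a `twopart_fit`.
#' @export
fit_twopart <- function(design, spec = attr(design, "model_spec"),
                        tol = 1e-6, max_iter = 100L) {
  list(presence = fit_presence_model(design, spec, tol = tol,
                                     max_iter = max_iter),
       strength = fit_strength_model(design, spec))
}

# ---- inference -------------------------------------------------------------

#' Wald F test with residual degrees-of-freedom approximation
#'
#' `F = (L b)' (L V L')^{-1} (L b) / rank(L)` with numerator df = rank(L) and
#' denominator df = `n_obs - rank(X)`.
#'
#' @param fit A `twopart_fit`.
#' @param L Contrast matrix (rows = contrasts) or a single contrast vector,
#'   conformable with the full fixed-effect vector `fit$coef_all`.
#' @return List with `F`, `df_num`, `df_den`, `p`.
#' @export
wald_f_test <- function(fit, L) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  if (ncol(L) != length(fit$coef_all))
    stop("contrast has ", ncol(L), " columns; fit has ",
         length(fit$coef_all), " fixed effects")
  q <- qr(L)$rank
  if (q < 1L) stop("contrast matrix has rank 0")
  Lb <- L %*% fit$coef_all
  M <- L %*% fit$cov_all %*% t(L)
  Minv <- tryCatch(solve(M), error = function(e)
    stop("L cov(beta) L' is singular"))
  Fstat <- as.numeric(t(Lb) %*% Minv %*% Lb) / q
  p <- stats::pf(Fstat, q, fit$df_den, lower.tail = FALSE)
  list(F = Fstat, df_num = q, df_den = fit$df_den, p = p)
}

#' Adaptive false discovery rate adjustment
#'
#' Two-stage adaptive linear step-up: the number of true nulls `m0` is
#' estimated by the lowest-slope method (ordered slopes
#' `s_j = (1 - p_(j)) / (m + 1 - j)`; at the first decrease,
#' `m0 = min(m, floor(1/s_j) + 1)`), then the Benjamini-Hochberg step-up is
#' applied with `m0` in place of `m`. With `m0 = m` this equals plain BH.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @return Adjusted p values in `[0, 1]`, in the input order.
#' @export
adaptive_fdr_adjust <- function(pvals) {
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  m0 <- estimate_m0_lsl(pvals)
  ord <- order(pvals)
  ranks <- seq_len(m)
  adj_sorted <- rev(cummin(rev(m0 * pvals[ord] / ranks)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

#' Lowest-slope estimate of the number of true null hypotheses
#'
#' @inheritParams adaptive_fdr_adjust
#' @return Integer estimate `m0` in `[1, m]`.
#' @export
estimate_m0_lsl <- function(pvals) {
  m <- length(pvals)
  if (m == 0L) return(0L)
  ps <- sort(pvals)
  s <- (1 - ps) / (m + 1 - seq_len(m))
  if (m >= 2L) {
    for (j in 2:m) {
      if (s[j] < s[j - 1L]) {
        if (s[j] <= 0) return(m)
        return(as.integer(min(m, floor(1 / s[j]) + 1)))
      }
    }
  }
  m
}

# ---- goodness of fit -------------------------------------------------------

#' Penalized-likelihood goodness-of-fit measures
#'
#' AIC, BIC, AICc, HQIC, CAIC from the fit's (restricted/pseudo) log
#' likelihood `l`, parameter count `K` (fixed effects plus covariance
#' parameters), and observation count `N`. AICc is undefined (NA) when
#' `N <= K + 1`.
#'
#' @param fit A `twopart_fit`, or a list with elements `loglik`, `n_params`,
#'   `n_obs`.
#' @return Named numeric vector `c(AIC, BIC, AICc, HQIC, CAIC)`.
#' @export
gof_measures <- function(fit) {
  ll <- fit$loglik; K <- fit$n_params; N <- fit$n_obs
  aic <- -2 * ll + 2 * K
  bic <- -2 * ll + K * log(N)
  aicc <- if (N > K + 1) aic + 2 * K * (K + 1) / (N - K - 1) else NA_real_
  hqic <- -2 * ll + 2 * K * log(log(N))
  caic <- -2 * ll + K * (log(N) + 1)
  c(AIC = aic, BIC = bic, AICc = aicc, HQIC = hqic, CAIC = caic)
}

# ---- degree selection ------------------------------------------------------

#' Candidate polynomial degrees for the selection grid
#'
#' @param min_degree,max_degree Inclusive integer bounds.
#' @return Integer vector of candidate degrees.
#' @export
degree_grid <- function(min_degree, max_degree) {
  if (max_degree < min_degree) stop("empty degree range")
  seq.int(as.integer(min_degree), as.integer(max_degree))
}

#' Select the temporal polynomial degree
#'
#' Fits both model parts at every degree in the grid, tabulates the five GOF
#' criteria and the covariate-of-interest estimates per degree, and chooses
#' the midpoint (rounded down) of the longest contiguous run of degrees whose
#' key estimates are mutually consistent: every consecutive pair in the run
#' changes by less than `consistency_tol` in relative terms. Ties go to the
#' run appearing first (smaller degrees). Degrees that fail to fit are
#' recorded and excluded.
#'
#' @inheritParams fit_presence_model
#' @param degrees Integer vector of candidate degrees (e.g.
#'   `degree_grid(3, 18)`).
#' @param consistency_tol Relative-change threshold defining "consistent"
#'   neighboring degrees (default 0.1).
#' @return List with `chosen` (selected degree), `gof` (data frame: degree,
#'   part, the five criteria, converged), `estimates` (data frame of key
#'   COI-related estimates and p values per degree), `fits` (list of the
#'   per-degree two-part fits).
#' @export
degree_selection <- function(design, spec = attr(design, "model_spec"),
                             degrees = degree_grid(3, 18),
                             consistency_tol = 0.1) {
  if (length(degrees) == 0L) stop("degree grid is empty")
  gof_rows <- list(); est_rows <- list(); fits <- list()
  ok <- logical(length(degrees))
  key_mat <- list()
  for (i in seq_along(degrees)) {
    n <- degrees[i]
    sp <- spec
    sp$poly_degree <- as.integer(n)
    res <- tryCatch(fit_twopart(design, sp), error = function(e) e)
    if (inherits(res, "error")) {
      gof_rows[[length(gof_rows) + 1L]] <- data.frame(
        degree = n, part = "presence", AIC = NA, BIC = NA, AICc = NA,
        HQIC = NA, CAIC = NA, converged = FALSE)
      next
    }
    ok[i] <- res$presence$converged && res$strength$converged
    fits[[as.character(n)]] <- res
    for (part in c("presence", "strength")) {
      g <- res[[part]]$gof
      gof_rows[[length(gof_rows) + 1L]] <- data.frame(
        degree = n, part = part, AIC = g["AIC"], BIC = g["BIC"],
        AICc = g["AICc"], HQIC = g["HQIC"], CAIC = g["CAIC"],
        converged = res[[part]]$converged, row.names = NULL)
      b <- res[[part]]$beta
      coi_rows <- b[grepl(paste0("^", spec$coi), b$parameter), ]
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        degree = n, part = part, parameter = coi_rows$parameter,
        estimate = coi_rows$estimate, p_raw = coi_rows$p_raw,
        p_adj = coi_rows$p_adj, row.names = NULL)
    }
    key_mat[[as.character(n)]] <- unlist(lapply(c("presence", "strength"),
      function(part) {
        b <- res[[part]]$beta
        b$estimate[grepl(paste0("^", spec$coi), b$parameter)]
      }))
  }
  usable <- degrees[ok]
  if (length(usable) == 0L) stop("no degree produced a converged fit")
  # longest contiguous run of mutually consistent key-estimate vectors
  consistent_pair <- function(a, b) {
    v1 <- key_mat[[as.character(a)]]; v2 <- key_mat[[as.character(b)]]
    all(abs(v1 - v2) / pmax(abs(v1), abs(v2), 0.01) < consistency_tol)
  }
  best_run <- usable[1L]; run <- usable[1L]
  if (length(usable) > 1L) {
    for (i in 2:length(usable)) {
      if (consistent_pair(usable[i - 1L], usable[i])) {
        run <- c(run, usable[i])
      } else {
        run <- usable[i]
      }
      if (length(run) > length(best_run)) best_run <- run
    }
  }
  chosen <- best_run[floor((length(best_run) + 1) / 2)]
  list(chosen = chosen,
       gof = do.call(rbind, gof_rows),
       estimates = do.call(rbind, est_rows),
       fits = fits)
}
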