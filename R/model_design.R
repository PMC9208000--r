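# Orthonormal polynomial temporal basis, Fisher Z-transform, model
# specification, and assembly of the dyad x window long-format design table.

#' Orthonormal polynomial basis over window indices
#'
#' QR orthonormalization of the centered monomials `(t - mean(t))^o`,
#' `o = 1..n`, evaluated at `t = 1..T`. Columns have unit Euclidean norm, are
#' mutually orthogonal and orthogonal to the constant vector (the model's
#' intercept plays the degree-0 role). Sign convention: each column's leading
#' (highest-order) coefficient is positive.
#'
#' @param T_windows Number of window indices T.
#' @param degree_n Maximum polynomial degree n, `1 <= n <= T - 1`.
#' @return An object of class `ortho_basis`: list with `times` (1..T),
#'   `degree_n`, and `S`, a T x n matrix whose column o holds the degree-o
#'   polynomial values `s_(o)(t)`.
#' @export
orthonormal_basis <- function(T_windows, degree_n) {
  T_windows <- as.integer(T_windows)
  degree_n <- as.integer(degree_n)
  if (degree_n < 1L) stop("degree_n must be >= 1")
  if (degree_n >= T_windows)
    stop("degree_n must be < T (rank deficiency)")
  t <- seq_len(T_windows)
  tc <- t - mean(t)
  V <- outer(tc, 0:degree_n, `^`)  # constant column first
  qrd <- qr(V)
  Q <- qr.Q(qrd)
  R <- qr.R(qrd)
  # make diag(R) positive so each column's leading coefficient is positive
  sgn <- sign(diag(R))
  sgn[sgn == 0] <- 1
  Q <- sweep(Q, 2L, sgn, `*`)
  S <- Q[, -1L, drop = FALSE]
  colnames(S) <- paste0("s", seq_len(degree_n))
  structure(list(times = t, degree_n = degree_n, S = S),
            class = "ortho_basis")
}

#' @export
print.ortho_basis <- function(x, ...) {
  cat(sprintf("<ortho_basis> T = %d window indices, degree n = %d\n",
              length(x$times), x$degree_n))
  invisible(x)
}

#' Fisher Z-transform and its inverse
#'
#' `fisher_z(y) = atanh(y)` stabilizes/normalizes correlations in `[0, 1)`;
#' `inverse_fisher_z(z) = tanh(z)` maps back.
#'
#' @param y Correlation value(s), `|y| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(y) {
  if (any(abs(y) >= 1, na.rm = TRUE))
    stop("fisher_z requires |y| < 1")
  atanh(y)
}

#' @rdname fisher_z
#' @param z Real value(s) on the Fisher-Z scale.
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Two-part model specification
#'
#' Declares the covariate of interest, confounders, temporal polynomial
#' degree, and the random-effect structure shared by the presence and strength
#' parts. The five endogenous network terms (`C_avg`, `E_avg`, `l_avg`,
#' `k_diff`, `Q`) and the spatial-distance confounders (`dist`, `dist2`) are
#' always included as fixed effects.
#'
#' @param coi Name of the covariate of interest (a phenotype column).
#' @param coi_type `"continuous"` or `"binary"`.
#' @param confounders Named list declaring confounder types: each element is
#'   `"continuous"`, `"binary"`, or a character vector of >= 2 levels for a
#'   categorical confounder (reference-cell coding, first level = reference).
#' @param poly_degree Temporal polynomial degree n (>= 0; 0 disables the
#'   temporal trend, reducing to a static-model structure).
#' @param random_terms Subset of `c("intercept", "net", "dist", "nodal")`
#'   naming the participant-level random-effect families; `"nodal"` enables
#'   per-node connection-propensity terms (off by default: they commonly cause
#'   convergence problems at scale).
#' @param include_poly_random Include participant-level polynomial deviation
#'   terms (one independent variance per degree)?
#' @param standardize Z-score continuous covariates before fitting?
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(coi, coi_type = c("continuous", "binary"),
                       confounders = list(),
                       poly_degree = 2L,
                       random_terms = c("intercept"),
                       include_poly_random = TRUE,
                       standardize = FALSE) {
  coi_type <- match.arg(coi_type)
  poly_degree <- as.integer(poly_degree)
  if (poly_degree < 0L) stop("poly_degree must be >= 0")
  bad <- setdiff(random_terms, c("intercept", "net", "dist", "nodal"))
  if (length(bad)) stop("unknown random terms: ", paste(bad, collapse = ", "))
  for (nm in names(confounders)) {
    cf <- confounders[[nm]]
    if (is.character(cf) && length(cf) > 1L) {
      if (length(cf) < 2L) stop("categorical confounder '", nm,
                                "' needs >= 2 levels")
    } else if (!identical(cf, "continuous") && !identical(cf, "binary")) {
      stop("confounder '", nm,
           "' must be 'continuous', 'binary', or a vector of levels")
    }
  }
  structure(
    list(coi = coi, coi_type = coi_type,
         net_terms = c("C_avg", "E_avg", "l_avg", "k_diff", "Q"),
         confounders = confounders, poly_degree = poly_degree,
         random_terms = random_terms,
         include_poly_random = include_poly_random,
         standardize = standardize),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat("  covariate of interest:", x$coi, sprintf("(%s)\n", x$coi_type))
  cat("  confounders:", if (length(x$confounders))
    paste(names(x$confounders), collapse = ", ") else "none", "\n")
  cat("  polynomial degree:", x$poly_degree, "\n")
  cat("  random terms:", paste(x$random_terms, collapse = ", "),
      if (x$include_poly_random) "+ polynomial deviations" else "", "\n")
  invisible(x)
}

# names of fixed-effect columns (excluding intercept and polynomial columns)
.fixed_terms <- function(spec) {
  conf_cols <- character(0)
  for (nm in names(spec$confounders)) {
    cf <- spec$confounders[[nm]]
    if (is.character(cf) && length(cf) > 1L) {
      conf_cols <- c(conf_cols, paste0(nm, "_", cf[-1L]))
    } else {
      conf_cols <- c(conf_cols, nm)
    }
  }
  c(spec$net_terms, spec$coi,
    paste0(spec$coi, "_x_", spec$net_terms),
    conf_cols, "dist", "dist2")
}

# encode phenotype/confounder columns onto the design rows
.encode_phenotypes <- function(design, phenotypes, spec) {
  if (anyDuplicated(phenotypes$participant))
    stop("duplicate participants in phenotype table")
  miss <- setdiff(unique(design$participant), phenotypes$participant)
  if (length(miss))
    stop("phenotype missing for participant(s): ",
         paste(miss, collapse = ", "))
  idx <- match(design$participant, phenotypes$participant)
  needed <- c(spec$coi, names(spec$confounders))
  absent <- setdiff(needed, names(phenotypes))
  if (length(absent))
    stop("phenotype table lacks column(s): ", paste(absent, collapse = ", "))
  for (nm in needed) {
    v <- phenotypes[[nm]][idx]
    if (anyNA(v)) stop("missing phenotype values in column '", nm, "'")
    cf <- if (nm == spec$coi) spec$coi_type else spec$confounders[[nm]]
    if (is.character(cf) && length(cf) > 1L) {   # categorical
      v <- as.character(v)
      unseen <- setdiff(unique(v), cf)
      if (length(unseen))
        stop("confounder '", nm, "' has undeclared level(s): ",
             paste(unseen, collapse = ", "))
      for (lev in cf[-1L])
        design[[paste0(nm, "_", lev)]] <- as.numeric(v == lev)
    } else {
      design[[nm]] <- as.numeric(v)
    }
  }
  design
}

#' Assemble the dyad x window design table
#'
#' Produces one row per (participant, dyad j < k, window t) carrying the
#' presence indicator `R`, raw weight `Y`, Fisher-Z strength `S` (defined only
#' where `R = 1`), the endogenous dyad covariates, the encoded phenotypes,
#' COI-by-network interactions, and the orthonormal polynomial values at the
#' row's window index.
#'
#' @param nets_list List of thresholded `dyn_nets` objects (all with the same
#'   window count and node labels).
#' @param dyadcov Output of [dyad_covariates()] aligned with `nets_list`.
#' @param phenotypes Data frame with a `participant` column plus the declared
#'   phenotype columns (one row per participant).
#' @param spec A [model_spec()].
#' @return An object of class `dyad_design` (a data.frame with attributes
#'   `model_spec` and `basis`).
#' @export
assemble_design <- function(nets_list, dyadcov, phenotypes, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(nets_list, "dyn_nets")) nets_list <- list(nets_list)
  W_count <- length(nets_list[[1L]]$windows)
  labels <- nets_list[[1L]]$node_labels
  P <- length(labels)
  pair <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  rows <- list(); idx <- 1L
  for (nets in nets_list) {
    if (length(nets$windows) != W_count)
      stop("all participants must share the window count")
    if (!identical(nets$node_labels, labels))
      stop("all participants must share node labels")
    for (w in seq_len(W_count)) {
      M <- nets$windows[[w]]
      y <- M[pair]
      rows[[idx]] <- data.frame(
        participant = nets$participant_id, window = w,
        node_j = labels[pair[, 1L]], node_k = labels[pair[, 2L]],
        Y = y, stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  design <- do.call(rbind, rows)
  design$R <- as.integer(design$Y > 0)
  design$S <- ifelse(design$R == 1L, fisher_z(design$Y), NA_real_)
  key <- c("participant", "window", "node_j", "node_k")
  m <- merge(design, dyadcov, by = key, sort = FALSE)
  if (nrow(m) != nrow(design))
    stop("dyad covariates do not align with the networks")
  design <- m[order(m$participant, m$window, m$node_j, m$node_k), ]
  design <- .encode_phenotypes(design, phenotypes, spec)
  for (nt in spec$net_terms)
    design[[paste0(spec$coi, "_x_", nt)]] <- design[[spec$coi]] * design[[nt]]
  basis <- NULL
  if (spec$poly_degree > 0L) {
    basis <- orthonormal_basis(W_count, spec$poly_degree)
    for (o in seq_len(spec$poly_degree))
      design[[paste0("s", o)]] <- basis$S[design$window, o]
  }
  rownames(design) <- NULL
  structure(design, model_spec = spec, basis = basis,
            class = c("dyad_design", "data.frame"))
}

#' Count random-effects variance parameters (non-polynomial families)
#'
#' Under the full specification the participant-level random effects comprise
#' one intercept variance, one variance per network-term slope, one per
#' distance slope (`dist`, `dist2`), and — when nodal propensities are enabled
#' — one per node.
#'
#' @param spec A [model_spec()].
#' @param P Number of nodes (needed when `"nodal"` is a random term).
#' @return Integer count of non-polynomial variance parameters per model part.
#' @export
count_variance_parameters <- function(spec, P = NULL) {
  n <- 0L
  if ("intercept" %in% spec$random_terms) n <- n + 1L
  if ("net" %in% spec$random_terms) n <- n + length(spec$net_terms)
  if ("dist" %in% spec$random_terms) n <- n + 2L
  if ("nodal" %in% spec$random_terms) {
    if (is.null(P)) stop("P required when nodal propensities are random")
    n <- n + as.integer(P)
  }
  n
}
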