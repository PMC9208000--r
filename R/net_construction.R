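# Dynamic network construction: prewhitening, sliding-window correlation,
# nonnegativity thresholding.

#' ROI time-series container
#'
#' Bundle a participant's region-of-interest (ROI) time-series matrix with its
#' node labels. Rows are acquisition volumes (time), columns are regions.
#'
#' @param data Numeric T x P matrix (T volumes, P regions), all values finite.
#' @param participant_id Opaque participant label.
#' @param node_labels Character vector of P unique region labels. Defaults to
#'   the column names of `data`, or `"V1"..."VP"` when absent.
#' @param sampling_interval Optional sampling interval in seconds (metadata
#'   only; no computation depends on it).
#'
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, participant_id = "participant",
                   node_labels = NULL, sampling_interval = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("ROI time series contains non-finite values")
  if (nrow(data) < 2L) stop("need at least 2 timepoints (rows)")
  if (ncol(data) < 2L) stop("need at least 2 nodes (columns)")
  if (is.null(node_labels)) {
    node_labels <- colnames(data)
    if (is.null(node_labels)) node_labels <- paste0("V", seq_len(ncol(data)))
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != ncol(data))
    stop("node_labels length must match number of columns")
  if (anyDuplicated(node_labels))
    stop("node_labels must be unique")
  colnames(data) <- node_labels
  structure(
    list(participant_id = as.character(participant_id), data = data,
         node_labels = node_labels, sampling_interval = sampling_interval),
    class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> participant '%s': %d volumes x %d nodes\n",
              x$participant_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Sliding-window specification
#'
#' @param length_L Window length in volumes (>= 2).
#' @param shift Shift between consecutive window starts, in volumes (>= 1).
#'   `shift = length_L` gives non-overlapping windows.
#' @param weights Optional per-volume weight vector of length `length_L` for a
#'   tapered/modulated window; `NULL` means a plain rectangular (uniform)
#'   window.
#'
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_L, shift = length_L, weights = NULL) {
  length_L <- as.integer(length_L)
  shift <- as.integer(shift)
  if (length_L < 2L) stop("length_L must be >= 2")
  if (shift < 1L) stop("shift must be >= 1")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length_L)
      stop("weights must have length length_L")
    if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0)
      stop("weights must be nonnegative, finite, with positive sum")
  }
  structure(list(length_L = length_L, shift = shift, weights = weights),
            class = "window_spec")
}

#' Number and start indices of sliding windows
#'
#' `W = floor((T - L)/shift) + 1` windows; 1-based inclusive start indices.
#' Windows that would extend past `T` are not emitted.
#'
#' @param T_total Total number of volumes.
#' @param spec A [window_spec()].
#' @return Integer vector of window start indices (length W).
#' @export
window_starts <- function(T_total, spec) {
  stopifnot(inherits(spec, "window_spec"))
  T_total <- as.integer(T_total)
  if (spec$length_L > T_total)
    stop("window length exceeds series length")
  W <- (T_total - spec$length_L) %/% spec$shift + 1L
  seq.int(1L, by = spec$shift, length.out = W)
}

#' Prewhiten ROI time series by autoregressive residualization
#'
#' Removes serial autocorrelation before sliding-window correlation by fitting
#' an AR(p) model per node via least squares and keeping the standardized
#' residuals. With `ar_order = 0` the series is mean-centered and scaled to
#' unit variance but otherwise untouched.
#'
#' @param ts A [roi_ts()].
#' @param ar_order Autoregressive order p >= 0 (default 1).
#' @return A [roi_ts()] of length `T - ar_order`, each node's residual series
#'   having mean 0 and variance 1.
#' @export
prewhiten <- function(ts, ar_order = 1L) {
  stopifnot(inherits(ts, "roi_ts"))
  ar_order <- as.integer(ar_order)
  if (ar_order < 0L) stop("ar_order must be >= 0")
  X <- ts$data
  T_total <- nrow(X)
  if (T_total <= ar_order + 1L)
    stop("series too short for requested ar_order")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) node series: ",
         paste(ts$node_labels[sds == 0], collapse = ", "))
  if (ar_order == 0L) {
    out <- scale(X)
  } else {
    p <- ar_order
    n_res <- T_total - p
    out <- matrix(0, n_res, ncol(X))
    # lagged design shared across nodes only in shape; built per node
    for (j in seq_len(ncol(X))) {
      x <- X[, j]
      L <- sapply(seq_len(p), function(l) x[(p - l + 1L):(T_total - l)])
      fit <- stats::lm.fit(cbind(1, L), x[(p + 1L):T_total])
      r <- fit$residuals
      s <- stats::sd(r)
      if (s == 0)
        stop("prewhitening produced a constant residual series for node ",
             ts$node_labels[j])
      out[, j] <- (r - mean(r)) / s
    }
  }
  out <- as.matrix(out)
  dimnames(out) <- list(NULL, ts$node_labels)
  roi_ts(out, participant_id = ts$participant_id,
         node_labels = ts$node_labels,
         sampling_interval = ts$sampling_interval)
}

# weighted Pearson correlation matrix of the rows [i0, i0+L-1]; uniform
# weights reduce exactly to ordinary Pearson
.window_correlation <- function(X, i0, L, w = NULL) {
  S <- X[i0:(i0 + L - 1L), , drop = FALSE]
  if (is.null(w)) {
    sds <- apply(S, 2L, stats::sd)
    const <- sds == 0
    if (any(const)) {
      R <- matrix(0, ncol(S), ncol(S))
      ok <- !const
      if (sum(ok) >= 2L)
        R[ok, ok] <- stats::cor(S[, ok, drop = FALSE])
    } else {
      R <- stats::cor(S)
    }
  } else {
    w <- w / sum(w)
    mu <- colSums(S * w)
    Sc <- sweep(S, 2L, mu)
    cv <- crossprod(Sc * w, Sc)  # weighted covariance (normalized weights)
    v <- diag(cv)
    const <- v <= 0
    d <- sqrt(pmax(v, .Machine$double.eps))
    R <- cv / tcrossprod(d)
    R[const, ] <- 0
    R[, const] <- 0
  }
  diag(R) <- 0
  # exact symmetry at machine precision
  R <- (R + t(R)) / 2
  attr(R, "constant_nodes") <- which(apply(S, 2L, stats::sd) == 0)
  R
}

#' Sliding-window correlation networks
#'
#' Moves a window across the time series and computes the (window-weighted)
#' Pearson correlation between all node pairs at each shift, yielding one
#' symmetric zero-diagonal matrix per window. Correlations of exactly 1
#' (duplicated series) are clipped to `1 - 1e-12` so the Fisher Z-transform
#' stays finite downstream.
#'
#' @param ts A [roi_ts()] (typically prewhitened).
#' @param spec A [window_spec()].
#' @return An object of class `dyn_nets`: list with `participant_id`,
#'   `windows` (list of P x P matrices), `window_starts`, `node_labels`.
#' @export
sliding_window_correlate <- function(ts, spec) {
  stopifnot(inherits(ts, "roi_ts"), inherits(spec, "window_spec"))
  starts <- window_starts(nrow(ts$data), spec)
  mats <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    R <- .window_correlation(ts$data, starts[i], spec$length_L, spec$weights)
    cn <- attr(R, "constant_nodes")
    if (length(cn))
      warning(sprintf(
        "window starting at %d: constant node series (%s); correlations set to 0",
        starts[i], paste(ts$node_labels[cn], collapse = ", ")))
    attr(R, "constant_nodes") <- NULL
    R <- pmin(R, 1 - 1e-12)
    R <- pmax(R, -(1 - 1e-12))
    dimnames(R) <- list(ts$node_labels, ts$node_labels)
    mats[[i]] <- R
  }
  structure(
    list(participant_id = ts$participant_id, windows = mats,
         window_starts = starts, node_labels = ts$node_labels),
    class = "dyn_nets")
}

#' @export
print.dyn_nets <- function(x, ...) {
  cat(sprintf("<dyn_nets> participant '%s': %d windows, %d nodes\n",
              x$participant_id, length(x$windows), length(x$node_labels)))
  invisible(x)
}

#' Remove negative correlations from dynamic networks
#'
#' Sets all strictly negative entries to zero; nonnegative entries, symmetry
#' and the zero diagonal are preserved. Network measures on signed graphs are
#' poorly understood, so downstream modeling uses nonnegative weights only.
#'
#' @param nets A `dyn_nets` object.
#' @return A `dyn_nets` object with weights in `[0, 1)`.
#' @export
threshold_nonnegative <- function(nets) {
  stopifnot(inherits(nets, "dyn_nets"))
  nets$windows <- lapply(nets$windows, function(M) {
    M[M < 0] <- 0
    M
  })
  nets
}

#' Build thresholded dynamic networks from one participant's time series
#'
#' Convenience wrapper: [prewhiten()] then [sliding_window_correlate()] then
#' [threshold_nonnegative()].
#'
#' @inheritParams prewhiten
#' @inheritParams sliding_window_correlate
#' @return A `dyn_nets` object with nonnegative weights.
#' @export
build_dynamic_networks <- function(ts, spec, ar_order = 1L) {
  threshold_nonnegative(sliding_window_correlate(prewhiten(ts, ar_order), spec))
}
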