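# Temporal preprocessing of ROI time series: volume discarding, linear
# detrending, band-pass filtering (0.01-0.08 Hz), nuisance regression.

#' Construct an ROI time-series object
#'
#' @param data numeric T x N matrix (rows = time points, columns = regions).
#' @param tr_seconds repetition time in seconds.
#' @param node_labels character vector of N region names; defaults to
#'   `aal90_labels()` when N = 90, else `"node_<i>"`.
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_seconds = 2, node_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop_wmhnet("time series contains missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop_wmhnet("tr_seconds must be a positive real")
  n <- ncol(data)
  if (is.null(node_labels))
    node_labels <- if (n == 90) aal90_labels() else paste0("node_", seq_len(n))
  if (length(node_labels) != n)
    stop_wmhnet(sprintf("%d node labels supplied for %d columns",
                        length(node_labels), n))
  colnames(data) <- node_labels
  structure(list(data = data, tr_seconds = tr_seconds,
                 node_labels = node_labels),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d time points x %d regions, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

as_roi <- function(ts) {
  if (!inherits(ts, "roi_timeseries"))
    stop_wmhnet("expected a roi_timeseries object")
  ts
}

#' Discard initial volumes
#'
#' Removes the first `n_discard` time points (magnetization equilibration
#' scans); labels and TR are unchanged.
#'
#' @param ts a [roi_timeseries()].
#' @param n_discard number of leading time points to drop (default 10).
#' @return A `roi_timeseries` with `T - n_discard` rows.
#' @export
discard_initial <- function(ts, n_discard = 10L) {
  ts <- as_roi(ts)
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop_wmhnet("n_discard must be >= 0")
  if (nrow(ts$data) <= n_discard)
    stop_wmhnet(sprintf("cannot discard %d of %d time points",
                        n_discard, nrow(ts$data)))
  if (n_discard == 0L) return(ts)
  roi_timeseries(ts$data[-seq_len(n_discard), , drop = FALSE],
                 ts$tr_seconds, ts$node_labels)
}

#' Remove linear trends
#'
#' Per column, subtracts the least-squares line (intercept + slope * t);
#' residuals have zero mean and zero linear trend.
#'
#' @inheritParams discard_initial
#' @return Detrended `roi_timeseries`.
#' @export
detrend_linear <- function(ts) {
  ts <- as_roi(ts)
  nt <- nrow(ts$data)
  if (nt < 3L) stop_wmhnet("need at least 3 time points to detrend")
  X <- cbind(1, seq_len(nt))
  res <- ts$data - X %*% qr.coef(qr(X), ts$data)
  roi_timeseries(res, ts$tr_seconds, ts$node_labels)
}

#' Band-pass filter ROI time series
#'
#' Zero-phase Butterworth band-pass (default 0.01-0.08 Hz, the standard
#' resting-state BOLD band) applied column-wise; see [butter_bandpass()].
#'
#' @inheritParams discard_initial
#' @param low_hz,high_hz pass-band edges in Hz.
#' @param order Butterworth prototype order.
#' @return Filtered `roi_timeseries`, length unchanged.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08, order = 4L) {
  ts <- as_roi(ts)
  co <- butter_bandpass(low_hz, high_hz, fs = 1 / ts$tr_seconds, order = order)
  roi_timeseries(filtfilt_mat(co$b, co$a, ts$data), ts$tr_seconds,
                 ts$node_labels)
}

#' Confound regressor set
#'
#' @param regressors numeric T x K matrix of nuisance signals (e.g. six
#'   head-motion parameters, global, white-matter and CSF signals).
#' @param names optional K regressor names.
#' @return Object of class `confound_set`.
#' @export
confound_set <- function(regressors, names = NULL) {
  regressors <- as.matrix(regressors)
  if (length(regressors) == 0)
    regressors <- matrix(numeric(0), nrow = NROW(regressors), ncol = 0)
  storage.mode(regressors) <- "double"
  if (anyNA(regressors)) stop_wmhnet("confounds contain missing values")
  k <- ncol(regressors)
  if (is.null(names)) names <- colnames(regressors)
  if (is.null(names) && k > 0) names <- paste0("confound_", seq_len(k))
  if (k > 0 && length(names) != k)
    stop_wmhnet("confound names do not match column count")
  colnames(regressors) <- names
  structure(list(regressors = regressors, names = names),
            class = "confound_set")
}

#' Regress out nuisance signals
#'
#' Replaces each column with its OLS residual on an intercept plus the
#' confound columns; residuals are orthogonal to every confound.  With an
#' empty confound set this reduces to mean-centering.
#'
#' @inheritParams discard_initial
#' @param confounds a [confound_set()] with T rows.
#' @return Residualized `roi_timeseries`.
#' @export
regress_nuisance <- function(ts, confounds) {
  ts <- as_roi(ts)
  if (!inherits(confounds, "confound_set"))
    confounds <- confound_set(confounds)
  nt <- nrow(ts$data)
  R <- confounds$regressors
  if (ncol(R) > 0 && nrow(R) != nt)
    stop_wmhnet(sprintf("confounds have %d rows but series has %d time points",
                        nrow(R), nt))
  X <- cbind(`(intercept)` = rep(1, nt), R)
  if (nt <= ncol(X))
    stop_wmhnet("need more time points than regressors (plus intercept)")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop_wmhnet("rank-deficient confound design; collinear columns: ",
                paste(dropped, collapse = ", "))
  }
  res <- ts$data - X %*% qr.coef(qx, ts$data)
  roi_timeseries(res, ts$tr_seconds, ts$node_labels)
}

#' Full temporal preprocessing pipeline
#'
#' Runs discard -> detrend -> band-pass -> nuisance regression; each step
#' can be toggled.  Column count and node labels are preserved.
#'
#' @inheritParams bandpass
#' @param n_discard leading volumes to drop (0 disables).
#' @param confounds optional [confound_set()] (row count must match the
#'   series *after* discarding).
#' @param do_detrend,do_bandpass logical stage toggles.
#' @return Preprocessed `roi_timeseries`.
#' @export
preprocess_timeseries <- function(ts, n_discard = 10L, do_detrend = TRUE,
                                  do_bandpass = TRUE, low_hz = 0.01,
                                  high_hz = 0.08, confounds = NULL) {
  ts <- as_roi(ts)
  if (n_discard > 0L) ts <- discard_initial(ts, n_discard)
  if (do_detrend) ts <- detrend_linear(ts)
  if (do_bandpass) ts <- bandpass(ts, low_hz, high_hz)
  if (!is.null(confounds)) ts <- regress_nuisance(ts, confounds)
  ts
}
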