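# Per-subject metric profiles across the sparsity grid, plus the
# across-threshold summary (arithmetic mean of the per-threshold values,
# the convention that reproduces published summary figures; an AUC-style
# summary, mean x grid width, is available as an option).

#' Global metric profile across a sparsity grid
#'
#' Thresholds the connectivity matrix at every sparsity in `grid` and
#' computes Cp, Lp, Eglob, Eloc and (when `null_params` is supplied) the
#' small-world ratios gamma, lambda, sigma against degree-preserving
#' nulls.  The summary row is the arithmetic mean of each column across
#' thresholds.
#'
#' @param z a `connectivity_matrix` (typically Fisher z).
#' @param grid a [sparsity_grid()].
#' @param null_params a [null_ensemble_params()], or `NULL` to skip the
#'   random-network normalization (gamma/lambda/sigma become `NA`).
#' @param keep edge-retention rule, see [binarize_at_sparsity()].
#' @return Object of class `global_metric_profile`: a list with
#'   `per_threshold` (data frame, one row per sparsity), `summary`
#'   (named numeric means) and `auc` (means scaled by grid width).
#' @export
global_profile <- function(z, grid = sparsity_grid(), null_params = NULL,
                           keep = c("positive", "absolute")) {
  keep <- match.arg(keep)
  nets <- sparsity_sweep(z, grid, keep)
  rows <- lapply(seq_along(nets), function(i) {
    net <- nets[[i]]
    m <- binary_metrics(net)
    if (!is.null(null_params)) {
      np <- null_params
      np$seed <- derive_seeds(null_params$seed, length(nets))[i]
      sw <- small_world_indices(net, np)
      gamma <- sw$gamma; lambda <- sw$lambda; sigma <- sw$sigma
    } else gamma <- lambda <- sigma <- NA_real_
    data.frame(sparsity = net$sparsity, cp = m$cp, lp = m$lp,
               gamma = gamma, lambda = lambda, sigma = sigma,
               eglob = m$eglob, eloc = m$eloc,
               connected = net$connected)
  })
  per <- do.call(rbind, rows)
  metric_cols <- c("cp", "lp", "gamma", "lambda", "sigma", "eglob", "eloc")
  summ <- colMeans(per[metric_cols])
  width <- diff(range(as.numeric(grid)))
  structure(list(per_threshold = per, summary = summ,
                 auc = summ * width, grid = as.numeric(grid)),
            class = "global_metric_profile")
}

#' @export
print.global_metric_profile <- function(x, digits = 3, ...) {
  cat("<global_metric_profile>\n")
  print(round(x$per_threshold[seq_len(min(8, nrow(x$per_threshold))),
                              1:8], digits))
  cat("across-threshold means:\n")
  print(round(x$summary, digits))
  invisible(x)
}

#' Nodal metric profile across a sparsity grid
#'
#' Per node: nodal efficiency and nodal local efficiency at each
#' threshold, plus their across-threshold means.
#'
#' @inheritParams global_profile
#' @return Object of class `nodal_metric_profile`: list with matrices
#'   `nodal_e` and `nodal_eloc` (nodes x thresholds) and data frame
#'   `summary` (`label`, `nodal_e_mean`, `nodal_eloc_mean`).
#' @export
nodal_profile <- function(z, grid = sparsity_grid(),
                          keep = c("positive", "absolute")) {
  keep <- match.arg(keep)
  nets <- sparsity_sweep(z, grid, keep)
  ms <- lapply(nets, binary_metrics)
  ne <- sapply(ms, `[[`, "nodal_e")
  nl <- sapply(ms, `[[`, "nodal_eloc")
  colnames(ne) <- colnames(nl) <- paste0("s", as.numeric(grid))
  rownames(ne) <- rownames(nl) <- z$node_labels
  structure(list(nodal_e = ne, nodal_eloc = nl,
                 summary = data.frame(label = z$node_labels,
                                      nodal_e_mean = rowMeans(ne),
                                      nodal_eloc_mean = rowMeans(nl),
                                      row.names = NULL),
                 grid = as.numeric(grid)),
            class = "nodal_metric_profile")
}
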