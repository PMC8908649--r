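# Group-level analysis tables: global-metric comparisons (FDR over the
# 7 global metrics), per-node NodalE comparisons (FDR over nodes),
# WMH-volume vs nodal local-efficiency correlations, and partial
# correlations of significant nodal metrics with cognition.

global_metric_names <- c("cp", "lp", "gamma", "lambda", "sigma",
                         "eglob", "eloc")

comparison_row <- function(cmp) {
  data.frame(metric = cmp$metric_name,
             group_a = cmp$group_a_summary, group_b = cmp$group_b_summary,
             mean_a = cmp$mean_a, mean_b = cmp$mean_b,
             test_used = cmp$test_used, statistic = cmp$statistic,
             p_raw = cmp$p_raw, stringsAsFactors = FALSE)
}

#' Run the full group analysis
#'
#' Produces the four result tables of the workflow:
#' `global` -- two-group comparisons of the across-threshold summary of
#' each global metric, FDR-corrected within the family of global
#' metrics, with logistic age adjustment for significant metrics;
#' `nodal` -- per-node NodalE comparisons, FDR-corrected across nodes;
#' `volume_corr` -- Pearson correlation of WMH volume with each node's
#' local efficiency; `cognition_corr` -- partial correlations (covariates
#' age, sex, education) of the FDR-significant nodes' NodalE with MoCA
#' and MMSE.
#'
#' @param subjects subjects data frame (needs `group`, `wmh_volume_ml`,
#'   `age`, `sex`, `education_years`, `moca`, `mmse`).
#' @param global_summaries subjects x metrics data frame of
#'   across-threshold summary values (columns named as in
#'   `c("cp","lp","gamma","lambda","sigma","eglob","eloc")`; missing
#'   columns are skipped).
#' @param nodal_e subjects x nodes matrix of across-threshold mean nodal
#'   efficiency (column names = node labels).
#' @param nodal_eloc subjects x nodes matrix of nodal local efficiency.
#' @param alpha significance level (default 0.05).
#' @param cognition_fallback when no node survives FDR, correlate the
#'   smallest-raw-p node with cognition anyway (flagged); default TRUE so
#'   the table is never silently empty.
#' @return List of class `group_analysis` with the four data frames.
#' @export
run_group_analysis <- function(subjects, global_summaries, nodal_e,
                               nodal_eloc, alpha = 0.05,
                               cognition_fallback = TRUE) {
  need <- c("group", "wmh_volume_ml", "age", "sex", "education_years",
            "moca", "mmse")
  missing <- setdiff(need, names(subjects))
  if (length(missing))
    stop_wmhnet("subjects table missing column(s): ",
                paste(missing, collapse = ", "))
  ia <- subjects$group == "A"
  ib <- subjects$group == "B"
  if (!any(ia) || !any(ib)) stop_wmhnet("both groups must be present")

  # (a) global metrics (skip columns that are absent or all-NA, e.g.
  # gamma/lambda/sigma when the null ensemble was disabled)
  metrics <- intersect(global_metric_names, names(global_summaries))
  metrics <- metrics[vapply(metrics, function(mn)
    all(is.finite(global_summaries[[mn]])), logical(1))]
  glob <- do.call(rbind, lapply(metrics, function(mn) {
    v <- global_summaries[[mn]]
    comparison_row(compare_groups(v[ia], v[ib], mn, alpha))
  }))
  glob$p_fdr <- fdr_adjust(glob$p_raw)
  glob$significant <- glob$p_fdr < alpha
  glob$age_adj_coef <- glob$age_adj_p <- NA_real_
  for (i in which(glob$significant)) {
    aa <- age_adjusted_group_effect(global_summaries[[glob$metric[i]]],
                                    subjects$group, subjects$age)
    glob$age_adj_coef[i] <- aa$coefficient
    glob$age_adj_p[i] <- aa$p
  }

  # (b) nodal efficiency, FDR across nodes
  nodal_e <- as.matrix(nodal_e)
  labels <- colnames(nodal_e)
  nod <- do.call(rbind, lapply(seq_along(labels), function(j) {
    comparison_row(compare_groups(nodal_e[ia, j], nodal_e[ib, j],
                                  labels[j], alpha))
  }))
  names(nod)[names(nod) == "metric"] <- "label"
  nod$p_fdr <- fdr_adjust(nod$p_raw)
  nod$significant <- nod$p_fdr < alpha

  # (c) WMH volume vs nodal local efficiency
  nodal_eloc <- as.matrix(nodal_eloc)
  vol <- do.call(rbind, lapply(seq_len(ncol(nodal_eloc)), function(j) {
    pw <- tryCatch(pearson_with_p(subjects$wmh_volume_ml,
                                  nodal_eloc[, j]),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(label = colnames(nodal_eloc)[j], r = pw$r, p = pw$p)
  }))
  ok <- !is.na(vol$p)
  vol$p_fdr <- NA_real_
  vol$p_fdr[ok] <- fdr_adjust(vol$p[ok])

  # (d) partial correlations of significant nodes' NodalE with cognition
  sig_nodes <- nod$label[nod$significant]
  fallback_used <- FALSE
  if (!length(sig_nodes) && cognition_fallback && nrow(nod) > 0) {
    sig_nodes <- nod$label[which.min(nod$p_raw)]
    fallback_used <- TRUE
  }
  covs <- data.frame(age = subjects$age,
                     sex = as.integer(factor(subjects$sex)) - 1L,
                     education = subjects$education_years)
  cog <- do.call(rbind, lapply(sig_nodes, function(lb) {
    v <- nodal_e[, lb]
    pm <- partial_correlation(v, subjects$moca, covs, lb, "moca")
    ps <- partial_correlation(v, subjects$mmse, covs, lb, "mmse")
    data.frame(label = lb, moca_r = pm$r, moca_p = pm$p,
               mmse_r = ps$r, mmse_p = ps$p,
               fdr_significant = !fallback_used)
  }))
  if (is.null(cog))
    cog <- data.frame(label = character(0), moca_r = numeric(0),
                      moca_p = numeric(0), mmse_r = numeric(0),
                      mmse_p = numeric(0), fdr_significant = logical(0))

  structure(list(global = glob, nodal = nod, volume_corr = vol,
                 cognition_corr = cog, alpha = alpha,
                 n_a = sum(ia), n_b = sum(ib)),
            class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  cat(sprintf("<group_analysis> n_A = %d, n_B = %d\n", x$n_a, x$n_b))
  cat("global metric comparisons:\n")
  print(x$global[c("metric", "group_a", "group_b", "test_used",
                   "p_raw", "p_fdr")], digits = 3)
  cat(sprintf("nodal comparisons: %d nodes, %d FDR-significant\n",
              nrow(x$nodal), sum(x$nodal$significant)))
  invisible(x)
}

#' Write the four analysis tables as CSV
#'
#' @param ga a `group_analysis`.
#' @param directory output directory.
#' @return Invisibly, the vector of file paths.
#' @export
write_group_analysis <- function(ga, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- c(global = "table3_global.csv", nodal = "table4_nodal.csv",
             volume_corr = "table5_volume_corr.csv",
             cognition_corr = "table6_cognition_corr.csv")
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(directory, files[[nm]])
    write.csv(ga[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
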