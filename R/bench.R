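#' Run all three rhythm callers and combine the calls
#'
#' Runs the parametric curve-fitting caller, the JTK-style rank test and the
#' MetaCycle-style JTK + Lomb-Scargle integration on the same dataset and
#' returns one row per gene carrying every method's statistics plus
#' per-method rhythmic flags and a combined flag. The combined call is the
#' union of the individual calls: \code{combine = "all"} (default) unites all
#' three methods, \code{combine = "circan_mc"} restricts the union to the
#' parametric caller and the MetaCycle-style integration.
#'
#' @param es an \code{\link{expression_set}}.
#' @param circan a \code{\link{circan_config}}.
#' @param np an \code{\link{np_config}}.
#' @param combine which calls enter the combined flag (see above).
#' @param verbose passed to \code{\link{run_circan}}.
#' @return data.frame, one row per input gene, with \code{circan_}-,
#'   \code{jtk_}- and \code{meta_}-prefixed columns, the Lomb-Scargle p-value,
#'   per-method rhythmic flags and \code{combined_rhythmic}.
#' @export
full_mode_analysis <- function(es, circan = circan_config(), np = np_config(),
                               combine = c("all", "circan_mc"), verbose = FALSE) {
  combine <- match.arg(combine)
  if (!inherits(es, "expression_set")) stop("es must be an expression_set", call. = FALSE)
  cr <- run_circan(es, circan, verbose = verbose)
  jt <- run_jtk(es, np)
  ls <- run_ls(es, np)
  mc <- meta_combine(jt, ls)
  stopifnot(identical(cr$gene, jt$gene), identical(cr$gene, mc$gene))
  out <- data.frame(gene = cr$gene, stringsAsFactors = FALSE)
  out$circan_shape <- cr$shape
  out$circan_amplitude <- cr$amplitude
  out$circan_period <- cr$period
  out$circan_phase <- cr$phase
  out$circan_r2 <- cr$r2
  out$circan_p <- cr$combined_p
  out$circan_q <- cr$combined_q
  out$jtk_p <- jt$p
  out$jtk_q <- jt$q
  out$jtk_period <- jt$best_period
  out$jtk_lag <- jt$best_lag
  out$jtk_tau <- jt$tau
  out$ls_p <- ls$p
  out$ls_q <- ls$q
  out$ls_period <- ls$best_period
  out$meta_p <- mc$p_meta
  out$meta_q <- mc$q_meta
  out$meta_period <- mc$period
  out$meta_phase <- mc$phase
  out$circan_rhythmic <- cr$rhythmic
  out$jtk_rhythmic <- !is.na(jt$q) & jt$q < np$q_threshold
  out$meta_rhythmic <- !is.na(mc$q_meta) & mc$q_meta < np$q_threshold
  out$combined_rhythmic <- if (combine == "all")
    out$circan_rhythmic | out$jtk_rhythmic | out$meta_rhythmic
  else
    out$circan_rhythmic | out$meta_rhythmic
  out
}

#' Confusion-matrix summary of rhythmicity calls against simulation truth
#'
#' @param calls logical vector of rhythmic calls named by gene, or a
#'   data.frame with columns \code{gene} and a logical call column (its name
#'   given by \code{flag}).
#' @param truth the truth data.frame from \code{\link{simulate_dataset}}
#'   (columns \code{gene} and \code{rhythmic}).
#' @param flag call column name when \code{calls} is a data.frame.
#' @return list of class \code{benchmark_summary}: tp, fp, fn, tn,
#'   sensitivity = TP/(TP+FN), fp_rate = FP/(truly non-rhythmic genes),
#'   fdr = FP/(TP+FP), and the called gene set.
#' @export
confusion <- function(calls, truth, flag = "combined_rhythmic") {
  if (is.data.frame(calls)) {
    if (!flag %in% names(calls)) stop("no column '", flag, "' in calls", call. = FALSE)
    calls <- stats::setNames(calls[[flag]], calls$gene)
  }
  if (is.null(names(calls))) stop("calls must be named by gene", call. = FALSE)
  if (!setequal(names(calls), truth$gene))
    stop("gene sets of calls and truth differ", call. = FALSE)
  calls <- calls[truth$gene]
  pos <- truth$rhythmic
  tp <- sum(calls & pos); fp <- sum(calls & !pos)
  fn <- sum(!calls & pos); tn <- sum(!calls & !pos)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
                 called = names(calls)[calls]),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_summary: TP=%d FP=%d FN=%d TN=%d | ",
                     "sensitivity=%.1f%% fp_rate=%.2f%% fdr=%.2f%%>\n"),
              x$tp, x$fp, x$fn, x$tn, 100 * x$sensitivity, 100 * x$fp_rate,
              100 * x$fdr))
  invisible(x)
}

#' Exclusive intersection sizes of named call sets (upset-plot semantics)
#'
#' Every element of the union is counted in exactly one cell: the cell of the
#' sets it belongs to and no others.
#'
#' @param call_sets named list (>= 2 entries) of character vectors.
#' @return data.frame with one row per non-empty combination: the
#'   \code{combo} label (set names joined by \code{"&"}), per-set membership
#'   columns and the exclusive \code{count}.
#' @export
overlap_counts <- function(call_sets) {
  if (!is.list(call_sets) || length(call_sets) < 2 || is.null(names(call_sets)))
    stop("call_sets must be a named list of >= 2 sets", call. = FALSE)
  sets <- lapply(call_sets, unique)
  universe <- unique(unlist(sets))
  if (length(universe) == 0)
    return(data.frame(combo = character(0), count = integer(0)))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1, paste, collapse = "")
  tab <- table(key)
  memb_rows <- memb[match(names(tab), key), , drop = FALSE]
  combo <- apply(memb_rows, 1, function(r) paste(names(sets)[r], collapse = "&"))
  out <- data.frame(combo = combo, memb_rows, count = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$count), , drop = FALSE]
}

#' Coefficient-of-variation diagnostics
#'
#' Between-time-point CV (sd over mean of the per-time-point means) proxies
#' the amplitude of a gene; the between-replicate CV (mean across time points
#' of the per-time-point CV across replicates) proxies technical/biological
#' noise. Both are computed on the original (pre-standardization) scale,
#' since the CV is scale-dependent; genes with a non-positive mean are
#' returned as NA.
#'
#' @param es an \code{\link{expression_set}} on a positive expression scale.
#' @return data.frame: gene, cv_timepoints, cv_replicates (NA with a warning
#'   when there is a single replicate).
#' @export
cv_diagnostics <- function(es) {
  if (!inherits(es, "expression_set")) stop("es must be an expression_set", call. = FALSE)
  tf <- factor(es$time)
  nrep <- table(tf)
  tp_means <- t(apply(es$x, 1, function(x) tapply(x, tf, mean)))
  cv_tp <- apply(tp_means, 1, function(m)
    if (mean(m) <= 0) NA_real_ else stats::sd(m) / mean(m))
  if (all(nrep < 2)) {
    warning("single replicate per time point: between-replicate CV undefined")
    cv_rep <- rep(NA_real_, nrow(es$x))
  } else {
    cv_rep <- apply(es$x, 1, function(x) {
      m <- tapply(x, tf, mean)
      s <- tapply(x, tf, stats::sd)
      ok <- m > 0 & !is.na(s)
      if (!any(ok)) NA_real_ else mean(s[ok] / m[ok])
    })
  }
  data.frame(gene = rownames(es$x), cv_timepoints = as.numeric(cv_tp),
             cv_replicates = as.numeric(cv_rep), stringsAsFactors = FALSE)
}
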