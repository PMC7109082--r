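#' Confusion matrix of panel vs exome TMB-high calls at one cut-off
#'
#' A sample is called TMB-high when its TMB is greater than or equal to
#' the cut-off; the same rule is applied to the panel and to the exome
#' value. The exome call is the reference: TP = both high, FP = panel
#' high only, FN = exome high only, TN = neither. Percentages are of the
#' whole cohort, and the misclassification rate is FP% + FN%.
#'
#' @param profiles profile data frame from [build_sample_profiles()].
#' @param panel panel column name.
#' @param cutoff mutations/Mb.
#' @return one-row data frame: panel, cutoff, tp, fp, tn, fn, tp_pct,
#'   fp_pct, tn_pct, fn_pct, misclassified_pct.
#' @export
confusion_at_cutoff <- function(profiles, panel, cutoff) {
  if (!panel %in% names(profiles)) {
    stop("unknown panel '", panel, "' in profiles", call. = FALSE)
  }
  if (nrow(profiles) == 0L) stop("empty cohort", call. = FALSE)
  p <- profiles[[panel]] >= cutoff
  e <- profiles$exome_tmb >= cutoff
  n <- nrow(profiles)
  tp <- sum(p & e); fp <- sum(p & !e); fn <- sum(!p & e); tn <- sum(!p & !e)
  pct <- function(x) 100 * x / n
  data.frame(panel = panel, cutoff = cutoff,
             tp = tp, fp = fp, tn = tn, fn = fn,
             tp_pct = pct(tp), fp_pct = pct(fp),
             tn_pct = pct(tn), fn_pct = pct(fn),
             misclassified_pct = pct(fp) + pct(fn),
             stringsAsFactors = FALSE)
}

#' Sweep high-TMB cut-offs over panels
#'
#' Produces the confusion-grid report: one row per panel and cut-off,
#' default cut-offs 5, 10, 20 and 40 mutations/Mb.
#'
#' @param profiles profile data frame.
#' @param panels panel column names; default all panel columns.
#' @param cutoffs numeric vector of cut-offs.
#' @return data frame of stacked [confusion_at_cutoff()] rows.
#' @export
cutoff_sweep <- function(profiles, panels = panel_columns(profiles),
                         cutoffs = c(5, 10, 20, 40)) {
  if (nrow(profiles) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(length(panels) > 0L, all(cutoffs > 0))
  rows <- lapply(panels, function(pn) {
    do.call(rbind, lapply(cutoffs, function(co)
      confusion_at_cutoff(profiles, pn, co)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shared threshold sweep on scores vs binary labels. Returns the
# staircase over distinct score thresholds (descending), with a +Inf
# sentinel so the curve starts at (0, 0).
roc_sweep <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- sum(labels); neg <- sum(!labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call <- scores >= thr[i]
    tpr[i] <- sum(call & labels) / pos
    fpr[i] <- sum(call & !labels) / neg
  }
  list(thresholds = thr, tpr = tpr, fpr = fpr)
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' Accuracy-optimal classification threshold for scores vs labels
#'
#' Scans every achievable decision rule of the form `score >= t` (plus
#' the all-positive and all-negative rules) and returns the threshold
#' maximizing the fraction of correctly classified samples. Ties are
#' broken by the lowest threshold. The reported threshold is the
#' midpoint between the adjacent distinct observed scores realizing the
#' optimum, so the calibrated cut-point does not depend on sample
#' granularity; the boundary rules are reported as (min score - 1) for
#' all-positive and (max score + 1) for all-negative.
#'
#' @param scores numeric vector (e.g. panel TMB).
#' @param labels logical vector (reference high-TMB calls).
#' @return list with `cutpoint` and `accuracy`.
#' @export
optimal_cutpoint <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), length(scores) > 0L)
  labels <- as.logical(labels)
  s <- sort(unique(scores))
  k <- length(s)
  # candidate i (1..k): positives are scores >= s[i]; k+1: all negative
  cand <- c(s[1L] - 1, if (k > 1L) (s[-k] + s[-1L]) / 2, s[k] + 1)
  acc <- vapply(c(s, Inf), function(t) {
    mean((scores >= t) == labels)
  }, numeric(1L))
  best <- which(acc == max(acc))
  pick <- best[which.min(cand[best])]
  list(cutpoint = cand[pick], accuracy = acc[pick])
}

#' ROC analysis of a panel against the exome TMB dichotomy
#'
#' Labels are exome TMB dichotomised at `exome_cutoff` (default 10/Mb);
#' scores are the panel TMB values. The threshold sweep runs over the
#' distinct panel TMB values plus a sentinel above the maximum; the AUC
#' is computed by trapezoidal integration, which under this sweep equals
#' the Mann-Whitney probability-of-correct-ranking statistic (ties
#' counted one half). The accuracy-optimal calibrated cut-point is
#' attached (see [optimal_cutpoint()]).
#'
#' @param profiles profile data frame.
#' @param panel panel column name.
#' @param exome_cutoff reference dichotomisation, mutations/Mb.
#' @param stratum `"pan-cancer"` (all samples) or a tumour type present
#'   in the profiles.
#' @return object of class `roc_result`: panel, stratum, thresholds,
#'   tpr, fpr, auc, n_pos, n_neg, optimal_cutpoint, optimal_accuracy.
#' @export
roc_curve <- function(profiles, panel, exome_cutoff = 10,
                      stratum = "pan-cancer") {
  if (!panel %in% names(profiles)) {
    stop("unknown panel '", panel, "'", call. = FALSE)
  }
  if (!identical(stratum, "pan-cancer")) {
    if (!stratum %in% profiles$tumour_type) {
      stop("stratum '", stratum, "' not present in profiles", call. = FALSE)
    }
    profiles <- profiles[profiles$tumour_type == stratum, , drop = FALSE]
  }
  labels <- profiles$exome_tmb >= exome_cutoff
  if (all(labels) || !any(labels)) {
    stop("ROC undefined: stratum '", stratum,
         "' has a single class at exome cut-off ", exome_cutoff,
         call. = FALSE)
  }
  scores <- profiles[[panel]]
  sw <- roc_sweep(scores, labels)
  opt <- optimal_cutpoint(scores, labels)
  structure(list(panel = panel, stratum = stratum,
                 exome_cutoff = exome_cutoff,
                 thresholds = sw$thresholds, tpr = sw$tpr, fpr = sw$fpr,
                 auc = trapezoid_auc(sw$fpr, sw$tpr),
                 n_pos = sum(labels), n_neg = sum(!labels),
                 optimal_cutpoint = opt$cutpoint,
                 optimal_accuracy = opt$accuracy),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result '%s' [%s]: AUC %.3f (%d pos / %d neg), optimal cut-point %.2f/Mb (accuracy %.3f)\n",
              x$panel, x$stratum, x$auc, x$n_pos, x$n_neg,
              x$optimal_cutpoint, x$optimal_accuracy))
  invisible(x)
}

#' Base-graphics ROC plot
#' @param x a `roc_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s (%s), AUC %.3f", x$panel, x$stratum, x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Calibrated cut-points and AUCs across panels and strata
#'
#' Runs [roc_curve()] for every panel in each stratum and tabulates AUC
#' and the calibrated (accuracy-optimal) cut-point — the analogue of a
#' panel-specific threshold table. Strata with a single class at the
#' exome cut-off are skipped with a warning.
#'
#' @param profiles profile data frame.
#' @param panels panel column names; default all.
#' @param strata character vector of strata (`"pan-cancer"` and/or
#'   tumour types); default pan-cancer plus every tumour type present.
#' @param exome_cutoff reference dichotomisation, mutations/Mb.
#' @return data frame: panel, stratum, n, n_pos, n_neg, auc,
#'   optimal_cutpoint, optimal_accuracy.
#' @export
calibrate_cutpoints <- function(profiles, panels = panel_columns(profiles),
                                strata = c("pan-cancer",
                                           sort(unique(profiles$tumour_type))),
                                exome_cutoff = 10) {
  rows <- list()
  for (st in strata) {
    for (pn in panels) {
      r <- tryCatch(roc_curve(profiles, pn, exome_cutoff, st),
                    error = function(e) {
                      warning("skipping stratum '", st, "' for panel '", pn,
                              "': ", conditionMessage(e), call. = FALSE)
                      NULL
                    })
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        panel = pn, stratum = st, n = r$n_pos + r$n_neg,
        n_pos = r$n_pos, n_neg = r$n_neg, auc = r$auc,
        optimal_cutpoint = r$optimal_cutpoint,
        optimal_accuracy = r$optimal_accuracy,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no stratum had both classes; nothing calibrated",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC points of several panels as a long table
#' @param profiles profile data frame.
#' @param panels panel column names.
#' @param exome_cutoff reference dichotomisation.
#' @param stratum stratum passed to [roc_curve()].
#' @return data frame: panel, stratum, threshold, fpr, tpr.
#' @export
roc_points <- function(profiles, panels = panel_columns(profiles),
                       exome_cutoff = 10, stratum = "pan-cancer") {
  do.call(rbind, lapply(panels, function(pn) {
    r <- roc_curve(profiles, pn, exome_cutoff, stratum)
    data.frame(panel = pn, stratum = stratum,
               threshold = r$thresholds, fpr = r$fpr, tpr = r$tpr,
               stringsAsFactors = FALSE)
  }))
}
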