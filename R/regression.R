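#' Linear relation between mutational load and exome TMB
#'
#' Ordinary least squares of mutational load (response) on exome-based
#' TMB (predictor) within one tumour type. ML and TMB are linearly
#' related but in a tumour-type-specific way, so fits are per type.
#'
#' @param profiles profile data frame with `mutational_load`.
#' @param tumour_type tumour type to fit.
#' @return object of class `ml_tmb_fit`: tumour_type, slope (ML per
#'   mutation/Mb), intercept (ML), r_squared, n, slope_se, model (the
#'   underlying [stats::lm()] fit).
#' @export
fit_ml_vs_tmb <- function(profiles, tumour_type) {
  stopifnot("mutational_load" %in% names(profiles))
  d <- profiles[profiles$tumour_type == tumour_type, , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("tumour type '", tumour_type, "': need >= 3 samples, have ",
         nrow(d), call. = FALSE)
  }
  if (stats::var(d$exome_tmb) == 0) {
    stop("degenerate predictor: exome TMB has zero variance in '",
         tumour_type, "'", call. = FALSE)
  }
  fit <- stats::lm(mutational_load ~ exome_tmb, data = d)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no variance explained
  structure(list(tumour_type = tumour_type,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n = nrow(d),
                 slope_se = sm$coefficients[2L, 2L],
                 model = fit),
            class = "ml_tmb_fit")
}

#' @export
print.ml_tmb_fit <- function(x, ...) {
  cat(sprintf("ml_tmb_fit '%s' (n=%d): ML = %.1f x TMB + %.1f, R^2 = %.3f\n",
              x$tumour_type, x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Predicted mutational load at a given TMB
#' @param fit an `ml_tmb_fit`.
#' @param tmb mutations/Mb.
#' @return predicted mutational load (numeric).
#' @export
predict_ml <- function(fit, tmb) {
  stopifnot(inherits(fit, "ml_tmb_fit"))
  fit$slope * tmb + fit$intercept
}

#' Regression summary across tumour types
#'
#' Fits the ML-TMB line for each requested tumour type and reports the
#' line equation, goodness of fit and the predicted ML at a reference
#' TMB (default the 10/Mb high-TMB cut-off).
#'
#' @param profiles profile data frame.
#' @param types tumour types; default every type with >= 3 samples.
#' @param at_tmb reference TMB for the prediction column.
#' @return data frame: tumour_type, n, slope, intercept, r_squared,
#'   ml_at_tmb<at_tmb>.
#' @export
regression_summary <- function(profiles, types = NULL, at_tmb = 10) {
  if (is.null(types)) {
    tab <- table(profiles$tumour_type)
    types <- names(tab)[tab >= 3L]
  }
  out <- do.call(rbind, lapply(types, function(tt) {
    f <- tryCatch(fit_ml_vs_tmb(profiles, tt), error = function(e) {
      warning("skipping regression for '", tt, "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(f)) return(NULL)
    data.frame(tumour_type = tt, n = f$n, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               ml_at_ref = predict_ml(f, at_tmb),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) stop("no tumour type could be fitted", call. = FALSE)
  names(out)[names(out) == "ml_at_ref"] <- paste0("ml_at_tmb", at_tmb)
  rownames(out) <- NULL
  out
}
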