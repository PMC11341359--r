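# Competition HLA-binding analytics: percent inhibition, 4PL IC50 fits,
# dose-dependence testing and affinity binning.

#' Percent inhibition from raw competition signals
#'
#' `100 * (1 - (signal - background) / (max_signal - background))`, clipped
#' to [-10, 110]; clipping is flagged in the `clipped` attribute.
#'
#' @param signal Observed signal(s).
#' @param max_signal Uninhibited (no test peptide) signal.
#' @param background Background signal; must be below `max_signal`.
#' @return Percent inhibition, vectorized over `signal`.
#' @export
percent_inhibition <- function(signal, max_signal, background = 0) {
  if (max_signal <= background) stop("max_signal must exceed background")
  x <- 100 * (1 - (signal - background) / (max_signal - background))
  clipped <- x < -10 | x > 110
  structure(pmin(110, pmax(-10, x)), clipped = clipped)
}

#' Construct an inhibition curve
#'
#' @param peptide,allele Identifiers.
#' @param concentrations Exactly 7 strictly increasing concentrations (nM).
#' @param inhibition Numeric matrix 7 x 3 (triplicates per concentration) of
#'   percent-inhibition values, or a length-21 vector filled by
#'   concentration.
#' @return An `inhibition_curve`.
#' @export
inhibition_curve <- function(peptide, allele, concentrations, inhibition) {
  if (length(concentrations) != 7 || any(diff(concentrations) <= 0)) {
    stop("exactly 7 strictly increasing concentrations required")
  }
  m <- matrix(inhibition, nrow = 7, ncol = 3)
  if (!all(is.finite(m))) stop("inhibition values must be finite")
  structure(list(peptide = peptide, allele = allele,
                 concentrations = as.numeric(concentrations), inhibition = m),
            class = "inhibition_curve")
}

fourpl <- function(conc, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
}

#' Fit an IC50 from a competition inhibition curve
#'
#' Least-squares four-parameter logistic fit of percent inhibition against
#' log10 concentration, over all 21 replicate points, with soft bounds
#' (bottom in [-10, 20], top in [60, 110], hill > 0). The curve is called
#' dose-dependent when a one-sided Spearman trend test of concentration vs
#' per-concentration mean inhibition gives p < 0.05 AND the fitted IC50 lies
#' within 10x of the tested concentration range; otherwise the peptide is a
#' non-binder. Non-convergent fits are reported as non-binders with a
#' diagnostic.
#'
#' @param curve An `inhibition_curve`.
#' @param alpha Trend-test significance level.
#' @return An `ic50_result`: ic50 (nM), bottom, top, hill, trend_p,
#'   dose_dependent, affinity_class, converged, diagnostic.
#' @export
fit_ic50 <- function(curve, alpha = 0.05) {
  stopifnot(inherits(curve, "inhibition_curve"))
  conc <- rep(curve$concentrations, 3)
  y <- as.vector(curve$inhibition)
  means <- rowMeans(curve$inhibition)
  trend <- suppressWarnings(stats::cor.test(curve$concentrations, means,
                                            method = "spearman",
                                            alternative = "greater"))
  lo <- min(curve$concentrations); hi <- max(curve$concentrations)
  start <- list(
    bottom = max(-10, min(20, min(means))),
    top = max(60, min(110, max(means))),
    hill = 1,
    l50 = log10(curve$concentrations[which.min(abs(means - (min(means) + max(means)) / 2))])
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (l50 - log10(conc)))),
      start = start,
      lower = c(bottom = -10, top = 60, hill = 0.05, l50 = log10(lo) - 3),
      upper = c(bottom = 20, top = 110, hill = 10, l50 = log10(hi) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res <- list(ic50 = NA_real_, bottom = NA_real_, top = NA_real_,
                hill = NA_real_, trend_p = trend$p.value,
                dose_dependent = FALSE, converged = FALSE,
                diagnostic = conditionMessage(fit))
  } else {
    cf <- stats::coef(fit)
    ic50 <- 10^cf[["l50"]]
    in_range <- ic50 >= lo / 10 && ic50 <= hi * 10
    res <- list(ic50 = ic50, bottom = cf[["bottom"]], top = cf[["top"]],
                hill = cf[["hill"]], trend_p = trend$p.value,
                dose_dependent = trend$p.value < alpha && in_range,
                converged = TRUE, diagnostic = NA_character_)
  }
  res$peptide <- curve$peptide
  res$allele <- curve$allele
  res$affinity_class <- classify_affinity(res$ic50, res$dose_dependent)
  structure(res, class = "ic50_result")
}

#' @export
print.ic50_result <- function(x, ...) {
  cat(sprintf("<ic50_result> %s / %s: IC50 %s nM, %s%s\n", x$peptide, x$allele,
              if (is.na(x$ic50)) "NA" else format(round(x$ic50)),
              x$affinity_class,
              if (!x$dose_dependent) " (no dose-dependent inhibition)" else ""))
  invisible(x)
}

AFFINITY_BINS <- data.frame(
  class = c("very-high", "high", "moderate", "low", "negligible"),
  upper = c(100, 1e3, 1e4, 1e5, 1e6)
)

#' Affinity class of an IC50
#'
#' Bins: <= 100 nM very-high; (100, 1,000] high; (1,000, 10,000] moderate;
#' (10,000, 100,000] low; (100,000, 1,000,000] negligible; above 1,000,000 nM
#' or without dose-dependent inhibition, non-binder. "Weak" affinity in assay
#' reports corresponds to the low bin.
#'
#' @param ic50 IC50 in nM (NA allowed when not dose-dependent).
#' @param dose_dependent Logical.
#' @return Affinity class string.
#' @export
classify_affinity <- function(ic50, dose_dependent = TRUE) {
  if (!isTRUE(dose_dependent) || is.na(ic50) || ic50 > 1e6) return("non-binder")
  if (ic50 <= 0) stop("ic50 must be positive")
  AFFINITY_BINS$class[which(ic50 <= AFFINITY_BINS$upper)[1]]
}

#' Read binding-assay data from CSV
#'
#' Expects columns `peptide, allele, concentration_nM, replicate,
#' percent_inhibition`, or raw-signal columns `signal, max_signal,
#' background` which are converted via [percent_inhibition()].
#'
#' @param path CSV file.
#' @return List of `inhibition_curve`s, one per peptide-allele pair.
#' @export
read_binding_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"percent_inhibition" %in% names(df)) {
    df$percent_inhibition <- as.numeric(
      percent_inhibition(df$signal, df$max_signal, df$background))
  }
  keys <- unique(df[, c("peptide", "allele")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$peptide == keys$peptide[i] & df$allele == keys$allele[i], ]
    sub <- sub[order(sub$concentration_nM, sub$replicate), ]
    inhibition_curve(keys$peptide[i], keys$allele[i],
                     unique(sub$concentration_nM),
                     matrix(sub$percent_inhibition, nrow = 7, byrow = TRUE))
  })
}

#' Write IC50 results to CSV
#' @param results List of `ic50_result`s.
#' @param path Output CSV.
#' @export
write_ic50_csv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(peptide = r$peptide, allele = r$allele, ic50_nM = r$ic50,
               class = r$affinity_class, dose_dependent = r$dose_dependent,
               top = r$top, bottom = r$bottom, hill = r$hill,
               trend_p = r$trend_p, converged = r$converged)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dose-response plot for a fitted inhibition curve
#' @param curve An `inhibition_curve`.
#' @param fit Optional `ic50_result` for the overlay.
#' @return A ggplot object.
#' @export
plot_inhibition <- function(curve, fit = NULL) {
  df <- data.frame(conc = rep(curve$concentrations, 3),
                   inhibition = as.vector(curve$inhibition))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = conc, y = inhibition)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "% inhibition",
                  title = paste(curve$peptide, "/", curve$allele))
  if (!is.null(fit) && fit$converged) {
    grid <- exp(seq(log(min(curve$concentrations)), log(max(curve$concentrations)),
                    length.out = 100))
    fd <- data.frame(conc = grid,
                     inhibition = fourpl(grid, fit$bottom, fit$top, fit$hill, fit$ic50))
    gg <- gg + ggplot2::geom_line(data = fd, colour = "steelblue")
  }
  gg
}
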