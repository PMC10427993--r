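#' @export
tidy.bhm_lm <- function(x, ...) x$summary

#' @export
glance.bhm_lm <- function(x, ...) {
  tibble(n = x$n, n_parameters = nrow(x$summary),
         sigma = x$summary$mean[x$summary$parameter == "sigma"],
         rhat_max = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
         ess_min = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)),
         diagnostics_ok = x$diagnostics_ok)
}

#' @export
tidy.bhm_groups <- function(x, contrasts = FALSE, ...) {
  if (contrasts) x$contrasts else x$group_summary
}

#' @export
glance.bhm_groups <- function(x, ...) {
  tibble(n = x$n, n_groups = nrow(x$group_summary),
         rhat_max = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
         ess_min = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)),
         diagnostics_ok = x$diagnostics_ok)
}

#' @export
tidy.bhm_hfi <- function(x, contrasts = FALSE, ...) {
  if (contrasts) x$contrasts else x$type_summary
}

#' @export
glance.bhm_hfi <- function(x, ...) {
  tibble(n = x$n, n_triplets = x$n_triplets,
         rhat_max = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
         ess_min = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)),
         diagnostics_ok = x$diagnostics_ok)
}

#' @export
print.bhm_lm <- function(x, ...) {
  cat("<bhm_lm> Gaussian regression of", x$response, "on",
      paste(x$predictors, collapse = " + "), "\n")
  cat("  n =", x$n, "| diagnostics",
      if (x$diagnostics_ok) "ok" else "FAILED", "\n")
  print(x$summary)
  invisible(x)
}

#' @export
print.bhm_groups <- function(x, ...) {
  cat("<bhm_groups> posterior log10 diversification-rate means, n =",
      x$n, "genera\n")
  print(x$group_summary)
  cat("contrasts (back-transformed ratios):\n")
  print(dplyr::select(x$contrasts, "contrast", "mean", "ci95_low",
                      "ci95_high", dplyr::starts_with("ratio_")))
  invisible(x)
}

#' @export
print.bhm_hfi <- function(x, ...) {
  cat("<bhm_hfi> mean human footprint by taxon type,", x$n_triplets,
      "triplets,", x$n, "observations\n")
  print(x$type_summary)
  print(dplyr::select(x$contrasts, "contrast", "mean", "ci95_low",
                      "ci95_high", "clarity"))
  invisible(x)
}

interval_plot <- function(df, yvar, title, xlab) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean,
                                   y = .data[[yvar]])) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$ci95_low,
                                         xmax = .data$ci95_high),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$ci66_low,
                                         xmax = .data$ci66_high),
                            linewidth = 1.1) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = title, x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot posterior coefficient intervals
#'
#' Point = posterior mean; thick and thin lines = 66% and 95% equal-tailed
#' credible intervals.
#'
#' @param object A fitted `bhm_lm`, `bhm_groups`, or `bhm_hfi` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bhm_lm <- function(object, ...) {
  interval_plot(object$summary, "parameter",
                paste("Posterior:", object$response), "estimate")
}

#' @rdname autoplot.bhm_lm
#' @export
autoplot.bhm_groups <- function(object, ...) {
  interval_plot(object$group_summary, "group",
                "Posterior mean log10 diversification rate",
                "log10(species/Myr)")
}

#' @rdname autoplot.bhm_lm
#' @export
autoplot.bhm_hfi <- function(object, ...) {
  interval_plot(object$type_summary, "taxon_type",
                "Posterior mean human footprint index", "HFI")
}

#' Plot pairwise posterior contrasts
#'
#' @param x A `bhm_groups` or `bhm_hfi` fit.
#' @return A ggplot object showing each pairwise difference with 66%/95%
#'   intervals and a zero reference line.
#' @export
plot_contrasts <- function(x) {
  stopifnot(inherits(x, c("bhm_groups", "bhm_hfi")))
  interval_plot(x$contrasts, "contrast", "Pairwise posterior differences",
                "difference") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50")
}
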