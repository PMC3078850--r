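#' Plot an experiment grid
#'
#' Odds-ratio curves for a pooled experiment table: attenuation versus the
#' fatality differential (one curve per overall fatality level, panelled by
#' risk ratio) or versus statin use (one curve per risk ratio or per
#' eliminated-excess fraction). Requires ggplot2.
#'
#' @param result an `experiment_result` from a grid runner.
#' @param x name of the x variable (`"d"` for the fatality grid, `"s"` for
#'   the statin grids); guessed from the columns if `NULL`.
#' @return a ggplot object.
#' @export
plot_experiment <- function(result, x = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_experiment requires the ggplot2 package", call. = FALSE)
  }
  p <- result$pooled[!result$pooled$failed, ]
  if (is.null(x)) x <- if ("d" %in% names(p) && length(unique(p$d)) > 1) "d" else "s"
  grp <- if (x == "d") {
    "F"
  } else if ("e" %in% names(p) && length(unique(p$e)) > 1) {
    "e"
  } else {
    "RR"
  }
  p$group <- factor(p[[grp]])
  gg <- ggplot2::ggplot(p, ggplot2::aes(
    x = .data[[x]], y = .data[["pooled_or"]],
    colour = .data[["group"]], group = .data[["group"]]
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data[["oracle_or"]]),
                       linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(
      x = if (x == "d") "Fatality differential between genotypes" else
        "Fraction of population using statins",
      y = "Carrier vs noncarrier odds ratio",
      colour = grp
    ) +
    ggplot2::theme_minimal()
  if ("RR" %in% names(p) && length(unique(p$RR)) > 1 && grp != "RR") {
    gg <- gg + ggplot2::facet_wrap(~RR, labeller = ggplot2::label_both)
  }
  gg
}
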