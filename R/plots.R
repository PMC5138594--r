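## Result figures: control-relative scores with bootstrap CIs and
## star-coded evidence labels.

#' Plot control-relative scores with evidence labels
#'
#' One panel per shadow level: per-condition group mean control-relative
#' z-scored log reaction time (or coded depth difference), percentile
#' bootstrap confidence intervals, and the star-coded Bayes evidence label
#' above each bar (`0*` anecdotal ... `4*` extreme, for H0 or H1).
#'
#' @param summary the `summary` data frame from [analyze_rt_experiment()].
#' @return a ggplot object.
#' @export
plot_condition_scores <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_condition_scores requires the ggplot2 package")
  }
  summary$star_label <- paste0(summary$stars, "* ",
                               substr(summary$evidence,
                                      nchar(summary$evidence) - 1,
                                      nchar(summary$evidence)))
  summary$background <- ifelse(summary$shadows, "with shadows",
                               "without shadows")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = condition, y = mean_rel_z)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_lo, ymax = ci_hi)) +
    ggplot2::geom_text(ggplot2::aes(y = ci_hi, label = star_label),
                       vjust = -0.8, size = 3) +
    ggplot2::facet_wrap(~background) +
    ggplot2::labs(x = "edge-enhancement condition",
                  y = "control-relative z-scored log RT") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
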