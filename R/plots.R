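# Static visual aids for communicating absolute risk and trait predictions.

#' Plot absolute risk across polygenic score quantiles
#'
#' Bar chart of the case probability within each score quantile, with the
#' population prevalence as a reference line; optionally highlights the
#' quantile containing an individual's Z-score.
#'
#' @param table An `absolute_risk_table` from [risk_by_quantile()].
#' @param z Optional individual Z-score to highlight.
#' @param file Optional PNG path; when given, the plot is written there.
#' @return `NULL`, invisibly.
#' @export
plot_risk_by_quantile <- function(table, z = NULL, file = NULL) {
  stopifnot(inherits(table, "absolute_risk_table"))
  model <- attr(table, "model")
  if (!is.null(file)) {
    png(file, width = 900, height = 600)
    on.exit(dev.off(), add = TRUE)
  }
  cols <- rep("grey70", nrow(table))
  if (!is.null(z)) {
    idx <- partition_index(attr(table, "partition"), z)
    cols[idx] <- "firebrick"
  }
  barplot(100 * table$case_probability, names.arg = table$quantile,
          col = cols, border = NA,
          xlab = "Polygenic score quantile", ylab = "Probability of being a case (%)",
          main = sprintf("Absolute risk by polygenic score quantile (K = %g, AUC = %.3f)",
                         model$K, d_to_auc(model$d)))
  abline(h = 100 * model$K, lty = 2)
  invisible(NULL)
}

#' Plot trait mean and prediction interval across score quantiles
#'
#' Per-quantile conditional trait mean with a prediction interval band, and
#' the population mean as a reference line.
#'
#' @param table An `absolute_trait_table` from [trait_by_quantile()].
#' @param level Interval coverage for the whiskers (default 0.95).
#' @param z Optional individual Z-score to highlight.
#' @param file Optional PNG path.
#' @return `NULL`, invisibly.
#' @export
plot_trait_by_quantile <- function(table, level = 0.95, z = NULL, file = NULL) {
  stopifnot(inherits(table, "absolute_trait_table"))
  model <- attr(table, "model")
  if (!is.null(file)) {
    png(file, width = 900, height = 600)
    on.exit(dev.off(), add = TRUE)
  }
  half <- qnorm((1 + level) / 2) * table$trait_sd
  lo <- table$trait_mean - half
  hi <- table$trait_mean + half
  plot(table$quantile, table$trait_mean, pch = 19, ylim = range(lo, hi),
       xlab = "Polygenic score quantile", ylab = "Trait value",
       main = sprintf("Trait distribution by score quantile (mean = %g, SD = %g, R2 = %g)",
                      model$mean, model$sd, model$r2))
  arrows(table$quantile, lo, table$quantile, hi,
         angle = 90, code = 3, length = 0.03, col = "grey50")
  if (!is.null(z)) {
    idx <- partition_index(attr(table, "partition"), z)
    points(table$quantile[idx], table$trait_mean[idx], pch = 19, col = "firebrick")
  }
  abline(h = model$mean, lty = 2)
  invisible(NULL)
}
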