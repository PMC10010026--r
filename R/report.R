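#' Serialize a Hi-Bi result to a JSON report
#'
#' Writes the reporting bundle recommended for evidence-synthesis
#' practice: the zero-structure subtype, the number of double-zero
#' studies, the indices with their impact categories, and the method and
#' model used, plus the reference pooling and the minimal changing
#' combinations. The report round-trips losslessly through
#' [jsonlite::fromJSON()].
#'
#' @param result A `hibi_result` from [hibi()].
#' @param path File path; when `NULL` the JSON string is returned
#'   invisibly instead of written.
#' @return The report as a named list, invisibly.
#' @export
write_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "hibi_result"))
  changing <- list(
    hi = if (is.null(result$hi_combination)) NULL
         else as.integer(result$hi_combination),
    bi = if (is.null(result$bi_combination)) NULL
         else as.integer(result$bi_combination)
  )
  report <- list(
    subtype = result$subtype,
    n_double_zero = result$n_double_zero,
    method = result$method,
    model = result$model,
    measure = result$measure,
    alpha = result$alpha,
    max_cases = result$max_cases,
    cutoff = result$cutoff,
    hi = result$hi,
    bi = result$bi,
    hi_category = result$hi_category,
    bi_category = result$bi_category,
    reference = list(
      log_effect = result$reference$log_effect,
      se = result$reference$se,
      p = result$reference$p_value
    ),
    changing_combinations = changing,
    warn_inestimable = result$warn_inestimable,
    subtype_rule = paste(
      "MA-CMZ when single-zero, double-zero and nonzero studies are all",
      "present and neither arm's total case count is zero; MA-MZ for any",
      "other mixture of both zero kinds")
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(report)
}

#' Export the evaluation trace as CSV
#'
#' One row per evaluated combination (the reference first): the added-case
#' vector, target arm, total added, pooled log-effect, SE, p-value, and
#' the changed flag.
#'
#' @param result A `hibi_result`.
#' @param path Output CSV path.
#' @return The combined trace data frame, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "hibi_result"))
  trace <- rbind(result$traces$hi, result$traces$bi)
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(trace)
}

#' Plot the iteration process of one index
#'
#' Shows the pooled log-effect (with its confidence band) against the
#' total number of added cases, one point per evaluated combination, with
#' filled points for significant poolings and the minimal changing
#' combination highlighted. Rendering is deterministic given the trace.
#'
#' @param result A `hibi_result`.
#' @param arm `"treatment"` (Hi plot) or `"control"` (Bi plot).
#' @param path Optional file path (extension selects the device, e.g.
#'   `.png` or `.pdf`); when `NULL` the ggplot object is returned without
#'   writing.
#' @return The ggplot object, invisibly when written to file.
#' @export
render_index_plot <- function(result, arm = c("treatment", "control"),
                              path = NULL) {
  stopifnot(inherits(result, "hibi_result"))
  arm <- match.arg(arm)
  trace <- if (arm == "treatment") result$traces$hi else result$traces$bi
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  trace <- trace[trace$estimable, , drop = FALSE]
  index_val <- if (arm == "treatment") result$hi else result$bi
  label <- if (arm == "treatment") "Hi" else "Bi"
  z <- stats::qnorm(1 - result$alpha / 2)
  trace$lo <- trace$log_effect - z * trace$se
  trace$hi_ci <- trace$log_effect + z * trace$se
  first_change <- which(trace$changed)[1]

  p <- ggplot2::ggplot(trace,
                       ggplot2::aes(x = .data$total, y = .data$log_effect)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi_ci),
                           width = 0.1, colour = "grey60",
                           position = ggplot2::position_jitter(width = 0.08,
                                                               height = 0,
                                                               seed = 1)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                name = sprintf("p < %g", result$alpha)) +
    ggplot2::labs(
      x = "total cases added",
      y = sprintf("pooled log %s", result$measure),
      title = sprintf("%s plot (%s method, %s model): %s = %d",
                      label, result$method, result$model, label, index_val)
    ) +
    ggplot2::theme_minimal()
  if (!is.na(first_change)) {
    p <- p + ggplot2::geom_point(data = trace[first_change, , drop = FALSE],
                                 colour = "red", size = 4, shape = 1,
                                 stroke = 1.2)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
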