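#' Bar chart of per-tool CNV counts by type
#'
#' @param tool_counts Output of [count_by_tool_type()].
#' @return A ggplot object.
#' @export
plot_tool_counts <- function(tool_counts) {
  long <- tidyr::pivot_longer(tool_counts, c("DEL", "DUP"),
                              names_to = "cnv_type", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tool_id, y = .data$n,
                                     fill = .data$cnv_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "caller", y = "CNV calls", fill = "type",
                  title = "CNV calls per tool by type") +
    ggplot2::theme_minimal()
}

#' Bar chart of the CNV size distribution per tool
#'
#' @param size_dist Output of [size_histogram()] (per tool).
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(size_dist) {
  aes <- if ("tool_id" %in% names(size_dist)) {
    ggplot2::aes(x = .data$bin, y = .data$n, fill = .data$tool_id)
  } else {
    ggplot2::aes(x = .data$bin, y = .data$n)
  }
  ggplot2::ggplot(size_dist, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "CNV size", y = "calls", fill = "caller",
                  title = "CNV size distribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Bar chart of per-tool consensus overlap rates
#'
#' @param rates Output of [overlap_rate_by_tool()].
#' @return A ggplot object.
#' @export
plot_overlap_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$tool_id,
                                      y = .data$overlap_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "caller", y = "% of raw calls in consensus",
                  title = "Consensus overlap rate per tool") +
    ggplot2::theme_minimal()
}
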