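#' Consensus-calling parameters
#'
#' Bundles the tunable knobs of the consensus stage. The defaults encode the
#' standard high-confidence recipe for multi-caller WES CNV sets: two
#' intervals agree when they share at least 50% of each other's length
#' (reciprocal overlap), same-type agreeing regions are merged (bookended
#' regions included), and a merged region is kept only when at least two
#' distinct callers support it.
#'
#' @param f Reciprocal-overlap fraction in (0, 1]. Two intervals pass when the
#'   shared length is at least `f` of *both* interval lengths ("at least" is
#'   inclusive, so `f = 0.5` admits exactly-half overlaps).
#' @param min_tools Minimum number of distinct supporting callers (>= 2 by
#'   default) for a merged region to be retained as consensus.
#' @param merge_gap Maximum gap in bp between same-type fragments that still
#'   merge. The default 0 merges overlapping *and* bookended fragments,
#'   mirroring the usual interval-merge convention.
#'
#' @return A list of class `consensus_params`.
#' @examples
#' consensus_params()
#' consensus_params(f = 0.7, min_tools = 3)
#' @export
consensus_params <- function(f = 0.5, min_tools = 2L, merge_gap = 0L) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1) {
    abort("`f` must be a single number in (0, 1].")
  }
  if (!is.numeric(min_tools) || length(min_tools) != 1L || is.na(min_tools) ||
      min_tools < 1) {
    abort("`min_tools` must be a single integer >= 1.")
  }
  if (!is.numeric(merge_gap) || length(merge_gap) != 1L || is.na(merge_gap) ||
      merge_gap < 0) {
    abort("`merge_gap` must be a single non-negative number of bp.")
  }
  structure(
    list(f = as.numeric(f), min_tools = as.integer(min_tools),
         merge_gap = as.numeric(merge_gap)),
    class = "consensus_params"
  )
}

#' @export
print.consensus_params <- function(x, ...) {
  cat("Consensus parameters: reciprocal overlap >=", x$f,
      "| min tools", x$min_tools, "| merge gap", x$merge_gap, "bp\n")
  invisible(x)
}

#' Prioritisation parameters
#'
#' Gates applied to CNV annotation records: a phenotype-driven Exomiser score
#' threshold (inclusive, "at least 0.5") and the set of ACMG classes worth
#' reporting. A second, stricter score cut separates merely
#' phenotype-consistent genes from highly specific ones.
#'
#' @param exomiser_min Minimum Exomiser score in \[0, 1\] (inclusive gate).
#'   Records with a missing score are excluded by the gate.
#' @param acmg_keep Integer ACMG classes to retain; defaults to
#'   `c(3, 4, 5)` (VUS, likely pathogenic, pathogenic).
#' @param high_specificity_cut Score above which (strictly) a kept record is
#'   tiered "highly specific" rather than "consistent".
#'
#' @return A list of class `prioritization_params`.
#' @examples
#' prioritization_params()
#' @export
prioritization_params <- function(exomiser_min = 0.5,
                                  acmg_keep = c(3L, 4L, 5L),
                                  high_specificity_cut = 0.7) {
  if (!is.numeric(exomiser_min) || length(exomiser_min) != 1L ||
      is.na(exomiser_min) || exomiser_min < 0 || exomiser_min > 1) {
    abort("`exomiser_min` must be a single number in [0, 1].")
  }
  acmg_keep <- as.integer(acmg_keep)
  if (length(acmg_keep) == 0L || anyNA(acmg_keep) ||
      !all(acmg_keep %in% 1:5)) {
    abort("`acmg_keep` must be a non-empty subset of 1:5.")
  }
  structure(
    list(exomiser_min = as.numeric(exomiser_min),
         acmg_keep = sort(unique(acmg_keep)),
         high_specificity_cut = as.numeric(high_specificity_cut)),
    class = "prioritization_params"
  )
}

#' CNV size bins
#'
#' Left-closed size bins used for size-distribution summaries. The defaults
#' follow the conventional WES-CNV reporting scale: below 1 kb, 1-100 kb,
#' 100 kb-1 Mb, 1-10 Mb, and 10 Mb or larger.
#'
#' @param edges Strictly increasing bp thresholds separating the bins.
#'
#' @return A list of class `size_bins` with `edges` and human-readable
#'   `labels` (one more label than edges).
#' @examples
#' size_bins()
#' size_bins(edges = c(1e4, 1e6))
#' @export
size_bins <- function(edges = c(1e3, 1e5, 1e6, 1e7)) {
  edges <- as.numeric(edges)
  if (length(edges) < 1L || anyNA(edges) || any(diff(edges) <= 0) ||
      any(edges <= 0)) {
    abort("`edges` must be strictly increasing positive bp thresholds.")
  }
  fmt <- function(x) {
    ifelse(x >= 1e6, paste0(x / 1e6, " Mb"),
           ifelse(x >= 1e3, paste0(x / 1e3, " kb"), paste0(x, " bp")))
  }
  n <- length(edges)
  labels <- c(
    paste0("<", fmt(edges[1])),
    if (n > 1L) paste0(fmt(edges[-n]), "-", fmt(edges[-1])),
    paste0(">=", fmt(edges[n]))
  )
  structure(list(edges = edges, labels = labels), class = "size_bins")
}
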