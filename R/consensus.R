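#' Collapse a tool's overlapping same-type calls
#'
#' Within each (sample, tool, chromosome, type) group, overlapping or
#' bookended calls are replaced by their union. This prevents a single
#' caller that fragments one event into several overlapping segments from
#' being counted as more than one supporter during pairwise intersection.
#'
#' @param calls A calls tibble (see [read_callset()]).
#' @return A calls tibble with disjoint intervals per group, sorted.
#' @export
collapse_within_tool <- function(calls) {
  if (nrow(calls) == 0L) return(calls[intersect(names(calls),
    c("chrom", "start", "end", "cnv_type", "sample_id", "tool_id"))])
  calls |>
    dplyr::group_by(.data$sample_id, .data$tool_id, .data$chrom,
                    .data$cnv_type) |>
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
    dplyr::mutate(.grp = cumsum(.data$start >
      dplyr::lag(cummax(.data$end), default = -Inf))) |>
    dplyr::group_by(.data$.grp, .add = TRUE) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "cnv_type", "sample_id",
                  "tool_id") |>
    sort_calls() |>
    tibble::as_tibble()
}

empty_fragments <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 cnv_type = character(), sample_id = character(),
                 tool_a = character(), tool_b = character(),
                 a_start = numeric(), a_end = numeric(),
                 b_start = numeric(), b_end = numeric(),
                 frac_a = numeric(), frac_b = numeric())
}

#' Pairwise reciprocal-overlap intersection across tools
#'
#' For every unordered pair of distinct tools within a sample, emits one
#' fragment per pair of same-type calls that passes the reciprocal-overlap
#' criterion at `params$f`. The fragment interval is the *intersection*
#' region of the two calls; deletions never pair with duplications. Input
#' may hold several samples; pairs are always formed within a sample.
#'
#' @param calls A calls tibble covering >= 2 tools per sample.
#' @param params A [consensus_params()] object.
#' @param collapse Collapse each tool's overlapping same-type calls first
#'   (default `TRUE`; see [collapse_within_tool()]).
#' @return A fragment tibble: the intersection interval, the tool pair, the
#'   two source intervals and their overlap fractions, sorted.
#' @export
intersect_pairwise <- function(calls, params = consensus_params(),
                               collapse = TRUE) {
  stopifnot(inherits(params, "consensus_params"))
  if (nrow(calls) == 0L) return(empty_fragments())
  if (collapse) calls <- collapse_within_tool(calls)
  tools <- sort(unique(calls$tool_id))
  if (length(tools) < 2L) return(empty_fragments())
  per_tool <- lapply(tools, function(t)
    calls[calls$tool_id == t, , drop = FALSE])
  pair_idx <- utils::combn(length(tools), 2L, simplify = FALSE)
  out <- lapply(pair_idx, function(pr) {
    a <- per_tool[[pr[1]]]; b <- per_tool[[pr[2]]]
    # after the within-tool collapse each tool's same-type intervals are
    # disjoint per sample; without it fall back to the general join
    hit <- interval_pairs(a, b, params$f, by_sample = TRUE,
                          b_disjoint = collapse)
    if (length(hit$i) == 0L) return(NULL)
    tibble::tibble(
      chrom = a$chrom[hit$i],
      start = pmax(a$start[hit$i], b$start[hit$j]),
      end = pmin(a$end[hit$i], b$end[hit$j]),
      cnv_type = a$cnv_type[hit$i], sample_id = a$sample_id[hit$i],
      tool_a = tools[pr[1]], tool_b = tools[pr[2]],
      a_start = a$start[hit$i], a_end = a$end[hit$i],
      b_start = b$start[hit$j], b_end = b$end[hit$j],
      frac_a = hit$frac_a, frac_b = hit$frac_b
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) return(empty_fragments())
  tibble::as_tibble(sort_calls(out))
}

empty_consensus <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 cnv_type = character(), sample_id = character(),
                 n_tools = integer(), tools = character(),
                 n_fragments = integer())
}

#' Merge intersection fragments into consensus CNVs
#'
#' Fragments of the same sample, chromosome and CNV type whose intervals
#' overlap or lie within `params$merge_gap` bp of each other are merged
#' transitively into one region spanning their union (the default gap of 0
#' also merges bookended fragments). The supporting-tool set of a merged
#' region is the union of the tool pairs of its constituent fragments;
#' deletions and duplications never merge.
#'
#' @param fragments A fragment tibble from [intersect_pairwise()].
#' @param params A [consensus_params()] object.
#' @return A consensus tibble: interval, type, sample, `n_tools` (distinct
#'   supporters), `tools` (comma-joined, sorted) and `n_fragments`.
#' @export
merge_fragments <- function(fragments, params = consensus_params()) {
  stopifnot(inherits(params, "consensus_params"))
  if (nrow(fragments) == 0L) return(empty_consensus())
  out <- fragments |>
    dplyr::group_by(.data$sample_id, .data$chrom, .data$cnv_type) |>
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
    dplyr::mutate(.grp = cumsum(.data$start >
      dplyr::lag(cummax(.data$end), default = -Inf) + params$merge_gap)) |>
    dplyr::group_by(.data$.grp, .add = TRUE) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      tools = paste(sort(unique(c(.data$tool_a, .data$tool_b))),
                    collapse = ","),
      n_tools = length(unique(c(.data$tool_a, .data$tool_b))),
      n_fragments = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("chrom", "start", "end", "cnv_type", "sample_id",
                  "n_tools", "tools", "n_fragments")
  out$n_tools <- as.integer(out$n_tools)
  out$n_fragments <- as.integer(out$n_fragments)
  tibble::as_tibble(sort_calls(out))
}

#' Retain consensus CNVs with sufficient tool support
#'
#' Keeps regions supported by at least `params$min_tools` *distinct* tools.
#' Support is recounted from the `tools` column, so hand-built records are
#' handled defensively.
#'
#' @param consensus A consensus tibble.
#' @param params A [consensus_params()] object.
#' @return The filtered consensus tibble.
#' @export
filter_support <- function(consensus, params = consensus_params()) {
  stopifnot(inherits(params, "consensus_params"))
  if (nrow(consensus) == 0L) return(consensus)
  n <- vapply(strsplit(consensus$tools, ",", fixed = TRUE),
              function(t) length(unique(t[nzchar(t)])), integer(1))
  consensus$n_tools <- n
  consensus[n >= params$min_tools, , drop = FALSE]
}

#' Call consensus CNVs from multi-tool call sets
#'
#' The full consensus recipe:
#' [intersect_pairwise()] (pairwise reciprocal-overlap intersection across
#' tools, per sample) , then [merge_fragments()] (same-type transitive
#' merging), then [filter_support()] (keep regions supported by at least
#' `params$min_tools` distinct tools). With a single tool no pair exists and
#' the consensus is empty.
#'
#' @param calls A calls tibble (one or many samples).
#' @param params A [consensus_params()] object.
#' @param collapse Passed to [intersect_pairwise()].
#' @return A consensus tibble sorted by (chromosome, start, end).
#' @examples
#' calls <- tibble::tibble(
#'   chrom = "1", start = c(0, 40, 80), end = c(100, 140, 180),
#'   cnv_type = "DEL", sample_id = "S1", tool_id = c("A", "B", "C"))
#' call_consensus(calls, consensus_params(min_tools = 2))
#' @export
call_consensus <- function(calls, params = consensus_params(),
                           collapse = TRUE) {
  calls |>
    intersect_pairwise(params, collapse = collapse) |>
    merge_fragments(params) |>
    filter_support(params)
}
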