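# Round half away from zero (printed-percentage convention: 69.85 -> 69.9),
# unlike base round()'s round-half-even. A tiny epsilon absorbs binary
# representation error in the last digit.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-tool CNV counts by type
#'
#' Counts each tool's raw calls split into deletions and duplications, with
#' per-tool totals — the numbers behind the usual caller-comparison bar
#' chart.
#'
#' @param calls A calls tibble from one or more tools.
#' @return A tibble with columns `tool_id`, `DEL`, `DUP`, `total` (zero rows
#'   in, all-zero columns out).
#' @export
count_by_tool_type <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(tool_id = character(), DEL = integer(),
                          DUP = integer(), total = integer()))
  }
  calls |>
    dplyr::count(.data$tool_id, .data$cnv_type) |>
    tidyr::pivot_wider(names_from = "cnv_type", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (ty in c("DEL", "DUP")) if (!ty %in% names(d)) d[[ty]] <- 0L
      d
    })() |>
    dplyr::mutate(total = .data$DEL + .data$DUP) |>
    dplyr::select("tool_id", "DEL", "DUP", "total") |>
    dplyr::arrange(.data$tool_id)
}

#' Size-bin histogram of CNV calls
#'
#' Assigns every call to exactly one left-closed size bin
#' (size = end - start) and counts calls per bin — per tool when a
#' `tool_id` column is present. Empty bins are reported with a zero count.
#'
#' @param calls A calls tibble.
#' @param bins A [size_bins()] object.
#' @return A tibble with `tool_id` (when present), `bin` (ordered factor)
#'   and `n`; bin counts sum to the number of calls.
#' @export
size_histogram <- function(calls, bins = size_bins()) {
  stopifnot(inherits(bins, "size_bins"))
  lab <- factor(bins$labels, levels = bins$labels, ordered = TRUE)
  by_tool <- "tool_id" %in% names(calls)
  if (nrow(calls) == 0L) {
    out <- tibble::tibble(bin = lab, n = 0L)
    if (by_tool) out <- tibble::tibble(tool_id = character(),
                                       bin = lab[0], n = integer())
    return(out)
  }
  sz <- calls$end - calls$start
  binned <- lab[findInterval(sz, bins$edges) + 1L]
  df <- tibble::tibble(bin = binned)
  if (by_tool) df$tool_id <- calls$tool_id
  grp <- if (by_tool) c("tool_id", "bin") else "bin"
  df |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), .drop = FALSE) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)))
}

#' Fraction of a tool's raw calls represented in the consensus
#'
#' The overlap rate of a tool is the percentage of its raw calls that have
#' at least `f` reciprocal overlap with a same-type consensus CNV of the
#' same sample. Rounded half-up to one decimal, matching the conventional
#' reporting style.
#'
#' @param tool_calls One tool's raw calls tibble (>= 1 call).
#' @param consensus The cohort consensus tibble from [call_consensus()].
#' @param params A [consensus_params()]; only `f` is used.
#' @return A single percentage in \[0, 100\].
#' @export
overlap_rate <- function(tool_calls, consensus,
                         params = consensus_params()) {
  stopifnot(inherits(params, "consensus_params"))
  if (nrow(tool_calls) == 0L) {
    abort("Cannot compute an overlap rate for an empty tool call set.")
  }
  hit <- interval_pairs(tool_calls, consensus, params$f, by_sample = TRUE,
                        b_disjoint = FALSE)
  round_half_up(100 * length(unique(hit$i)) / nrow(tool_calls), 1L)
}

#' Per-tool overlap-rate table
#'
#' Convenience wrapper running [overlap_rate()] for every tool in a cohort
#' call set.
#'
#' @param calls The cohort's raw calls tibble (all tools).
#' @param consensus The cohort consensus tibble.
#' @param params A [consensus_params()].
#' @return A tibble with `tool_id`, `n_calls`, `overlap_rate`.
#' @export
overlap_rate_by_tool <- function(calls, consensus,
                                 params = consensus_params()) {
  tools <- sort(unique(calls$tool_id))
  tibble::tibble(
    tool_id = tools,
    n_calls = vapply(tools, function(t) sum(calls$tool_id == t), integer(1)),
    overlap_rate = vapply(tools, function(t) {
      overlap_rate(calls[calls$tool_id == t, , drop = FALSE], consensus,
                   params)
    }, numeric(1))
  )
}

# Exact null distribution of the signed-rank statistic for given |d| ranks:
# generating-function convolution over doubled ranks (integers even with
# mid-ranks), giving P(W2 = k) for k = 0..sum(2r) under random signs.
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  coef <- numeric(total + 1L)
  coef[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), coef[seq_len(total + 1L - r)])
    coef <- coef + shifted
  }
  coef / 2^length(ranks2)
}

#' Paired signed-rank test for deletion/duplication bias
#'
#' Wilcoxon signed-rank test on per-sample paired counts (deletions vs
#' duplications called by one tool), probing whether the tool systematically
#' favours one CNV type. Differences of zero are discarded (classic
#' convention) or down-weighted by Pratt's method; absolute differences are
#' ranked with mid-ranks on ties; the statistic is the sum of the ranks of
#' positive differences. The two-sided p-value is exact (full sign
#' enumeration via a generating-function convolution, valid under ties) for
#' up to 25 nonzero pairs, and uses the tie-corrected normal approximation
#' beyond that. When every difference is zero the result is flagged
#' degenerate with p = 1.
#'
#' @param counts A data frame with integer columns `n_del` and `n_dup`, one
#'   row per sample; alternatively supply the `n_del`/`n_dup` vectors.
#' @param n_del,n_dup Paired count vectors (used when `counts` is `NULL`).
#' @param zero_method `"wilcoxon"` (discard zero differences, default) or
#'   `"pratt"` (rank with zeros included, then drop their ranks).
#' @param exact_max Largest number of nonzero pairs for which the exact
#'   null distribution is enumerated.
#' @return An object of class `signed_rank_test` with fields `n_pairs`
#'   (nonzero differences), `statistic` (W), `p_value`, `method`, and
#'   `degenerate`; see [tidy()] / [glance()].
#' @examples
#' deldup_signed_rank(n_del = c(3, 5, 4, 7), n_dup = c(1, 2, 4, 3))
#' @export
deldup_signed_rank <- function(counts = NULL, n_del = NULL, n_dup = NULL,
                               zero_method = c("wilcoxon", "pratt"),
                               exact_max = 25L) {
  zero_method <- match.arg(zero_method)
  if (!is.null(counts)) {
    stopifnot(all(c("n_del", "n_dup") %in% names(counts)))
    n_del <- counts$n_del; n_dup <- counts$n_dup
  }
  stopifnot(length(n_del) == length(n_dup), length(n_del) >= 1L)
  d <- as.numeric(n_del) - as.numeric(n_dup)
  if (zero_method == "wilcoxon") {
    d_used <- d[d != 0]
    r <- rank(abs(d_used))
  } else {
    r_all <- rank(abs(d))
    d_used <- d[d != 0]
    r <- r_all[d != 0]
  }
  n <- length(d_used)
  if (n == 0L) {
    res <- list(n_pairs = 0L, statistic = 0, p_value = 1,
                method = "degenerate (all differences zero)",
                degenerate = TRUE)
    class(res) <- "signed_rank_test"
    return(res)
  }
  w <- sum(r[d_used > 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    pmf <- signed_rank_null(ranks2)
    obs <- as.integer(round(2 * w))
    p_lo <- sum(pmf[seq_len(obs + 1L)])
    p_hi <- sum(pmf[(obs + 1L):length(pmf)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  res <- list(n_pairs = n, statistic = w, p_value = p, method = method,
              degenerate = FALSE)
  class(res) <- "signed_rank_test"
  res
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test (DEL vs DUP counts)\n")
  cat("  nonzero pairs:", x$n_pairs, "\n")
  cat("  W =", x$statistic, ", two-sided p =", format(x$p_value), "\n")
  cat("  method:", x$method, "\n")
  invisible(x)
}

#' @rdname deldup_signed_rank
#' @param x A `signed_rank_test` object.
#' @param ... Unused.
#' @export
tidy.signed_rank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n.pairs = x$n_pairs, method = x$method,
                 degenerate = x$degenerate)
}

#' @rdname deldup_signed_rank
#' @export
glance.signed_rank_test <- function(x, ...) tidy.signed_rank_test(x)

#' Cohort demographic summary
#'
#' Tabulates a trio cohort: number of complete trios and individuals
#' (3 per trio) and, from a proband phenotype table, per-sex counts and
#' sub-phenotype percentages (of each sex, rounded half-up to one decimal).
#'
#' @param manifest A trio manifest tibble (see [read_trio_manifest()]).
#' @param phenotypes A tibble with columns `sample_id` (proband), `sex`,
#'   `subphenotype`.
#' @return A list of class `cohort_demographics`: `n_trios`,
#'   `n_individuals`, `by_sex`, and a `subphenotypes` tibble with `pct`.
#' @export
cohort_demographics <- function(manifest, phenotypes = NULL) {
  if (nrow(manifest) == 0L) abort("Cohort has no trios.")
  ids <- c("proband_id", "mother_id", "father_id")
  for (i in seq_len(nrow(manifest))) {
    v <- unlist(manifest[i, ids], use.names = FALSE)
    if (anyNA(v) || any(!nzchar(v))) {
      abort(paste0("Incomplete trio '", manifest$trio_id[i],
                   "': proband, mother and father IDs are all required."))
    }
  }
  out <- list(n_trios = nrow(manifest),
              n_individuals = 3L * nrow(manifest),
              by_sex = NULL, subphenotypes = NULL)
  if (!is.null(phenotypes) && nrow(phenotypes) > 0L) {
    ph <- phenotypes[phenotypes$sample_id %in% manifest$proband_id, ,
                     drop = FALSE]
    out$by_sex <- dplyr::count(ph, .data$sex, name = "n")
    out$subphenotypes <- ph |>
      dplyr::count(.data$sex, .data$subphenotype, name = "n") |>
      dplyr::group_by(.data$sex) |>
      dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1L)) |>
      dplyr::ungroup()
  }
  class(out) <- "cohort_demographics"
  out
}

#' @export
print.cohort_demographics <- function(x, ...) {
  cat("Trio cohort:", x$n_trios, "trios,", x$n_individuals, "individuals\n")
  if (!is.null(x$subphenotypes)) {
    print(x$subphenotypes)
  }
  invisible(x)
}
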