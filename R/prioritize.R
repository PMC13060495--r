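#' Human-readable ACMG class labels
#'
#' Maps the 1-5 ACMG structural-variant classification onto its standard
#' wording: 1 benign, 2 likely benign, 3 variant of uncertain significance
#' (VUS), 4 likely pathogenic, 5 pathogenic.
#'
#' @param acmg_class Integer vector with values in 1..5.
#' @return Character vector of labels.
#' @examples
#' acmg_label(c(5, 4, 3))
#' @export
acmg_label <- function(acmg_class) {
  cls <- as.integer(acmg_class)
  if (anyNA(cls) || !all(cls %in% 1:5)) {
    abort("ACMG class must be an integer in 1..5.")
  }
  c("benign", "likely benign", "VUS", "likely pathogenic",
    "pathogenic")[cls]
}

#' Prioritise CNV annotation records
#'
#' Applies the phenotype-driven gates: keep records whose Exomiser score is
#' at least `params$exomiser_min` (inclusive; records with a missing score
#' are dropped) and whose ACMG class is in `params$acmg_keep`. Each kept
#' record is tiered by phenotype consistency: `"highly specific"` when the
#' score strictly exceeds `params$high_specificity_cut` (default 0.7),
#' `"consistent"` otherwise.
#'
#' @param records An annotation tibble (see [read_annotations()]).
#' @param params A [prioritization_params()] object.
#' @return The gated tibble with an added `tier` column and `acmg_label`.
#' @export
filter_priority <- function(records, params = prioritization_params()) {
  stopifnot(inherits(params, "prioritization_params"))
  keep <- !is.na(records$exomiser_score) &
    records$exomiser_score >= params$exomiser_min &
    records$acmg_class %in% params$acmg_keep
  out <- records[keep, , drop = FALSE]
  out$acmg_label <- acmg_label(out$acmg_class)
  out$tier <- ifelse(out$exomiser_score > params$high_specificity_cut,
                     "highly specific", "consistent")
  out
}

#' Build a per-proband prioritised-CNV report
#'
#' Joins prioritised annotation records to trio inheritance calls and emits
#' one row per prioritised CNV in the conventional report layout: patient,
#' coordinates, size (end - start), CNV type, ACMG class and label, top
#' gene, Exomiser score, phenotype tier, and inheritance label. Records are
#' joined on (sample, chromosome, type) by exact coordinates first, falling
#' back to reciprocal overlap at `f`; an annotation record with no
#' inheritance counterpart triggers a warning and is emitted with an `NA`
#' label. The number of distinct probands in the report is messaged and
#' attached as attribute `n_probands`.
#'
#' @param priority Output of [filter_priority()].
#' @param inheritance Output of [classify_trio()] (may cover many trios);
#'   pass a zero-row tibble to skip the join.
#' @param f Reciprocal-overlap fraction for the fallback join.
#' @return A report tibble.
#' @export
build_report <- function(priority, inheritance, f = 0.5) {
  if (nrow(priority) == 0L) {
    message("Report: 0 records after prioritisation.")
    out <- tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          size = numeric(), cnv_type = character(),
                          acmg_class = integer(), acmg_label = character(),
                          top_gene = character(), exomiser_score = numeric(),
                          tier = character(), label = character())
    attr(out, "n_probands") <- 0L
    return(out)
  }
  lab <- rep(NA_character_, nrow(priority))
  if (!is.null(inheritance) && nrow(inheritance) > 0L) {
    for (i in seq_len(nrow(priority))) {
      cand <- inheritance$sample_id == priority$sample_id[i] &
        normalize_chrom(inheritance$chrom) ==
          normalize_chrom(priority$chrom[i]) &
        inheritance$cnv_type == priority$cnv_type[i]
      if (!any(cand)) next
      exact <- cand & inheritance$start == priority$start[i] &
        inheritance$end == priority$end[i]
      if (any(exact)) {
        lab[i] <- inheritance$label[which(exact)[1]]
      } else {
        ok <- which(cand)[passes_reciprocal(
          priority$start[i], priority$end[i],
          inheritance$start[cand], inheritance$end[cand], f = f)]
        if (length(ok)) lab[i] <- inheritance$label[ok[1]]
      }
    }
  }
  if (anyNA(lab)) {
    warn(paste0(sum(is.na(lab)), " prioritised record(s) had no matching ",
                "inheritance call; emitted without a label."))
  }
  out <- tibble::tibble(
    sample_id = priority$sample_id,
    chrom = priority$chrom,
    start = priority$start,
    end = priority$end,
    size = priority$end - priority$start,
    cnv_type = priority$cnv_type,
    acmg_class = priority$acmg_class,
    acmg_label = acmg_label(priority$acmg_class),
    top_gene = priority$top_gene,
    exomiser_score = priority$exomiser_score,
    tier = if ("tier" %in% names(priority)) priority$tier else
      NA_character_,
    label = lab
  )
  out <- out[order(chrom_rank(out$chrom), out$start, out$end,
                   out$sample_id), , drop = FALSE]
  n_prob <- dplyr::n_distinct(out$sample_id)
  message("Report: ", nrow(out), " prioritised CNV(s) across ", n_prob,
          " distinct proband(s).")
  attr(out, "n_probands") <- n_prob
  out
}
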