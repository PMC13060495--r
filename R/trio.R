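# Match each proband region against one parent's regions: same type, same
# chromosome, reciprocal overlap >= f. Returns a tibble of (proband row,
# parent row, fractions). Parental intervals may overlap one another.
match_parent <- function(proband, parent, f) {
  hit <- interval_pairs(proband, parent, f, by_sample = FALSE,
                        b_disjoint = FALSE)
  tibble::tibble(p_row = hit$i, q_row = hit$j,
                 frac_proband = hit$frac_a, frac_parent = hit$frac_b)
}

#' Classify proband CNVs as de novo or inherited
#'
#' A proband CNV is *inherited* when at least one parental CNV of the same
#' type passes the reciprocal-overlap criterion at `params$f`, and *de novo*
#' otherwise — a parental event of the opposite type, or one overlapping
#' below the threshold, does not rescue a call from de novo status (the
#' `parental_matches` list-column lets users inspect borderline cases:
#' de novo calls always have an empty match table). Parental call sets are
#' typically the parents' *consensus* CNVs, but raw per-tool calls collapsed
#' per type can be supplied for a more conservative comparison.
#'
#' @param proband,mother,father Consensus tibbles for the three trio
#'   members (each from [call_consensus()]); the two parental sets may also
#'   be any interval tibble with `chrom`, `start`, `end`, `cnv_type`. Each
#'   parental set must hold disjoint intervals per (chromosome, type).
#' @param params A [consensus_params()]; only `f` is used for matching.
#' @param manifest Optional single-row trio manifest; when supplied, the
#'   `sample_id` columns of the three inputs are checked against it.
#' @return The proband tibble with `label` (one of `de_novo`,
#'   `inherited_maternal`, `inherited_paternal`, `inherited_both`),
#'   `n_parental_matches`, and a `parental_matches` list-column of matching
#'   parental intervals with their reciprocal fractions.
#' @examples
#' pro <- tibble::tibble(chrom = "1", start = 100, end = 200,
#'                       cnv_type = "DEL", sample_id = "P")
#' dad <- tibble::tibble(chrom = "1", start = 110, end = 210,
#'                       cnv_type = "DEL", sample_id = "F")
#' mom <- dad[0, ]
#' classify_trio(pro, mom, dad)$label
#' @export
classify_trio <- function(proband, mother, father,
                          params = consensus_params(), manifest = NULL) {
  stopifnot(inherits(params, "consensus_params"))
  if (!is.null(manifest)) {
    stopifnot(nrow(manifest) == 1L)
    check_one <- function(x, id, who) {
      if (nrow(x) > 0L && !all(x$sample_id == id)) {
        abort(paste0("Sample IDs in the ", who,
                     " call set do not match the manifest (expected '",
                     id, "')."))
      }
    }
    check_one(proband, manifest$proband_id, "proband")
    check_one(mother, manifest$mother_id, "mother")
    check_one(father, manifest$father_id, "father")
  }
  m_hit <- match_parent(proband, mother, params$f)
  f_hit <- match_parent(proband, father, params$f)
  in_m <- seq_len(nrow(proband)) %in% m_hit$p_row
  in_f <- seq_len(nrow(proband)) %in% f_hit$p_row
  label <- dplyr::case_when(
    in_m & in_f ~ "inherited_both",
    in_m ~ "inherited_maternal",
    in_f ~ "inherited_paternal",
    .default = "de_novo"
  )
  match_table <- function(i) {
    mm <- m_hit[m_hit$p_row == i, , drop = FALSE]
    ff <- f_hit[f_hit$p_row == i, , drop = FALSE]
    dplyr::bind_rows(
      if (nrow(mm)) tibble::tibble(
        parent = "mother", chrom = mother$chrom[mm$q_row],
        start = mother$start[mm$q_row], end = mother$end[mm$q_row],
        cnv_type = mother$cnv_type[mm$q_row],
        frac_proband = mm$frac_proband, frac_parent = mm$frac_parent),
      if (nrow(ff)) tibble::tibble(
        parent = "father", chrom = father$chrom[ff$q_row],
        start = father$start[ff$q_row], end = father$end[ff$q_row],
        cnv_type = father$cnv_type[ff$q_row],
        frac_proband = ff$frac_proband, frac_parent = ff$frac_parent)
    )
  }
  out <- proband
  out$label <- label
  out$n_parental_matches <- vapply(seq_len(nrow(proband)), function(i) {
    sum(m_hit$p_row == i) + sum(f_hit$p_row == i)
  }, integer(1))
  out$parental_matches <- lapply(seq_len(nrow(proband)), match_table)
  out
}

#' De novo fraction of a classified call set
#'
#' @param calls Output of [classify_trio()] (rows from one or many trios).
#' @return Fraction of calls labelled `de_novo`, in \[0, 1\].
#' @export
denovo_rate <- function(calls) {
  if (nrow(calls) == 0L) abort("Cannot compute a de novo rate of zero calls.")
  mean(calls$label == "de_novo")
}
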