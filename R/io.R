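#' Normalise CNV type tokens
#'
#' Maps the type vocabulary used by common read-depth callers onto the
#' DEL/DUP dichotomy, case-insensitively: deletion/del/loss and copy-number
#' codes below 2 (`CN0`, `CN1`) become `"DEL"`; duplication/dup/gain and
#' copy-number codes above 2 become `"DUP"`.
#'
#' @param x Character vector of raw type tokens.
#' @return Character vector of `"DEL"`/`"DUP"`.
#' @examples
#' normalize_cnv_type(c("deletion", "Gain", "CN1", "dup"))
#' @export
normalize_cnv_type <- function(x) {
  tok <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(tok))
  out[tok %in% c("DEL", "DELETION", "LOSS", "CN0", "CN1")] <- "DEL"
  out[tok %in% c("DUP", "DUPLICATION", "GAIN", "AMP", "AMPLIFICATION")] <- "DUP"
  cn <- grepl("^CN[0-9]+$", tok)
  if (any(cn & is.na(out))) {
    n_copy <- as.integer(sub("^CN", "", tok[cn & is.na(out)]))
    out[cn & is.na(out)] <- ifelse(n_copy < 2L, "DEL",
                                   ifelse(n_copy > 2L, "DUP", NA_character_))
  }
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    abort(paste0("Unknown CNV type token(s): ",
                 paste(shQuote(bad), collapse = ", "),
                 ". Expected DEL/DUP vocabulary (deletion, loss, CN0/1, ",
                 "duplication, gain, CN3+...)."))
  }
  out
}

# Strip thousands separators ("18,528,750") and parse as numbers; returns NA
# for anything non-numeric so callers can report line-level errors.
parse_coord <- function(x) {
  suppressWarnings(as.numeric(gsub(",", "", trimws(x), fixed = TRUE)))
}

#' Read a CNV call set in the BED-like dialect
#'
#' Reads tab-separated CNV calls: required columns 1-4 are chromosome,
#' start (0-based), end (exclusive) and CNV type; optional columns 5-7 are
#' sample ID, tool ID and a pass-through caller score. Lines starting with
#' `#` or `track` are skipped. Type tokens are normalised via
#' [normalize_cnv_type()]; thousands separators in coordinates are accepted.
#' Calls are returned sorted by (chromosome natural order, start, end).
#'
#' @param path Path to the file.
#' @param tool_id,sample_id Identity of the call set. When the file carries
#'   its own sample/tool columns these arguments are optional; when given
#'   they override the file's values.
#' @return A tibble with columns `chrom`, `start`, `end`, `cnv_type`,
#'   `sample_id`, `tool_id`, `score`.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr12\t153887435\t159145021\tDEL", p)
#' read_callset(p, tool_id = "exomedepth", sample_id = "S1")
#' @seealso [write_callset()]
#' @export
read_callset <- function(path, tool_id = NULL, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|track($|\\s)|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), cnv_type = character(),
                          sample_id = character(), tool_id = character(),
                          score = numeric())
    return(out)
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 4L)) {
    abort(paste0("Line ", rows[which(ncol < 4L)[1]],
                 ": expected >= 4 tab-separated columns (chrom, start, end, ",
                 "cnv_type), got ", ncol[which(ncol < 4L)[1]], "."))
  }
  field <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else NA_character_, "")
  start <- parse_coord(field(2)); end <- parse_coord(field(3))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) {
    abort(paste0("Line ", rows[which(bad)[1]], ": malformed coordinates '",
                 field(2)[which(bad)[1]], "', '", field(3)[which(bad)[1]],
                 "' (integers required)."))
  }
  bad <- end <= start | start < 0
  if (any(bad)) {
    abort(paste0("Line ", rows[which(bad)[1]], ": invalid interval [",
                 start[which(bad)[1]], ", ", end[which(bad)[1]],
                 ") (need 0 <= start < end)."))
  }
  out <- tibble::tibble(
    chrom = field(1),
    start = start,
    end = end,
    cnv_type = normalize_cnv_type(field(4)),
    sample_id = if (!is.null(sample_id)) as.character(sample_id) else field(5),
    tool_id = if (!is.null(tool_id)) as.character(tool_id) else field(6),
    score = parse_coord(ifelse(field(7) %in% c(".", "", NA), NA, field(7)))
  )
  if (anyNA(out$sample_id)) abort("No sample ID: supply `sample_id` or a 5th column.")
  if (anyNA(out$tool_id)) abort("No tool ID: supply `tool_id` or a 6th column.")
  tibble::as_tibble(sort_calls(out))
}

#' Write CNV calls or consensus CNVs in the BED-like dialect
#'
#' Plain calls are written as chrom, start, end, cnv_type, sample_id,
#' tool_id, score (missing scores as `.`). Consensus records (recognised by
#' an `n_tools` column) are written as chrom, start, end, cnv_type, n_tools,
#' comma-joined sorted tool IDs, then sample_id. Reading the file back with
#' [read_callset()] / [read_consensus()] restores every field.
#'
#' @param calls A calls or consensus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(calls, path) {
  if ("n_tools" %in% names(calls)) {
    df <- data.frame(calls$chrom, format_coord(calls$start),
                     format_coord(calls$end), calls$cnv_type,
                     calls$n_tools, calls$tools, calls$sample_id)
  } else {
    score <- if ("score" %in% names(calls)) calls$score else rep(NA_real_, nrow(calls))
    df <- data.frame(calls$chrom, format_coord(calls$start),
                     format_coord(calls$end), calls$cnv_type,
                     calls$sample_id, calls$tool_id,
                     ifelse(is.na(score), ".", as.character(score)))
  }
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read consensus CNVs written by [write_callset()]
#'
#' @param path Path to a consensus BED-dialect file (columns chrom, start,
#'   end, cnv_type, n_tools, tools, sample_id).
#' @return A consensus tibble sorted like [call_consensus()] output.
#' @export
read_consensus <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                            "cnv_type", "n_tools", "tools",
                                            "sample_id"),
                        col_types = "cddcicc", comment = "#",
                        progress = FALSE)
  df$cnv_type <- normalize_cnv_type(df$cnv_type)
  tibble::as_tibble(sort_calls(df))
}

#' Read a trio manifest
#'
#' A tab-separated table with header columns `trio_id`, `proband_id`,
#' `mother_id`, `father_id`. The three member IDs of each trio must be
#' distinct.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with the four columns.
#' @export
read_trio_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("trio_id", "proband_id", "mother_id", "father_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("Manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- df[need]
  dup <- vapply(seq_len(nrow(df)), function(i) {
    anyDuplicated(c(df$proband_id[i], df$mother_id[i], df$father_id[i])) > 0
  }, logical(1))
  if (any(dup)) {
    abort(paste0("Trio '", df$trio_id[which(dup)[1]],
                 "': proband, mother and father IDs must be distinct."))
  }
  tibble::as_tibble(df)
}

# Header synonyms for annotation tables (AnnotSV-style layouts included);
# matching is case-insensitive on the candidates listed per field.
default_annotation_cols <- function() {
  list(
    sample_id      = c("sample_id", "patient_id", "samples_id", "id"),
    chrom          = c("chrom", "sv_chrom", "chr", "chromosome"),
    start          = c("start", "sv_start"),
    end            = c("end", "sv_end"),
    cnv_type       = c("cnv_type", "sv_type", "type"),
    acmg_class     = c("acmg_class", "acmg", "annotsv_ranking_class"),
    exomiser_score = c("exomiser_score", "exomiser_gene_pheno_score"),
    genes          = c("genes", "gene_name", "gene", "genes_in_region"),
    top_gene       = c("top_gene")
  )
}

#' Read a CNV annotation table
#'
#' Reads a header-driven TSV of per-CNV annotations (AnnotSV-style layouts
#' supported through header synonyms or an explicit `col_map`): coordinates,
#' CNV type, ACMG class (1-5), Exomiser score in \[0, 1\], and the gene
#' content of the region. Missing Exomiser scores (`NA`, empty, `.`) are
#' retained with `exomiser_score = NA`; the prioritisation gate excludes
#' them later. Unrecognised columns are passed through untouched.
#'
#' @param path Path to the TSV.
#' @param col_map Named list mapping the canonical field names
#'   (`sample_id`, `chrom`, `start`, `end`, `cnv_type`, `acmg_class`,
#'   `exomiser_score`, `genes`, `top_gene`) to candidate header names;
#'   entries you supply override the defaults.
#' @param gene_delim Delimiter splitting the gene column (default `";"`).
#' @return A tibble with the canonical columns (plus `size` = end - start
#'   and any pass-through columns); `genes` is a list-column of gene-symbol
#'   vectors and `top_gene` falls back to the first listed gene.
#' @export
read_annotations <- function(path, col_map = list(), gene_delim = ";") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  cmap <- utils::modifyList(default_annotation_cols(), col_map)
  lower <- tolower(names(raw))
  locate <- function(field) {
    hit <- match(tolower(cmap[[field]]), lower)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else NA_integer_
  }
  idx <- vapply(names(cmap), locate, integer(1))
  required <- setdiff(names(cmap), "top_gene")
  if (anyNA(idx[required])) {
    abort(paste0("Annotation table is missing required column(s): ",
                 paste(required[is.na(idx[required])], collapse = ", ")))
  }
  clean_gene <- function(g) {
    g <- gsub("\\*", "", trimws(g))
    g[nzchar(g)]
  }
  genes <- lapply(strsplit(raw[[idx[["genes"]]]], gene_delim, fixed = TRUE),
                  clean_gene)
  missing_tok <- c("", "NA", "na", ".", "-")
  score_raw <- trimws(raw[[idx[["exomiser_score"]]]])
  score <- suppressWarnings(as.numeric(ifelse(score_raw %in% missing_tok,
                                              NA, score_raw)))
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    abort("Exomiser scores must lie in [0, 1].")
  }
  acmg <- suppressWarnings(as.integer(trimws(raw[[idx[["acmg_class"]]]])))
  if (anyNA(acmg) || !all(acmg %in% 1:5)) {
    abort("ACMG class must be an integer in 1..5 for every record.")
  }
  out <- tibble::tibble(
    sample_id = raw[[idx[["sample_id"]]]],
    chrom = raw[[idx[["chrom"]]]],
    start = parse_coord(raw[[idx[["start"]]]]),
    end = parse_coord(raw[[idx[["end"]]]]),
    cnv_type = normalize_cnv_type(raw[[idx[["cnv_type"]]]]),
    acmg_class = acmg,
    exomiser_score = score,
    genes = genes,
    top_gene = if (!is.na(idx[["top_gene"]]))
      gsub("\\*", "", trimws(raw[[idx[["top_gene"]]]]))
    else vapply(genes, function(g) if (length(g)) g[1] else NA_character_, "")
  )
  if (anyNA(out$start) || anyNA(out$end) || any(out$end <= out$start)) {
    abort("Annotation coordinates must be integers with end > start.")
  }
  out$size <- out$end - out$start
  extra <- setdiff(seq_along(raw), idx[!is.na(idx)])
  if (length(extra)) out <- dplyr::bind_cols(out, raw[extra])
  out
}
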