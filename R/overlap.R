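#' Reciprocal overlap between genomic intervals
#'
#' Computes, for paired intervals in 0-based half-open coordinates, the
#' shared length and the fraction of each interval that the shared region
#' covers. Intervals on different chromosomes share nothing. All arguments
#' are vectorised and recycled to a common length.
#'
#' @param start1,end1 Coordinates of the first interval(s); `end` exclusive.
#' @param start2,end2 Coordinates of the second interval(s).
#' @param chrom1,chrom2 Optional chromosome names; when supplied, pairs on
#'   different (normalised) chromosomes get zero overlap.
#'
#' @return A tibble with columns `overlap` (shared bp), `frac1`
#'   (`overlap / (end1 - start1)`) and `frac2`.
#' @examples
#' reciprocal_overlap(100, 200, 150, 250)   # half of each
#' reciprocal_overlap(0, 1000, 0, 100)      # asymmetric containment
#' @seealso [passes_reciprocal()]
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  stopifnot(all(end1 > start1), all(end2 > start2))
  n <- max(length(start1), length(start2))
  start1 <- rep_len(as.numeric(start1), n); end1 <- rep_len(as.numeric(end1), n)
  start2 <- rep_len(as.numeric(start2), n); end2 <- rep_len(as.numeric(end2), n)
  ov <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  if (!is.null(chrom1) || !is.null(chrom2)) {
    if (is.null(chrom1) || is.null(chrom2)) {
      abort("Supply both `chrom1` and `chrom2`, or neither.")
    }
    same <- normalize_chrom(rep_len(chrom1, n)) ==
      normalize_chrom(rep_len(chrom2, n))
    ov[!same] <- 0
  }
  tibble::tibble(overlap = ov, frac1 = ov / (end1 - start1),
                 frac2 = ov / (end2 - start2))
}

#' Reciprocal-overlap test
#'
#' `TRUE` when the shared length is at least fraction `f` of *both* interval
#' lengths (the reciprocal criterion, boundary inclusive).
#'
#' @inheritParams reciprocal_overlap
#' @param f Required fraction in (0, 1].
#' @return Logical vector.
#' @examples
#' passes_reciprocal(100, 200, 150, 250, f = 0.5)  # TRUE: exactly half
#' passes_reciprocal(0, 1000, 0, 100, f = 0.5)     # FALSE: 10% of the larger
#' @export
passes_reciprocal <- function(start1, end1, start2, end2, f = 0.5,
                              chrom1 = NULL, chrom2 = NULL) {
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f <= 1)
  fr <- reciprocal_overlap(start1, end1, start2, end2, chrom1, chrom2)
  fr$frac1 >= f & fr$frac2 >= f
}

#' Normalise chromosome names for comparison
#'
#' Strips an optional leading "chr" prefix and upper-cases the rest, so that
#' "chr12", "Chr12" and "12" compare equal while stored names stay verbatim.
#'
#' @param chrom Character vector of chromosome names.
#' @return Normalised character vector.
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX", "MT"))
#' @export
normalize_chrom <- function(chrom) {
  toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
}

# Rank chromosomes in natural order: numeric first, then X, Y, M/MT, then
# anything else alphabetically. Used for all sorted outputs.
chrom_rank <- function(chrom) {
  key <- normalize_chrom(chrom)
  num <- suppressWarnings(as.numeric(key))
  special <- match(key, c("X", "Y", "M", "MT"))
  rank <- ifelse(!is.na(num), num,
                 ifelse(!is.na(special), 1e6 + special, NA_real_))
  other <- is.na(rank)
  if (any(other)) {
    rank[other] <- 2e6 + as.numeric(factor(key[other], levels = sort(unique(key[other]))))
  }
  rank
}

# Sort a calls-like tibble by (chrom natural order, start, end, type, tool).
sort_calls <- function(x) {
  ord_cols <- intersect(c("sample_id", "cnv_type", "tool_id"), names(x))
  x[do.call(order, c(list(chrom_rank(x$chrom), x$start, x$end),
                     unname(as.list(x[ord_cols])))), , drop = FALSE]
}

# Find, between two sets of disjoint sorted half-open intervals, every index
# pair (i, j) with positive overlap. Exploits disjointness: for each a-row the
# overlapping b-rows form a contiguous run located with findInterval.
overlap_join_disjoint <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0L || length(b_start) == 0L) {
    return(list(i = integer(), j = integer()))
  }
  lo <- findInterval(a_start, b_end) + 1L        # first b with b_end >  a_start
  hi <- findInterval(a_end - 0.5, b_start)       # last  b with b_start < a_end
  n <- pmax(0L, hi - lo + 1L)
  list(i = rep.int(seq_along(a_start), n),
       j = sequence(n, from = lo))
}

# Partition possibly-overlapping intervals into "levels" such that intervals
# sharing a level are pairwise disjoint (greedy first-fit over start-sorted
# intervals); lets the sorted disjoint join above serve arbitrary sets.
interval_levels <- function(start, end) {
  n <- length(start)
  lev <- integer(n)
  if (n == 0L) return(lev)
  ord <- order(start, end)
  open_end <- numeric(0)
  for (i in ord) {
    k <- which(open_end <= start[i])
    if (length(k) == 0L) {
      open_end <- c(open_end, end[i])
      lev[i] <- length(open_end)
    } else {
      open_end[k[1]] <- end[i]
      lev[i] <- k[1]
    }
  }
  lev
}

# All overlapping row pairs between two interval tables, grouped by
# (optional sample, normalised chromosome, CNV type), with both overlap
# fractions. Groups are laid out on one axis with a per-group coordinate
# offset so a single sorted sweep covers every group. `b_disjoint = TRUE`
# asserts b's intervals are disjoint within each group (consensus sets are);
# otherwise b is decomposed into disjoint levels first.
interval_pairs <- function(a, b, f = 0, by_sample = TRUE,
                           b_disjoint = FALSE) {
  empty <- list(i = integer(), j = integer(), overlap = numeric(),
                frac_a = numeric(), frac_b = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  key_a <- paste(if (by_sample) a$sample_id else "", normalize_chrom(a$chrom),
                 a$cnv_type)
  key_b <- paste(if (by_sample) b$sample_id else "", normalize_chrom(b$chrom),
                 b$cnv_type)
  keys <- intersect(unique(key_a), unique(key_b))
  if (length(keys) == 0L) return(empty)
  ga <- match(key_a, keys); gb <- match(key_b, keys)
  ia <- which(!is.na(ga)); ib <- which(!is.na(gb))
  off <- max(a$end[ia], b$end[ib]) + 1
  as <- a$start[ia] + ga[ia] * off; ae <- a$end[ia] + ga[ia] * off
  bs <- b$start[ib] + gb[ib] * off; be <- b$end[ib] + gb[ib] * off
  run <- function(sel_b) {
    os <- order(bs[sel_b], be[sel_b])
    sb <- sel_b[os]
    hit <- overlap_join_disjoint(as, ae, bs[sb], be[sb])
    list(i = hit$i, j = sb[hit$j])
  }
  if (b_disjoint) {
    hits <- run(seq_along(bs))
  } else {
    lev <- interval_levels(bs, be)
    parts <- lapply(unique(lev), function(l) run(which(lev == l)))
    hits <- list(i = unlist(lapply(parts, `[[`, "i")),
                 j = unlist(lapply(parts, `[[`, "j")))
  }
  if (length(hits$i) == 0L) return(empty)
  i <- ia[hits$i]; j <- ib[hits$j]
  ov <- pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j])
  frac_a <- ov / (a$end[i] - a$start[i])
  frac_b <- ov / (b$end[j] - b$start[j])
  keep <- frac_a >= f & frac_b >= f
  list(i = i[keep], j = j[keep], overlap = ov[keep],
       frac_a = frac_a[keep], frac_b = frac_b[keep])
}
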