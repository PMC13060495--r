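#' Default emulated caller profiles
#'
#' Four synthetic read-depth caller profiles spanning the behaviours seen in
#' practice among WES CNV callers: a high-sensitivity, high-false-positive
#' caller (`exomedepth`-like), a conservative low-noise caller
#' (`cn_mops`-like, unable to detect events under 1 kb), and two
#' intermediate callers. Sensitivities are per size-bin (recycled scalars
#' here), false positives are a per-sample Poisson mean, and breakpoint
#' jitter is the SD in bp of the rounded normal noise added to each
#' breakpoint.
#'
#' @return A tibble with columns `tool_id`, `sensitivity` (list-column),
#'   `fp_per_sample`, `jitter_sd`, `min_size`.
#' @export
default_tool_profiles <- function() {
  tibble::tibble(
    tool_id = c("gatk_gcnv", "exomedepth", "codex", "cn_mops"),
    sensitivity = list(0.85, 0.95, 0.80, 0.70),
    fp_per_sample = c(3, 8, 4, 1),
    jitter_sd = c(300, 500, 400, 200),
    min_size = c(0, 0, 0, 1000)
  )
}

#' Simulation parameters for a synthetic trio cohort
#'
#' Defines the generative model for a WES-like case-parent trio cohort with
#' known CNV truth: each parent carries a Poisson number of CNVs placed on a
#' small synthetic genome (sizes log-uniform between 500 bp and 6 Mb, equal
#' odds of deletion and duplication), each parental CNV is transmitted to
#' the proband with probability 1/2 at identical coordinates, and each
#' proband additionally acquires a Poisson number of de novo CNVs present in
#' neither parent. Four imperfect callers then observe every individual's
#' truth through per-tool sensitivity, breakpoint jitter, a minimum
#' detectable size, and independent false-positive calls.
#'
#' @param n_trios Number of case-parent trios (default 26).
#' @param chrom_lengths Named vector of chromosome lengths in bp; the
#'   default is two 50 Mb synthetic chromosomes (real chrom.sizes tables can
#'   be supplied for genome-scale runs).
#' @param n_cnv_mean Poisson mean of true CNVs per parent.
#' @param size_range Log-uniform CNV size law bounds in bp.
#' @param p_del Probability that a true CNV is a deletion.
#' @param denovo_mean Poisson mean of de novo CNVs per proband.
#' @param transmission_prob Per-CNV probability of parent-to-proband
#'   transmission.
#' @param tool_profiles Caller-profile tibble, see
#'   [default_tool_profiles()]; `sensitivity` entries may be single numbers
#'   or per-size-bin vectors matching `bins`.
#' @param bins [size_bins()] used for size-dependent sensitivity.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_trios = 26L,
                              chrom_lengths = c(chrA = 5e7, chrB = 5e7),
                              n_cnv_mean = 12,
                              size_range = c(500, 6e6),
                              p_del = 0.5,
                              denovo_mean = 1,
                              transmission_prob = 0.5,
                              tool_profiles = default_tool_profiles(),
                              bins = size_bins()) {
  if (length(chrom_lengths) == 0L || is.null(names(chrom_lengths)) ||
      any(chrom_lengths <= 0)) {
    abort("`chrom_lengths` must be a named vector of positive bp lengths.")
  }
  stopifnot(n_trios >= 1L, n_cnv_mean >= 0, denovo_mean >= 0,
            p_del >= 0, p_del <= 1,
            transmission_prob >= 0, transmission_prob <= 1,
            length(size_range) == 2L, size_range[1] > 0,
            size_range[2] > size_range[1],
            all(c("tool_id", "sensitivity", "fp_per_sample", "jitter_sd",
                  "min_size") %in% names(tool_profiles)))
  structure(
    list(n_trios = as.integer(n_trios), chrom_lengths = chrom_lengths,
         n_cnv_mean = n_cnv_mean, size_range = size_range, p_del = p_del,
         denovo_mean = denovo_mean, transmission_prob = transmission_prob,
         tool_profiles = tool_profiles, bins = bins),
    class = "simulation_params"
  )
}

# Draw one interval (chrom, start, end) not overlapping any interval already
# in `occupied` (a list of chrom/start/end vectors); NULL when placement
# keeps colliding. Sizes are log-uniform over size_range.
draw_interval <- function(params, occupied, max_tries = 60L) {
  lens <- params$chrom_lengths
  for (i in seq_len(max_tries)) {
    size <- round(exp(runif(1, log(params$size_range[1]),
                            log(params$size_range[2]))))
    ok_chr <- names(lens)[lens > size]
    if (length(ok_chr) == 0L) next
    chrom <- sample(ok_chr, 1L, prob = lens[ok_chr])
    start <- floor(runif(1, 0, lens[[chrom]] - size))
    end <- start + size
    if (length(occupied$chrom) > 0L) {
      clash <- occupied$chrom == chrom & occupied$start < end &
        occupied$end > start
      if (any(clash)) next
    }
    return(list(chrom = chrom, start = start, end = end))
  }
  NULL
}

# Per-size sensitivity lookup: scalar profiles recycle, vector profiles are
# indexed by size bin.
sens_for_size <- function(size, sens, bins) {
  if (length(sens) == 1L) return(rep(sens, length(size)))
  stopifnot(length(sens) == length(bins$labels))
  sens[findInterval(size, bins$edges) + 1L]
}

#' Simulate a multi-caller case-parent trio cohort
#'
#' Generates ground-truth CNVs for every trio member and the raw call sets
#' an imperfect panel of callers would report for them; see
#' [simulation_params()] for the generative model. Truth CNVs are placed
#' without overlap within a trio so that inheritance bookkeeping is
#' unambiguous. Fully deterministic given `seed`.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer RNG seed.
#' @return A list of class `cnv_cohort`:
#'   * `truth`: per-individual true CNVs with `origin` (`parental_own`,
#'     `maternal`, `paternal`, `de_novo`) and a shared `cnv_id` linking a
#'     transmitted proband CNV to its parental copy;
#'   * `calls`: raw caller output for every individual and tool, in the
#'     standard calls-tibble layout;
#'   * `manifest`: the trio manifest.
#' @examples
#' sim <- simulate_cohort(simulation_params(n_trios = 2), seed = 7)
#' dplyr::count(sim$calls, tool_id)
#' @export
simulate_cohort <- function(params = simulation_params(), seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(seed)
  profiles <- params$tool_profiles
  manifest <- tibble::tibble(
    trio_id = sprintf("T%02d", seq_len(params$n_trios)),
    proband_id = sprintf("T%02d_pro", seq_len(params$n_trios)),
    mother_id = sprintf("T%02d_mat", seq_len(params$n_trios)),
    father_id = sprintf("T%02d_pat", seq_len(params$n_trios))
  )
  # truth generation: sequential within a trio (rejection sampling keeps the
  # trio's CNVs pairwise disjoint), accumulated in flat vectors
  acc <- list(trio_id = character(), sample_id = character(),
              role = character(), chrom = character(), start = numeric(),
              end = numeric(), cnv_type = character(), origin = character(),
              cnv_id = character())
  cnv_counter <- 0L
  push <- function(acc, trio, sid, role, origin, iv, ty, id) {
    acc$trio_id <- c(acc$trio_id, trio)
    acc$sample_id <- c(acc$sample_id, sid)
    acc$role <- c(acc$role, role)
    acc$chrom <- c(acc$chrom, iv$chrom)
    acc$start <- c(acc$start, iv$start)
    acc$end <- c(acc$end, iv$end)
    acc$cnv_type <- c(acc$cnv_type, ty)
    acc$origin <- c(acc$origin, origin)
    acc$cnv_id <- c(acc$cnv_id, id)
    acc
  }
  for (t in seq_len(params$n_trios)) {
    occ <- list(chrom = character(), start = numeric(), end = numeric())
    grab <- function() {
      iv <- draw_interval(params, occ)
      if (!is.null(iv)) {
        occ$chrom <<- c(occ$chrom, iv$chrom)
        occ$start <<- c(occ$start, iv$start)
        occ$end <<- c(occ$end, iv$end)
      }
      iv
    }
    for (parent in c("mat", "pat")) {
      sid <- if (parent == "mat") manifest$mother_id[t] else
        manifest$father_id[t]
      role <- if (parent == "mat") "mother" else "father"
      for (k in seq_len(rpois(1L, params$n_cnv_mean))) {
        iv <- grab()
        if (is.null(iv)) next
        cnv_counter <- cnv_counter + 1L
        ty <- if (runif(1) < params$p_del) "DEL" else "DUP"
        id <- sprintf("cnv%06d", cnv_counter)
        acc <- push(acc, manifest$trio_id[t], sid, role, "parental_own",
                    iv, ty, id)
        if (runif(1) < params$transmission_prob) {
          acc <- push(acc, manifest$trio_id[t], manifest$proband_id[t],
                      "proband",
                      if (parent == "mat") "maternal" else "paternal",
                      iv, ty, id)
        }
      }
    }
    for (k in seq_len(rpois(1L, params$denovo_mean))) {
      iv <- grab()
      if (is.null(iv)) next
      cnv_counter <- cnv_counter + 1L
      ty <- if (runif(1) < params$p_del) "DEL" else "DUP"
      acc <- push(acc, manifest$trio_id[t], manifest$proband_id[t],
                  "proband", "de_novo", iv, ty,
                  sprintf("cnv%06d", cnv_counter))
    }
  }
  truth <- tibble::as_tibble(acc)
  individuals <- c(manifest$proband_id, manifest$mother_id,
                   manifest$father_id)
  # caller emulation: vectorised over all individuals per tool
  lens <- params$chrom_lengths
  call_rows <- list()
  for (j in seq_len(nrow(profiles))) {
    prof <- profiles[j, ]
    sens_vec <- prof$sensitivity[[1]]
    detected <- NULL
    if (nrow(truth) > 0L) {
      p_det <- sens_for_size(truth$end - truth$start, sens_vec, params$bins)
      hit <- runif(nrow(truth)) < p_det
      if (any(hit)) {
        tv <- truth[hit, , drop = FALSE]
        # breakpoint error scales with event size (segment boundaries track
        # the event) up to the caller's absolute resolution limit
        sd_i <- pmin(prof$jitter_sd, 0.1 * (tv$end - tv$start))
        js <- tv$start + round(rnorm(nrow(tv), 0, sd_i))
        je <- tv$end + round(rnorm(nrow(tv), 0, sd_i))
        js <- pmax(0, js)
        je <- pmin(je, unname(lens[tv$chrom]))
        je <- pmax(je, js + 50)     # jittered size floor
        keep <- (je - js) >= prof$min_size
        if (any(keep)) {
          detected <- tibble::tibble(
            chrom = tv$chrom[keep], start = js[keep], end = je[keep],
            cnv_type = tv$cnv_type[keep], sample_id = tv$sample_id[keep],
            tool_id = prof$tool_id, score = NA_real_)
        }
      }
    }
    # independent false positives: Poisson count per individual, placed
    # uniformly with sizes from the (tool-truncated) size law
    n_fp <- rpois(length(individuals), prof$fp_per_sample)
    fps <- NULL
    if (sum(n_fp) > 0L) {
      fp_sid <- rep(individuals, n_fp)
      m <- length(fp_sid)
      lo <- max(params$size_range[1], prof$min_size, 50)
      fp_size <- round(exp(runif(m, log(lo), log(params$size_range[2]))))
      fp_chrom <- sample(names(lens), m, replace = TRUE, prob = lens)
      fp_start <- unname(floor(runif(m, 0, pmax(1, lens[fp_chrom] - fp_size))))
      fps <- tibble::tibble(
        chrom = fp_chrom, start = fp_start,
        end = unname(pmin(fp_start + fp_size, lens[fp_chrom])),
        cnv_type = ifelse(runif(m) < params$p_del, "DEL", "DUP"),
        sample_id = fp_sid, tool_id = prof$tool_id, score = NA_real_)
    }
    call_rows[[j]] <- dplyr::bind_rows(detected, fps)
  }
  calls <- dplyr::bind_rows(call_rows)
  if (nrow(calls) > 0L) calls <- tibble::as_tibble(sort_calls(calls))
  truth <- tibble::as_tibble(sort_calls(truth))
  structure(list(truth = truth, calls = calls, manifest = manifest,
                 params = params, seed = seed),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("Synthetic CNV cohort:", nrow(x$manifest), "trios,",
      nrow(x$truth), "truth CNVs,", nrow(x$calls), "raw calls from",
      dplyr::n_distinct(x$calls$tool_id), "tools (seed", x$seed, ")\n")
  invisible(x)
}

#' Score a call set against simulated truth
#'
#' Greedy one-to-one matching of calls to truth CNVs within each sample:
#' candidate pairs share chromosome and CNV type and pass reciprocal
#' overlap at `params$f`; pairs are consumed in order of decreasing
#' reciprocal overlap (the smaller of the two fractions), each call and
#' each truth CNV matching at most once.
#'
#' @param truth A truth tibble (from [simulate_cohort()]), any subset.
#' @param calls Any calls-like tibble (raw tool calls or consensus CNVs).
#' @param params A [consensus_params()]; only `f` is used.
#' @return A one-row tibble: `n_true`, `n_called`, `n_matched`,
#'   `precision` (`NA` when nothing was called), `recall`, `f1`.
#' @export
evaluate_calls <- function(truth, calls, params = consensus_params()) {
  stopifnot(inherits(params, "consensus_params"))
  pairs <- greedy_match(truth, calls, params$f)
  n_true <- nrow(truth); n_called <- nrow(calls); n_m <- nrow(pairs)
  precision <- if (n_called > 0L) n_m / n_called else NA_real_
  recall <- if (n_true > 0L) n_m / n_true else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  tibble::tibble(n_true = n_true, n_called = n_called, n_matched = n_m,
                 precision = precision, recall = recall, f1 = f1)
}

# Greedy one-to-one matching; returns a tibble of (truth_row, call_row,
# frac) global row indices.
greedy_match <- function(truth, calls, f) {
  empty <- tibble::tibble(truth_row = integer(), call_row = integer(),
                          frac = numeric())
  if (nrow(truth) == 0L || nrow(calls) == 0L) return(empty)
  hit <- interval_pairs(truth, calls, f, by_sample = TRUE,
                        b_disjoint = FALSE)
  if (length(hit$i) == 0L) return(empty)
  cand <- tibble::tibble(truth_row = hit$i, call_row = hit$j,
                         frac = pmin(hit$frac_a, hit$frac_b))
  cand <- cand[order(-cand$frac, cand$truth_row, cand$call_row), ,
               drop = FALSE]
  used_t <- logical(nrow(truth)); used_c <- logical(nrow(calls))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_t[cand$truth_row[i]] && !used_c[cand$call_row[i]]) {
      keep[i] <- TRUE
      used_t[cand$truth_row[i]] <- TRUE
      used_c[cand$call_row[i]] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' De novo classification confusion matrix against truth
#'
#' Matches proband consensus CNVs (with inheritance labels) one-to-one to
#' proband truth CNVs, then scores de novo detection: a true de novo CNV
#' matched by a call labelled `de_novo` is a true positive; unmatched or
#' mislabelled true de novo CNVs are false negatives; de-novo-labelled
#' calls without a true de novo counterpart (caller artefacts surviving
#' consensus, or mislabelled inherited events) are false positives;
#' inherited-labelled calls matched to inherited truth are true negatives.
#'
#' @param truth The truth tibble from [simulate_cohort()].
#' @param inheritance Labelled proband consensus calls from
#'   [classify_trio()] (all trios together).
#' @param params A [consensus_params()].
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`.
#' @export
denovo_confusion <- function(truth, inheritance,
                             params = consensus_params()) {
  pro_truth <- truth[truth$role == "proband", , drop = FALSE]
  pairs <- greedy_match(pro_truth, inheritance, params$f)
  truth_origin <- pro_truth$origin[pairs$truth_row]
  call_label <- inheritance$label[pairs$call_row]
  tp <- sum(truth_origin == "de_novo" & call_label == "de_novo")
  n_true_dn <- sum(pro_truth$origin == "de_novo")
  fn <- n_true_dn - tp
  n_called_dn <- sum(inheritance$label == "de_novo")
  fp <- n_called_dn - tp
  tn <- sum(truth_origin != "de_novo" & call_label != "de_novo")
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Run the whole pipeline on a simulated cohort
#'
#' Simulation, consensus calling, trio classification, cohort summaries and
#' truth-based evaluation, end to end through the public interfaces. If the
#' simulated cohort exposes fewer tools than the profile table requests
#' (e.g. one caller's output removed), the pipeline proceeds with the
#' remaining tools and messages the change.
#'
#' @param params A [simulation_params()].
#' @param seed Integer RNG seed for the simulation.
#' @param cparams A [consensus_params()] for consensus, trio matching and
#'   evaluation.
#' @param calls Optional pre-simulated calls tibble overriding the
#'   simulated one (e.g. with one tool dropped); the cohort's truth is
#'   still used for evaluation.
#' @return A list of class `cnv_pipeline`: the `cnv_cohort`, `consensus`,
#'   `inheritance`, summary tables (`tool_counts`, `size_dist`,
#'   `overlap_rates`, `deldup_tests`), `evaluation` (per tool and
#'   consensus) and `denovo` (confusion matrix). `tidy()` returns the
#'   evaluation table; `glance()` a one-row overview.
#' @examples
#' \donttest{
#' res <- run_pipeline_end_to_end(simulation_params(n_trios = 4), seed = 1)
#' glance(res)
#' }
#' @export
run_pipeline_end_to_end <- function(params = simulation_params(),
                                    seed = 1L,
                                    cparams = consensus_params(),
                                    calls = NULL) {
  sim <- simulate_cohort(params, seed)
  if (!is.null(calls)) sim$calls <- calls
  tools_present <- sort(unique(sim$calls$tool_id))
  tools_wanted <- sort(params$tool_profiles$tool_id)
  if (!setequal(tools_present, tools_wanted)) {
    message("Pipeline running with tools {",
            paste(tools_present, collapse = ", "), "} instead of {",
            paste(tools_wanted, collapse = ", "), "}.")
  }
  consensus <- call_consensus(sim$calls, cparams)
  inheritance <- purrr::map_dfr(seq_len(nrow(sim$manifest)), function(i) {
    m <- sim$manifest[i, ]
    pick <- function(id) consensus[consensus$sample_id == id, , drop = FALSE]
    classify_trio(pick(m$proband_id), pick(m$mother_id), pick(m$father_id),
                  cparams, manifest = m)
  })
  per_sample <- sim$calls |>
    dplyr::count(.data$tool_id, .data$sample_id, .data$cnv_type) |>
    tidyr::pivot_wider(names_from = "cnv_type", values_from = "n",
                       values_fill = 0L)
  for (ty in c("DEL", "DUP")) {
    if (!ty %in% names(per_sample)) per_sample[[ty]] <- 0L
  }
  deldup <- per_sample |>
    dplyr::group_by(.data$tool_id) |>
    dplyr::group_modify(function(d, key) {
      tidy(deldup_signed_rank(n_del = d$DEL, n_dup = d$DUP))
    }) |>
    dplyr::ungroup()
  evaluation <- dplyr::bind_rows(
    purrr::map_dfr(tools_present, function(t) {
      dplyr::mutate(
        evaluate_calls(sim$truth,
                       sim$calls[sim$calls$tool_id == t, , drop = FALSE],
                       cparams),
        set = t, .before = 1)
    }),
    dplyr::mutate(evaluate_calls(sim$truth, consensus, cparams),
                  set = "consensus", .before = 1)
  )
  res <- list(
    cohort = sim,
    consensus = consensus,
    inheritance = inheritance,
    tool_counts = count_by_tool_type(sim$calls),
    size_dist = size_histogram(sim$calls, params$bins),
    overlap_rates = overlap_rate_by_tool(sim$calls, consensus, cparams),
    deldup_tests = deldup,
    evaluation = evaluation,
    denovo = denovo_confusion(sim$truth, inheritance, cparams),
    cparams = cparams
  )
  class(res) <- "cnv_pipeline"
  res
}

#' @export
print.cnv_pipeline <- function(x, ...) {
  cat("CNV consensus pipeline on", nrow(x$cohort$manifest),
      "simulated trios\n")
  cat("  raw calls:", nrow(x$cohort$calls), " consensus CNVs:",
      nrow(x$consensus), "\n")
  cat("  de novo sensitivity:", format(x$denovo$sensitivity, digits = 3),
      " specificity:", format(x$denovo$specificity, digits = 3), "\n")
  invisible(x)
}

#' @rdname run_pipeline_end_to_end
#' @param x A `cnv_pipeline` object.
#' @param ... Unused.
#' @export
tidy.cnv_pipeline <- function(x, ...) x$evaluation

#' @rdname run_pipeline_end_to_end
#' @export
glance.cnv_pipeline <- function(x, ...) {
  cons <- x$evaluation[x$evaluation$set == "consensus", ]
  tibble::tibble(
    n_trios = nrow(x$cohort$manifest),
    n_raw_calls = nrow(x$cohort$calls),
    n_consensus = nrow(x$consensus),
    consensus_precision = cons$precision,
    consensus_recall = cons$recall,
    denovo_sensitivity = x$denovo$sensitivity,
    denovo_specificity = x$denovo$specificity
  )
}
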