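noise_free_profiles <- function() {
  tibble::tibble(
    tool_id = c("t1", "t2", "t3", "t4"),
    sensitivity = list(1, 1, 1, 1),
    fp_per_sample = 0, jitter_sd = 0, min_size = 0)
}

test_that("simulation is fully deterministic given the seed", {
  prm <- simulation_params(n_trios = 3)
  a <- simulate_cohort(prm, seed = 99)
  b <- simulate_cohort(prm, seed = 99)
  expect_identical(a$truth, b$truth)
  expect_identical(a$calls, b$calls)
  expect_identical(a$manifest, b$manifest)
  c <- simulate_cohort(prm, seed = 100)
  expect_false(identical(a$calls, c$calls))

  # and byte-identical files on repeated runs
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_callset(a$calls, p1); write_callset(b$calls, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("Mendelian bookkeeping: inherited proband CNVs are verbatim parental copies", {
  sim <- simulate_cohort(simulation_params(n_trios = 6), seed = 5)
  tr <- sim$truth
  for (i in which(tr$origin %in% c("maternal", "paternal"))) {
    trio <- sim$manifest[sim$manifest$trio_id == tr$trio_id[i], ]
    parent_id <- if (tr$origin[i] == "maternal") trio$mother_id else
      trio$father_id
    hit <- tr$sample_id == parent_id & tr$cnv_id == tr$cnv_id[i]
    expect_equal(sum(hit), 1L)
    expect_equal(tr$start[hit], tr$start[i])
    expect_equal(tr$end[hit], tr$end[i])
    expect_equal(tr$cnv_type[hit], tr$cnv_type[i])
  }
  # de novo CNVs overlap no parental truth interval
  for (i in which(tr$origin == "de_novo")) {
    trio <- sim$manifest[sim$manifest$trio_id == tr$trio_id[i], ]
    parents <- tr[tr$sample_id %in% c(trio$mother_id, trio$father_id), ]
    clash <- parents$chrom == tr$chrom[i] & parents$start < tr$end[i] &
      parents$end > tr$start[i]
    expect_false(any(clash))
  }
  # origins partition the proband truth set
  pro <- tr[tr$role == "proband", ]
  expect_true(all(pro$origin %in% c("maternal", "paternal", "de_novo")))
})

test_that("with perfect tools every call set equals the truth and consensus recall is 1", {
  prm <- simulation_params(n_trios = 4, tool_profiles = noise_free_profiles())
  sim <- simulate_cohort(prm, seed = 3)
  for (t in unique(sim$calls$tool_id)) {
    tc <- sim$calls[sim$calls$tool_id == t, c("chrom", "start", "end",
                                              "cnv_type", "sample_id")]
    tc <- tc[order(tc$sample_id, tc$chrom, tc$start), ]
    tv <- sim$truth[, c("chrom", "start", "end", "cnv_type", "sample_id")]
    tv <- tv[order(tv$sample_id, tv$chrom, tv$start), ]
    expect_equal(as.data.frame(tc), as.data.frame(tv), ignore_attr = TRUE)
  }
  cons <- call_consensus(sim$calls)
  ev <- evaluate_calls(sim$truth, cons)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(cons$n_tools, rep(4L, nrow(cons)))
})

test_that("a 1 kb minimum detectable size empties the sub-kb bin for that tool", {
  prm <- simulation_params(n_trios = 8)
  sim <- simulate_cohort(prm, seed = 17)
  h <- size_histogram(sim$calls, size_bins())
  sub_kb <- h[h$bin == "<1 kb", ]
  expect_equal(sub_kb$n[sub_kb$tool_id == "cn_mops"], 0L)
  expect_gt(sum(sub_kb$n), 0L)   # other tools do call sub-kb events
})

test_that("evaluation matching is one-to-one and agrees with brute-force matching", {
  truth <- tibble::tibble(chrom = "1", start = 0, end = 1000,
                          cnv_type = "DEL", sample_id = "S")
  calls <- tibble::tibble(chrom = "1", start = c(0, 10), end = c(1000, 1010),
                          cnv_type = "DEL", sample_id = "S")
  ev <- evaluate_calls(truth, calls)
  expect_equal(ev$n_matched, 1L)   # one truth CNV matches at most one call
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 1)

  expect_equal(evaluate_calls(truth, calls[1, ])$precision, 1)
  ev0 <- evaluate_calls(truth, calls[0, ])
  expect_true(is.na(ev0$precision))  # nothing called: precision undefined
  expect_equal(ev0$recall, 0)
  same <- evaluate_calls(truth, truth)
  expect_equal(c(same$precision, same$recall), c(1, 1))
})

test_that("greedy matching prefers the strongest reciprocal overlaps", {
  truth <- tibble::tibble(chrom = "1", start = c(0, 900), end = c(1000, 1900),
                          cnv_type = "DEL", sample_id = "S")
  calls <- tibble::tibble(chrom = "1", start = c(0, 880), end = c(1010, 1900),
                          cnv_type = "DEL", sample_id = "S")
  ev <- evaluate_calls(truth, calls)
  expect_equal(ev$n_matched, 2L)
  expect_equal(ev$f1, 1)
})

test_that("the end-to-end pipeline with no noise makes no de novo classification errors", {
  prm <- simulation_params(n_trios = 4, tool_profiles = noise_free_profiles())
  res <- run_pipeline_end_to_end(prm, seed = 11)
  expect_equal(res$denovo$fp, 0L)
  expect_equal(res$denovo$fn, 0L)
  expect_equal(res$denovo$sensitivity, 1)
  expect_equal(res$denovo$specificity, 1)
  expect_equal(denovo_rate(res$inheritance),
               sum(res$cohort$truth$origin == "de_novo") /
                 sum(res$cohort$truth$role == "proband"))
})

test_that("the pipeline runs with one tool's call set removed and logs the change", {
  prm <- simulation_params(n_trios = 2)
  sim <- simulate_cohort(prm, seed = 23)
  three <- sim$calls[sim$calls$tool_id != "codex", ]
  expect_message(
    res <- run_pipeline_end_to_end(prm, seed = 23, calls = three),
    "instead of")
  expect_setequal(unique(res$tool_counts$tool_id),
                  c("gatk_gcnv", "exomedepth", "cn_mops"))
  expect_gt(nrow(res$consensus), 0L)
})

test_that("glance and tidy expose the pipeline's headline metrics", {
  res <- run_pipeline_end_to_end(simulation_params(n_trios = 2), seed = 41)
  g <- glance(res)
  expect_equal(g$n_trios, 2L)
  expect_true(all(c("consensus_precision", "denovo_sensitivity") %in%
                    names(g)))
  td <- tidy(res)
  expect_true("consensus" %in% td$set)
  expect_equal(nrow(td), 5L)   # 4 tools + consensus
})

test_that("simulation parameter validation rejects degenerate genomes", {
  expect_error(simulation_params(chrom_lengths = c(chrA = 0)), "positive")
  expect_error(simulation_params(chrom_lengths = numeric(0)), "named")
})
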