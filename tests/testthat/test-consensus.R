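three_tool_calls <- function() {
  tibble::tibble(chrom = "1", start = c(0, 40, 80), end = c(100, 140, 180),
                 cnv_type = "DEL", sample_id = "S1",
                 tool_id = c("A", "B", "C"))
}

test_that("pairwise intersection emits intersection-region fragments per passing pair", {
  frags <- intersect_pairwise(three_tool_calls())
  # (A,B) and (B,C) overlap by 60 (0.6 each); (A,C) overlaps 20 (0.2): fails
  expect_equal(nrow(frags), 2L)
  expect_equal(frags$start, c(40, 80))
  expect_equal(frags$end, c(100, 140))
  expect_setequal(paste(frags$tool_a, frags$tool_b), c("A B", "B C"))
  # matches the exhaustive all-pairs oracle
  orc <- oracle_fragments(as.data.frame(three_tool_calls()), 0.5)
  expect_equal(frags[c("start", "end")],
               tibble::tibble(start = sort(orc$start), end = sort(orc$end)))
})

test_that("identical calls from two tools give one fragment; DEL never pairs with DUP", {
  two <- tibble::tibble(chrom = "1", start = 100, end = 200,
                        cnv_type = "DEL", sample_id = "S1",
                        tool_id = c("A", "B"))
  frags <- intersect_pairwise(two)
  expect_equal(nrow(frags), 1L)
  expect_equal(c(frags$start, frags$end), c(100, 200))

  mixed <- two
  mixed$cnv_type <- c("DEL", "DUP")
  expect_equal(nrow(intersect_pairwise(mixed)), 0L)
})

test_that("every fragment is contained in both of its source calls (random instances)", {
  withr::local_seed(7)
  for (rep in 1:25) {
    calls <- random_calls(sample(10:60, 1))
    frags <- intersect_pairwise(calls)
    if (nrow(frags) == 0L) next
    expect_true(all(frags$start >= frags$a_start & frags$end <= frags$a_end))
    expect_true(all(frags$start >= frags$b_start & frags$end <= frags$b_end))
    expect_true(all(frags$frac_a >= 0.5 & frags$frac_b >= 0.5))
  }
})

test_that("same-type fragments merge transitively with tool-set union", {
  frags <- intersect_pairwise(three_tool_calls())
  cons <- merge_fragments(frags)
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(40, 140))
  expect_equal(cons$tools, "A,B,C")
  expect_equal(cons$n_tools, 3L)
})

test_that("DEL and DUP fragments never merge; bookended fragments do merge at gap 0", {
  frags <- tibble::tibble(
    chrom = "1", start = c(0, 0), end = c(50, 50),
    cnv_type = c("DEL", "DUP"), sample_id = "S1",
    tool_a = "A", tool_b = "B")
  cons <- merge_fragments(frags)
  expect_equal(nrow(cons), 2L)
  expect_setequal(cons$cnv_type, c("DEL", "DUP"))

  book <- tibble::tibble(
    chrom = "1", start = c(0, 50), end = c(50, 100),
    cnv_type = "DEL", sample_id = "S1", tool_a = c("A", "A"),
    tool_b = c("B", "C"))
  cons <- merge_fragments(book)
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(0, 100))
  # and the repeated-scan merge oracle agrees
  book$frac_a <- book$frac_b <- 1
  orc <- oracle_merge(as.data.frame(book))
  expect_equal(c(orc$start, orc$end), c(0, 100))
  expect_equal(orc$tools, "A,B,C")
})

test_that("support filtering counts distinct tools and respects min_tools", {
  cons <- tibble::tibble(chrom = "1", start = c(0, 100), end = c(50, 200),
                         cnv_type = "DEL", sample_id = "S1",
                         n_tools = c(2L, 1L), tools = c("A,B", "A"))
  expect_equal(nrow(filter_support(cons, consensus_params(min_tools = 2))), 1L)
  # defensive: a hand-built single-tool record is dropped
  expect_equal(filter_support(cons, consensus_params(min_tools = 2))$tools,
               "A,B")
  # the 3-tool worked example survives min_tools 3 but not 4
  full <- call_consensus(three_tool_calls(), consensus_params(min_tools = 3))
  expect_equal(nrow(full), 1L)
  expect_equal(nrow(call_consensus(three_tool_calls(),
                                   consensus_params(min_tools = 4))), 0L)
})

test_that("a single tool yields empty consensus; unanimity reproduces the call set", {
  one <- tibble::tibble(chrom = "1", start = 0, end = 100,
                        cnv_type = "DEL", sample_id = "S1", tool_id = "A")
  expect_equal(nrow(call_consensus(one)), 0L)

  four <- dplyr::bind_rows(lapply(c("A", "B", "C", "D"), function(t) {
    tibble::tibble(chrom = c("1", "2"), start = c(100, 5000),
                   end = c(900, 9000), cnv_type = c("DEL", "DUP"),
                   sample_id = "S1", tool_id = t)
  }))
  cons <- call_consensus(four)
  expect_equal(nrow(cons), 2L)
  expect_equal(cons$n_tools, c(4L, 4L))
  expect_equal(cons$start, c(100, 5000))
  expect_equal(cons$end, c(900, 9000))
})

test_that("native consensus equals the brute-force reference on random instances", {
  withr::local_seed(123)
  for (rep in 1:60) {
    calls <- random_calls(sample(c(20, 50, 100), 1), n_tools = 4L)
    native <- call_consensus(calls)
    brute <- oracle_consensus(as.data.frame(calls))
    expect_equal(consensus_key(native), consensus_key(brute))
  }
})

test_that("within-tool overlapping duplicates are collapsed before pairing", {
  # tool A reports the same event twice; B once: support must stay 2-of-2,
  # and A's two segments must not create support on their own
  calls <- tibble::tibble(
    chrom = "1", start = c(0, 50, 10), end = c(120, 200, 190),
    cnv_type = "DEL", sample_id = "S1", tool_id = c("A", "A", "B"))
  cons <- call_consensus(calls)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$tools, "A,B")
  only_a <- calls[calls$tool_id == "A", ]
  expect_equal(nrow(call_consensus(only_a)), 0L)
  collapsed <- collapse_within_tool(only_a)
  expect_equal(nrow(collapsed), 1L)
  expect_equal(c(collapsed$start, collapsed$end), c(0, 200))
})

test_that("fragment sets shrink as f rises and consensus shrinks as min_tools rises", {
  withr::local_seed(99)
  for (rep in 1:10) {
    calls <- random_calls(60, n_tools = 4L)
    fs <- c(0.25, 0.5, 0.75, 1)
    n_frag <- vapply(fs, function(f)
      nrow(intersect_pairwise(calls, consensus_params(f = f))), integer(1))
    expect_true(all(diff(n_frag) <= 0))
    n_cons <- vapply(2:4, function(mt)
      nrow(call_consensus(calls, consensus_params(min_tools = mt))),
      integer(1))
    expect_true(all(diff(n_cons) <= 0))
  }
})

test_that("per-sample same-type consensus intervals are disjoint and sorted", {
  withr::local_seed(5)
  for (rep in 1:10) {
    cons <- call_consensus(random_calls(80, n_tools = 4L, n_samples = 2L))
    grp <- split(cons, paste(cons$sample_id, cons$chrom, cons$cnv_type))
    for (g in grp) {
      if (nrow(g) < 2L) next
      expect_true(all(diff(g$start) > 0))
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))  # gap 0 merges bookends
    }
  }
})

test_that("consensus is idempotent when its output is replayed as pseudo-tool calls", {
  withr::local_seed(31)
  for (rep in 1:10) {
    cons <- call_consensus(random_calls(60, n_tools = 4L))
    if (nrow(cons) == 0L) next
    # replay each consensus region as one identical call per supporting tool
    replay <- dplyr::bind_rows(lapply(seq_len(nrow(cons)), function(i) {
      tools <- strsplit(cons$tools[i], ",")[[1]]
      tibble::tibble(chrom = cons$chrom[i], start = cons$start[i],
                     end = cons$end[i], cnv_type = cons$cnv_type[i],
                     sample_id = cons$sample_id[i], tool_id = tools)
    }))
    again <- call_consensus(replay)
    expect_equal(consensus_key(again)[c("chrom", "start", "end", "cnv_type",
                                        "sample_id", "tools")],
                 consensus_key(cons)[c("chrom", "start", "end", "cnv_type",
                                       "sample_id", "tools")])
  }
})

test_that("consensus never pairs calls across samples", {
  calls <- tibble::tibble(chrom = "1", start = 0, end = 100,
                          cnv_type = "DEL", sample_id = c("S1", "S2"),
                          tool_id = c("A", "B"))
  expect_equal(nrow(call_consensus(calls)), 0L)
})
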