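# Independent brute-force reference implementations used as oracles.
# Deliberately naive (all-pairs enumeration, repeated-scan merging) and kept
# free of the package's internal helpers.

# Base-by-base overlap count between two half-open intervals on one chrom.
oracle_overlap_bases <- function(s1, e1, s2, e2) {
  length(intersect(seq.int(s1, e1 - 1L), seq.int(s2, e2 - 1L)))
}

# Collapse overlapping/bookended same-type intervals of one tool by
# repeated scanning.
oracle_collapse <- function(df) {
  repeat {
    merged <- FALSE
    if (nrow(df) < 2L) break
    for (i in seq_len(nrow(df) - 1L)) {
      for (j in (i + 1L):nrow(df)) {
        same <- df$chrom[i] == df$chrom[j] &&
          df$cnv_type[i] == df$cnv_type[j] &&
          df$sample_id[i] == df$sample_id[j] &&
          df$tool_id[i] == df$tool_id[j]
        if (same && df$start[i] <= df$end[j] && df$start[j] <= df$end[i]) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  df
}

# All-pairs fragment enumeration across distinct tools.
oracle_fragments <- function(calls, f, collapse = TRUE) {
  if (collapse) {
    parts <- split(calls, paste(calls$sample_id, calls$tool_id,
                                calls$chrom, calls$cnv_type))
    calls <- do.call(rbind, lapply(parts, oracle_collapse))
  }
  out <- list()
  n <- nrow(calls)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (calls$sample_id[i] != calls$sample_id[j]) next
        if (calls$tool_id[i] == calls$tool_id[j]) next
        if (calls$chrom[i] != calls$chrom[j]) next
        if (calls$cnv_type[i] != calls$cnv_type[j]) next
        L <- max(0, min(calls$end[i], calls$end[j]) -
                   max(calls$start[i], calls$start[j]))
        if (L / (calls$end[i] - calls$start[i]) >= f &&
            L / (calls$end[j] - calls$start[j]) >= f) {
          tools <- sort(c(calls$tool_id[i], calls$tool_id[j]))
          out[[length(out) + 1L]] <- data.frame(
            chrom = calls$chrom[i],
            start = max(calls$start[i], calls$start[j]),
            end = min(calls$end[i], calls$end[j]),
            cnv_type = calls$cnv_type[i],
            sample_id = calls$sample_id[i],
            tool_a = tools[1], tool_b = tools[2])
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), cnv_type = character(),
                      sample_id = character(), tool_a = character(),
                      tool_b = character()))
  }
  do.call(rbind, out)
}

# Transitive same-type merging by repeated scanning; tools tracked as a
# comma-set.
oracle_merge <- function(frags, gap = 0) {
  if (nrow(frags) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), cnv_type = character(),
                      sample_id = character(), tools = character()))
  }
  frags$tools <- paste(frags$tool_a, frags$tool_b, sep = ",")
  repeat {
    merged <- FALSE
    if (nrow(frags) >= 2L) {
      for (i in seq_len(nrow(frags) - 1L)) {
        for (j in (i + 1L):nrow(frags)) {
          same <- frags$chrom[i] == frags$chrom[j] &&
            frags$cnv_type[i] == frags$cnv_type[j] &&
            frags$sample_id[i] == frags$sample_id[j]
          if (same && frags$start[i] <= frags$end[j] + gap &&
              frags$start[j] <= frags$end[i] + gap) {
            frags$start[i] <- min(frags$start[i], frags$start[j])
            frags$end[i] <- max(frags$end[i], frags$end[j])
            frags$tools[i] <- paste(frags$tools[i], frags$tools[j],
                                    sep = ",")
            frags <- frags[-j, , drop = FALSE]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  frags$tools <- vapply(strsplit(frags$tools, ","), function(t)
    paste(sort(unique(t)), collapse = ","), "")
  frags[c("chrom", "start", "end", "cnv_type", "sample_id", "tools")]
}

# Full brute-force consensus reference.
oracle_consensus <- function(calls, f = 0.5, min_tools = 2L, gap = 0) {
  frags <- oracle_fragments(as.data.frame(calls), f)
  cons <- oracle_merge(frags, gap)
  cons$n_tools <- vapply(strsplit(cons$tools, ","), function(t)
    length(unique(t)), integer(1))
  cons <- cons[cons$n_tools >= min_tools, , drop = FALSE]
  cons[order(cons$chrom, cons$start, cons$end, cons$cnv_type,
             cons$sample_id), , drop = FALSE]
}

# Canonical comparable form of a consensus table.
consensus_key <- function(x) {
  x <- as.data.frame(x)[c("chrom", "start", "end", "cnv_type", "sample_id",
                          "n_tools", "tools")]
  x <- x[order(x$chrom, x$start, x$end, x$cnv_type, x$sample_id), ,
         drop = FALSE]
  rownames(x) <- NULL
  x
}

# Exhaustive sign-enumeration two-sided p for the signed-rank statistic
# (zero differences discarded, mid-ranks on ties).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                 mean(w_all >= w_obs - 1e-9)))
}

# Random multi-tool call-set generator for property tests.
random_calls <- function(n_calls, n_tools = 4L, n_samples = 1L,
                         chroms = c("1", "2"), max_coord = 1e5,
                         max_size = 2e4) {
  start <- sample.int(max_coord, n_calls, replace = TRUE)
  size <- sample.int(max_size, n_calls, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n_calls, replace = TRUE),
    start = as.numeric(start),
    end = as.numeric(start + size),
    cnv_type = sample(c("DEL", "DUP"), n_calls, replace = TRUE),
    sample_id = sample(paste0("S", seq_len(n_samples)), n_calls,
                       replace = TRUE),
    tool_id = sample(LETTERS[seq_len(n_tools)], n_calls, replace = TRUE),
    score = NA_real_
  )
}
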