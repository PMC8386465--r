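# Independent oracles and fixture builders.  These deliberately share no
# code with the package implementation.

# Per-column tally of an aligned pair under a named gap policy.
oracle_dist <- function(a, b, mode, count_terminal = TRUE) {
  A <- strsplit(chartr("U.", "T-", toupper(a)), "")[[1]]
  B <- strsplit(chartr("U.", "T-", toupper(b)), "")[[1]]
  stopifnot(length(A) == length(B))
  ga <- A == "-"
  gb <- B == "-"
  keep <- !(ga & gb)
  if (!count_terminal) {
    both <- which(!ga & !gb)
    if (length(both) == 0) return(1)
    keep <- keep & seq_along(A) >= min(both) & seq_along(A) <= max(both)
  }
  units <- 0L; diffs <- 0L; run <- ""
  for (i in which(keep)) {
    if (ga[i] || gb[i]) {
      side <- if (ga[i]) "a" else "b"
      if (mode == "each-gap-a-difference") {
        units <- units + 1L; diffs <- diffs + 1L
      } else if (mode == "gap-run-single-difference") {
        if (run != side) { units <- units + 1L; diffs <- diffs + 1L }
      }
      run <- if (mode == "gap-run-single-difference") side else ""
    } else {
      units <- units + 1L
      if (A[i] != B[i]) diffs <- diffs + 1L
      run <- ""
    }
  }
  if (units == 0) 1 else diffs / units
}

# Exhaustive all-pairs neighbor list (brute force).
oracle_all_pairs <- function(seqs, d_max, mode, count_terminal = TRUE) {
  n <- length(seqs)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- oracle_dist(seqs[i], seqs[j], mode, count_terminal)
      if (d <= d_max + 1e-12)
        out[[length(out) + 1]] <- data.frame(i = i, j = j, distance = d)
    }
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  do.call(rbind, out)
}

random_aligned_seqs <- function(n, len, gap_prob = 0.1, seed = 1) {
  set.seed(seed)
  replicate(n, {
    repeat {
      s <- sample(c("A", "C", "G", "T", "-"), len, replace = TRUE,
                  prob = c(rep((1 - gap_prob) / 4, 4), gap_prob))
      if (!all(s == "-")) break
    }
    paste(s, collapse = "")
  })
}

# Two assignments describe the same partition iff co-membership matches.
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  identical(match(a, unique(a)), match(b, unique(b)))
}

write_fasta <- function(records, path) {
  writeLines(paste0(">", names(records), "\n", unname(records)), path)
  path
}

write_meta <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Random sparse instance on n items: distances uniform below 2*threshold so
# roughly half the pairs are within.
random_instance <- function(n, threshold, seed) {
  set.seed(seed)
  pr <- t(combn(n, 2))
  d <- runif(nrow(pr), 0, 2 * threshold)
  keep <- d <= 2 * threshold
  neighbor_set(data.frame(i = pr[, 1], j = pr[, 2], distance = d)[keep, ],
               n_items = n, d_max = 2 * threshold)
}

# A whole-gene region spec for synthetic sequences of length L.
region_full <- function(L) {
  tibble::tibble(name = "full", ref_start = 1L, ref_end = as.integer(L))
}
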