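# MCC-maximizing iterative OTU assignment, with furthest-neighbor and
# exhaustive oracles.  Truth for a pair of items is "distance <= threshold";
# a call is "co-clustered"; the objective is the Matthews correlation
# coefficient over all item pairs.

#' Matthews correlation coefficient from pair-confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.  A clustering
#' with no false calls of either kind is perfect (1.0); otherwise, if any
#' denominator factor is zero the coefficient is defined as 0.
#'
#' @param confusion named numeric vector with elements `TP`, `TN`, `FP`,
#'   `FN`.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(confusion) {
  mcc_counts(confusion[["TP"]], confusion[["TN"]],
             confusion[["FP"]], confusion[["FN"]])
}

mcc_counts <- function(tp, tn, fp, fn) {
  if (fp == 0 && fn == 0) return(1)
  f1 <- tp + fp; f2 <- tp + fn; f3 <- tn + fp; f4 <- tn + fn
  if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0) return(0)
  (tp * tn - fp * fn) / (sqrt(f1 * f2) * sqrt(f3 * f4))
}

# Move-evaluation objective: MCC on counts shifted by a tiny constant, so
# that states whose exact MCC has a zero denominator (e.g. TN = 0 on tiny
# instances) are still totally ordered and the hill-climb can cross them;
# agrees with the exact MCC to ~1e-9 everywhere else.
mcc_counts_reg <- function(tp, tn, fp, fn, eps = 1e-9) {
  tp <- tp + eps; tn <- tn + eps; fp <- fp + eps; fn <- fn + eps
  (tp * tn - fp * fn) /
    (sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn)))
}

new_partition <- function(otu_of, threshold, confusion, mcc_value, method,
                          mcc_trace = NULL) {
  structure(list(otu_of = otu_of, threshold = threshold,
                 confusion = confusion, mcc = mcc_value, method = method,
                 n_items = length(otu_of), mcc_trace = mcc_trace),
            class = "rrn_partition")
}

#' @export
print.rrn_partition <- function(x, ...) {
  cat("<rrn_partition> ", x$n_items, " items -> ",
      length(unique(x$otu_of)), " OTUs at threshold ", x$threshold,
      " (", x$method, "), MCC = ", format(x$mcc, digits = 4), "\n", sep = "")
  invisible(x)
}

# Canonical OTU labels: 1..K in order of each cluster's smallest member.
canonical_labels <- function(assign) {
  if (length(assign) == 0) return(integer(0))
  first <- tapply(seq_along(assign), assign, min)
  rank <- rank(first)
  unname(as.integer(rank[match(assign, names(first))]))
}

# Adjacency lists of within-threshold pairs.
threshold_adjacency <- function(nbrs, threshold) {
  keep <- nbrs$pairs$distance <= threshold + 1e-12
  ii <- nbrs$pairs$i[keep]; jj <- nbrs$pairs$j[keep]
  adj <- vector("list", nbrs$n_items)
  if (length(ii)) {
    ends <- split(c(jj, ii), c(ii, jj))
    idx <- as.integer(names(ends))
    adj[idx] <- ends
  }
  adj
}

#' Recompute pair-confusion counts of a partition from scratch
#'
#' Independent of any incremental bookkeeping: counts co-clustered pairs
#' against the within-threshold pair set.
#'
#' @param otu_of integer vector assigning each item to an OTU.
#' @param nbrs an `rrn_neighbor_set` covering the items.
#' @param threshold distance threshold (inclusive).
#' @return named vector `TP`, `TN`, `FP`, `FN`.
#' @export
partition_confusion <- function(otu_of, nbrs, threshold) {
  n <- length(otu_of)
  total <- n * (n - 1) / 2
  keep <- nbrs$pairs$distance <= threshold + 1e-12
  ii <- nbrs$pairs$i[keep]; jj <- nbrs$pairs$j[keep]
  npos <- sum(keep)
  tp <- sum(otu_of[ii] == otu_of[jj])
  sizes <- tabulate(otu_of)
  co <- sum(sizes * (sizes - 1) / 2)
  c(TP = tp, TN = total - co - (npos - tp), FP = co - tp, FN = npos - tp)
}

#' MCC-maximizing iterative clustering
#'
#' Starts from all singletons and repeatedly visits items in a seeded
#' random order, moving each to the existing or new cluster that maximizes
#' the global MCC (ties keep the current assignment, then prefer the
#' smallest cluster id; a fresh singleton is considered last).  A pass with
#' no moves, a pass whose total MCC gain is below 1e-10, or 100 passes ends
#' a run.  With `restarts > 1` the best of several seeded runs is returned.
#' Deterministic for fixed `(seed, restarts)`; the caller's RNG stream is
#' left untouched.
#'
#' @param nbrs an `rrn_neighbor_set`.
#' @param threshold clustering threshold; pairs at exactly the threshold
#'   count as within it.  Must not exceed `nbrs$d_max`.
#' @param seed integer seed for the visiting order.
#' @param restarts number of independent seeded runs (default 1).
#' @return an `rrn_partition`; `$mcc_trace` records the objective after
#'   every accepted move (non-decreasing within each run).
#' @export
opticlust_partition <- function(nbrs, threshold, seed = 1L, restarts = 1L) {
  if (threshold > nbrs$d_max + 1e-12)
    stop("configuration error: threshold (", threshold,
         ") exceeds neighbor set d_max (", nbrs$d_max, ")", call. = FALSE)
  n <- nbrs$n_items
  adj <- threshold_adjacency(nbrs, threshold)
  npos <- sum(lengths(adj)) / 2
  total <- n * (n - 1) / 2

  run_once <- function(run_seed) {
    assign <- seq_len(n)
    size <- rep(1L, 2L * n + 1L)
    if (n == 0) size <- integer(0)
    next_id <- n + 1L
    tp <- 0; sumpairs <- 0
    cur_mcc <- mcc_counts_reg(0, total - npos, 0, npos)
    trace <- cur_mcc
    with_seed_local(run_seed, {
      for (pass in seq_len(100L)) {
        ord <- sample.int(n)
        moved <- 0L
        pass_gain <- 0
        for (i in ord) {
          ci <- assign[i]
          nb <- adj[[i]]
          if (is.null(nb)) nb <- integer(0)
          ks <- integer(0); uc <- integer(0)
          if (length(nb)) {
            cl <- assign[nb]
            uc <- sort(unique(cl))
            ks <- tabulate(match(cl, uc), length(uc))
          }
          k_c <- if (ci %in% uc) ks[match(ci, uc)] else 0L
          s_c <- size[ci] - 1L
          tp0 <- tp - k_c
          sp0 <- sumpairs - s_c
          eval_opt <- function(k, s) {
            tpn <- tp0 + k; spn <- sp0 + s
            mcc_counts_reg(tpn, total - spn - npos + tpn, spn - tpn,
                           npos - tpn)
          }
          best_m <- eval_opt(k_c, s_c)  # staying put
          cur_m <- best_m
          best_d <- ci; best_k <- k_c; best_s <- s_c
          for (u in seq_along(uc)) {
            d <- uc[u]
            if (d == ci) next
            m <- eval_opt(ks[u], size[d])
            if (m > best_m + 1e-12) {
              best_m <- m; best_d <- d; best_k <- ks[u]; best_s <- size[d]
            }
          }
          if (s_c > 0) {  # fresh singleton, considered last
            m <- eval_opt(0L, 0L)
            if (m > best_m + 1e-12) {
              best_m <- m; best_d <- 0L; best_k <- 0L; best_s <- 0L
            }
          }
          if (best_d != ci) {
            if (best_d == 0L) {
              best_d <- next_id
              next_id <- next_id + 1L
              if (best_d > length(size)) size <- c(size, rep(0L, n))
              size[best_d] <- 0L
            }
            size[ci] <- size[ci] - 1L
            size[best_d] <- size[best_d] + 1L
            assign[i] <- best_d
            tp <- tp0 + best_k
            sumpairs <- sp0 + best_s
            pass_gain <- pass_gain + (best_m - cur_m)
            cur_mcc <- best_m
            trace <- c(trace, cur_mcc)
            moved <- moved + 1L
          }
        }
        if (moved == 0L || pass_gain < 1e-10) break
      }
    })
    list(assign = assign, tp = tp, sumpairs = sumpairs, mcc = cur_mcc,
         trace = trace)
  }

  best <- NULL
  traces <- list()
  for (r in seq_len(restarts)) {
    res <- run_once(derive_seed(seed, r))
    traces[[r]] <- res$trace
    if (is.null(best) || res$mcc > best$mcc + 1e-12) best <- res
  }
  conf <- c(TP = best$tp,
            TN = total - best$sumpairs - (npos - best$tp),
            FP = best$sumpairs - best$tp,
            FN = npos - best$tp)
  new_partition(canonical_labels(best$assign), threshold, conf, mcc(conf),
                "opticlust", mcc_trace = traces)
}

#' Furthest-neighbor (complete-linkage) clustering
#'
#' Agglomeration in which two clusters merge only while every cross-pair is
#' within the threshold, taking the mergeable pair with the smallest
#' furthest cross distance first.  Pairs absent from the neighbor set are
#' treated as beyond any threshold.  Partitions are nested across
#' thresholds.
#'
#' @inheritParams opticlust_partition
#' @return an `rrn_partition`.
#' @export
complete_linkage_partition <- function(nbrs, threshold) {
  n <- nbrs$n_items
  if (n == 1) {
    return(new_partition(1L, threshold, c(TP = 0, TN = 0, FP = 0, FN = 0), 1,
                         "complete-linkage"))
  }
  m <- matrix(1.5, n, n)
  diag(m) <- 0
  if (nrow(nbrs$pairs)) {
    idx_i <- nbrs$pairs$i; idx_j <- nbrs$pairs$j
    m[cbind(idx_i, idx_j)] <- nbrs$pairs$distance
    m[cbind(idx_j, idx_i)] <- nbrs$pairs$distance
  }
  hc <- stats::hclust(stats::as.dist(m), method = "complete")
  cut <- stats::cutree(hc, h = threshold + 1e-12)
  otu_of <- canonical_labels(as.integer(cut))
  conf <- partition_confusion(otu_of, nbrs, threshold)
  new_partition(otu_of, threshold, conf, mcc(conf), "complete-linkage")
}

#' Exhaustive MCC-optimal clustering (verification oracle)
#'
#' Enumerates every set partition of the items (restricted-growth-string
#' order) and returns one with maximal MCC; ties prefer fewer clusters,
#' then the lexicographically smallest assignment.  Refuses more than 10
#' items.
#'
#' @inheritParams opticlust_partition
#' @return an `rrn_partition`.
#' @export
brute_force_optimal <- function(nbrs, threshold) {
  n <- nbrs$n_items
  if (n > 10)
    stop("brute_force_optimal refuses n_items > 10 (got ", n, ")",
         call. = FALSE)
  if (n <= 1) {
    otu_of <- canonical_labels(seq_len(n))
    conf <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    return(new_partition(otu_of, threshold, conf, 1, "brute-force"))
  }
  keep <- nbrs$pairs$distance <= threshold + 1e-12
  within <- matrix(FALSE, n, n)
  if (any(keep)) {
    within[cbind(nbrs$pairs$i[keep], nbrs$pairs$j[keep])] <- TRUE
  }
  pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
  pj_ <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  truth <- within[cbind(pi_, pj_)]
  npos <- sum(truth)
  total <- length(truth)

  best <- NULL
  assign <- integer(n)
  score <- function() {
    co <- assign[pi_] == assign[pj_]
    tp <- sum(co & truth)
    fp <- sum(co & !truth)
    fn <- npos - tp
    mcc_counts(tp, total - tp - fp - fn, fp, fn)
  }
  rec <- function(i, maxid) {
    if (i > n) {
      m <- score()
      k <- maxid
      if (is.null(best) || m > best$mcc + 1e-12 ||
          (abs(m - best$mcc) <= 1e-12 && k < best$k)) {
        best <<- list(assign = assign, mcc = m, k = k)
      }
      return(invisible())
    }
    for (g in seq_len(maxid + 1L)) {
      assign[i] <<- g
      rec(i + 1L, max(maxid, g))
    }
    invisible()
  }
  if (n > 0) {
    assign[1] <- 1L
    rec(2L, 1L)
  } else {
    best <- list(assign = integer(0), mcc = 1, k = 0L)
  }
  otu_of <- canonical_labels(best$assign)
  conf <- partition_confusion(otu_of, nbrs, threshold)
  new_partition(otu_of, threshold, conf, mcc(conf), "brute-force")
}

#' Write OTU membership in list-format text
#'
#' One line per partition: label, number of OTUs, then one tab-separated
#' field per OTU with comma-joined member ids.
#'
#' @param partition an `rrn_partition`.
#' @param path output path; appended to when it exists.
#' @param ids item names (defaults to 1..n).
#' @export
write_list_format <- function(partition, path,
                              ids = as.character(seq_len(partition$n_items))) {
  groups <- split(ids, partition$otu_of)
  line <- paste(c(format(partition$threshold), length(groups),
                  vapply(groups, paste, "", collapse = ",")),
                collapse = "\t")
  cat(line, "\n", sep = "", file = path, append = file.exists(path))
  invisible(path)
}
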