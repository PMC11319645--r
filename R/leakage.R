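# Leakage control: Hamming distances over 23-nt guide+PAM sequences,
# similarity clustering, source-vs-target filtering, and cluster-aware
# train/test assignment.
#
# Thresholds follow a strict-inequality convention throughout: two guides are
# "linked" iff Hamming(a, b) < link_threshold. The pre-training split links at
# distance < 5, fine-tuning splits link at <= 4 (the same graph), and
# source-vs-target removal drops source guides at distance < 4 from any
# target guide.

#' Hamming distance between two equal-length strings
#' @param a,b character scalars of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stopf("hamming(): length mismatch (%d vs %d)", nchar(a), nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

seq_matrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = n, ncol = L, byrow = TRUE)
}

#' Find all near-duplicate pairs among fixed-length sequences
#'
#' Returns exactly the index pairs at Hamming distance `<= max_dist`.
#' Candidate generation uses pigeonhole segmentation: the sequence is cut
#' into `max_dist + 1` contiguous segments (lengths differing by at most one,
#' e.g. 5,5,5,4,4 for 23-mers at `max_dist = 4`), so any pair within
#' `max_dist` mismatches must agree exactly on at least one segment.
#' Candidates sharing a segment are then verified by exact distance, which
#' avoids the quadratic all-pairs scan on large guide libraries.
#'
#' @param seqs character vector of equal-length sequences.
#' @param max_dist maximum Hamming distance (inclusive).
#' @return integer matrix with columns `i`, `j`, `dist` (`i < j`), zero rows
#'   when no pair qualifies.
#' @export
find_similar_pairs <- function(seqs, max_dist) {
  n <- length(seqs)
  empty <- matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("i", "j", "dist")))
  if (n < 2L) return(empty)
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stopf("sequences must all have the same length")
  if (max_dist >= L) max_dist <- L - 1L

  nseg <- max_dist + 1L
  base <- L %/% nseg; extra <- L %% nseg
  seg_len <- c(rep(base + 1L, extra), rep(base, nseg - extra))
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L

  cand_i <- integer(0); cand_j <- integer(0)
  for (s in seq_len(nseg)) {
    keys <- substr(seqs, seg_start[s], seg_end[s])
    buckets <- split(seq_len(n), keys)
    for (b in buckets) {
      m <- length(b)
      if (m < 2L) next
      pr <- utils::combn(b, 2L)
      cand_i <- c(cand_i, pr[1L, ]); cand_j <- c(cand_j, pr[2L, ])
    }
  }
  if (!length(cand_i)) return(empty)
  key <- unique(cand_i * (n + 1) + cand_j)
  ci <- as.integer(key %/% (n + 1)); cj <- as.integer(key %% (n + 1))

  M <- seq_matrix(seqs)
  d <- rowSums(M[ci, , drop = FALSE] != M[cj, , drop = FALSE])
  keep <- d <= max_dist
  out <- cbind(i = ci[keep], j = cj[keep], dist = as.integer(d[keep]))
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Remove source guides similar to any target guide
#'
#' Drops from the source dataset every record whose 23-nt guide+PAM sequence
#' lies within Hamming distance `<= max_dist` (i.e. `< max_dist + 1`) of a
#' guide in any target dataset, preventing source-to-target leakage during
#' transfer learning. The default `max_dist = 3` implements the
#' "distance < 4" removal rule.
#'
#' @param source a `guide_dataset`.
#' @param targets list of `guide_dataset`s to protect.
#' @param max_dist maximum distance (inclusive) that triggers removal.
#' @param log_path optional TSV path for the removal log
#'   (id, nearest target id, distance).
#' @return filtered source dataset; the removal log is attached as attribute
#'   `"removal_log"`.
#' @export
remove_source_leakage <- function(source, targets, max_dist = 3L, log_path = NULL) {
  src23 <- guide23(source)
  log <- data.frame(id = character(0), nearest_target_id = character(0),
                    dist = integer(0))
  if (length(targets)) {
    tgt23 <- unlist(lapply(targets, guide23))
    tgt_ids <- unlist(lapply(targets, function(d) d$records$id))
    ns <- length(src23)
    pairs <- find_similar_pairs(c(src23, tgt23), max_dist)
    cross <- pairs[, "i"] <= ns & pairs[, "j"] > ns
    if (any(cross)) {
      pc <- pairs[cross, , drop = FALSE]
      ord <- order(pc[, "i"], pc[, "dist"])
      pc <- pc[ord, , drop = FALSE]
      first <- !duplicated(pc[, "i"])
      log <- data.frame(id = source$records$id[pc[first, "i"]],
                        nearest_target_id = tgt_ids[pc[first, "j"] - ns],
                        dist = pc[first, "dist"])
      source <- subset_dataset(source, setdiff(source$records$id, log$id))
    }
  }
  if (n_guides(source) == 0L)
    stopf("leakage removal left zero source records")
  if (!is.null(log_path))
    utils::write.table(log, log_path, sep = "\t", row.names = FALSE, quote = FALSE)
  attr(source, "removal_log") <- log
  source
}

#' Cluster guides by Hamming similarity
#'
#' Connected components of the graph whose edges join guide pairs with
#' Hamming distance `< link_threshold` over the 23-nt guide+PAM sequence,
#' computed with union-find over [find_similar_pairs()] candidates. Any two
#' guides in the same component must stay on the same side of a train/test
#' split.
#'
#' @param ds a `guide_dataset`.
#' @param link_threshold strict distance threshold (edge iff dist < threshold).
#' @return list of clusters, each a character vector of record ids, ordered
#'   by decreasing size with ties broken by lexicographically smallest member
#'   id; each cluster is sorted internally.
#' @export
cluster_guides <- function(ds, link_threshold) {
  seqs <- guide23(ds)
  n <- length(seqs)
  parent <- seq_len(n)
  find_root <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  pairs <- find_similar_pairs(seqs, as.integer(link_threshold) - 1L)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find_root(pairs[k, 1L]); rj <- find_root(pairs[k, 2L])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find_root, 0L)
  comps <- split(ds$records$id, roots)
  comps <- lapply(comps, sort)
  sizes <- lengths(comps)
  mins <- vapply(comps, `[`, "", 1L)
  comps[order(-sizes, mins)]
}

#' Assign whole clusters to train and test sets
#'
#' Clusters are taken in the requested order ("by_size_desc": decreasing
#' size, ties by smallest member id; "random": permuted under `seed`) and
#' greedily assigned to whichever set is currently furthest below its target
#' count, so the achieved test fraction is within `max(cluster size) / N` of
#' the request while no cluster is ever split.
#'
#' @param clusters list of id vectors from [cluster_guides()].
#' @param test_fraction requested test fraction in (0,1).
#' @param ordering `"by_size_desc"` (the pre-training protocol) or
#'   `"random"` (the fine-tuning protocol).
#' @param seed integer seed for `ordering = "random"`.
#' @param link_threshold recorded in the plan for downstream audits.
#' @return a `split_plan`: list with `train_ids`, `test_ids`, `ratio`,
#'   `link_threshold`, `ordering`, `seed`.
#' @export
split_by_clusters <- function(clusters, test_fraction, ordering = c("by_size_desc", "random"),
                              seed = NULL, link_threshold = NA_integer_) {
  ordering <- match.arg(ordering)
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (ordering == "random") {
    if (is.null(seed)) stopf("ordering='random' requires a seed")
    clusters <- with_seed(seed, sample(clusters))
  }
  N <- sum(lengths(clusters))
  target_test <- test_fraction * N
  target_train <- (1 - test_fraction) * N
  n_tr <- 0; n_te <- 0
  train <- character(0); test <- character(0)
  for (cl in clusters) {
    sz <- length(cl)
    if (sz > max(target_train, target_test)) {
      warnf("cluster of size %d exceeds both set quotas; assigned to train", sz)
      train <- c(train, cl); n_tr <- n_tr + sz
      next
    }
    deficit_tr <- target_train - n_tr
    deficit_te <- target_test - n_te
    if (deficit_te > deficit_tr) { test <- c(test, cl); n_te <- n_te + sz }
    else { train <- c(train, cl); n_tr <- n_tr + sz }
  }
  structure(list(train_ids = train, test_ids = test, ratio = test_fraction,
                 link_threshold = as.integer(link_threshold),
                 ordering = ordering, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan>: %d train / %d test (requested test fraction %.3f, link threshold %s)\n",
              length(x$train_ids), length(x$test_ids), x$ratio,
              ifelse(is.na(x$link_threshold), "?", x$link_threshold)))
  invisible(x)
}

#' Cluster-aware train/test split of a dataset
#'
#' Convenience wrapper: cluster at `link_threshold`, then assign whole
#' clusters via [split_by_clusters()].
#'
#' @param ds a `guide_dataset`.
#' @param test_fraction requested test fraction.
#' @param link_threshold strict Hamming link threshold.
#' @param ordering,seed passed to [split_by_clusters()].
#' @return a `split_plan`.
#' @export
split_dataset <- function(ds, test_fraction, link_threshold = 5L,
                          ordering = "by_size_desc", seed = NULL) {
  cl <- cluster_guides(ds, link_threshold)
  split_by_clusters(cl, test_fraction, ordering = ordering, seed = seed,
                    link_threshold = link_threshold)
}

#' Constrain the test set to condition-complete records
#'
#' Moves any test record lacking an efficiency under any of the listed
#' conditions into the train set. Moving records toward train can never
#' violate the cross-set distance invariant.
#'
#' @param plan a `split_plan`.
#' @param ds the `guide_dataset` the plan refers to.
#' @param conditions condition labels that must all be present in test
#'   records; defaults to all of the dataset's conditions.
#' @return the adjusted `split_plan`.
#' @export
constrain_test_complete <- function(plan, ds, conditions = NULL) {
  conditions <- conditions %||% ds$condition_labels
  rec <- ds$records[match(plan$test_ids, ds$records$id), , drop = FALSE]
  complete <- rep(TRUE, nrow(rec))
  for (cond in conditions) complete <- complete & !is.na(rec[[paste0("eff_", cond)]])
  plan$train_ids <- c(plan$train_ids, plan$test_ids[!complete])
  plan$test_ids <- plan$test_ids[complete]
  plan
}

#' Assign clusters to k cross-validation folds
#'
#' Greedy balance: clusters (largest first) go to the currently smallest
#' fold, so no near-duplicate pair ever spans two folds.
#'
#' @param clusters list of id vectors from [cluster_guides()].
#' @param k number of folds (>= 2).
#' @param seed optional seed to permute equal-size choices.
#' @return list of k id vectors.
#' @export
clusters_to_folds <- function(clusters, k, seed = NULL) {
  stopifnot(k >= 2L)
  ord <- order(-lengths(clusters))
  folds <- vector("list", k)
  sizes <- numeric(k)
  jitter <- if (is.null(seed)) rep(0, k) else with_seed(seed, stats::runif(k, 0, 1e-9))
  for (ci in ord) {
    tgt <- which.min(sizes + jitter)
    folds[[tgt]] <- c(folds[[tgt]], clusters[[ci]])
    sizes[tgt] <- sizes[tgt] + length(clusters[[ci]])
  }
  folds
}

#' Serialize a split plan to JSON
#' @param plan a `split_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a split plan from JSON
#' @param path JSON path written by [write_split_plan()].
#' @return a `split_plan`.
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(x$train_ids),
                 test_ids = as.character(x$test_ids),
                 ratio = x$ratio, link_threshold = as.integer(x$link_threshold),
                 ordering = x$ordering, seed = x$seed), class = "split_plan")
}
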