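test_that("hamming counts mismatching positions and enforces equal length", {
  expect_equal(hamming("ACGT", "ACGT"), 0L)
  expect_equal(hamming("ACGT", "ACTT"), 1L)
  expect_error(hamming("ACG", "ACGT"), "length mismatch")
  # naive-loop oracle on random pairs
  g <- paste0(random_guides21(100, seed = 31), "GG")
  pairs <- with_seed(32, cbind(sample(100, 250, TRUE), sample(100, 250, TRUE)))
  for (k in seq_len(nrow(pairs))) {
    a <- g[pairs[k, 1]]; b <- g[pairs[k, 2]]
    expect_identical(hamming(a, b), brute_hamming(a, b))
  }
})

test_that("find_similar_pairs equals brute force on random instances", {
  # identical sequences: all pairs at distance 0
  same <- rep(paste0(strrep("ACGTA", 4), "AGG"), 5)
  pr <- find_similar_pairs(same, 4L)
  expect_equal(nrow(pr), choose(5, 2))
  expect_true(all(pr[, "dist"] == 0L))

  # random 23-mers are pairwise distant: empty result
  far <- paste0(random_guides21(30, seed = 77), "GG")
  expect_equal(nrow(find_similar_pairs(far, 2L)), 0L)

  # oracle equivalence over many random instances, including planted
  # near-duplicates so the candidate stage is actually exercised
  for (rep_i in 1:10) {
    base <- paste0(random_guides21(40, seed = 1000 + rep_i), "GG")
    mut <- vapply(seq_len(20), function(k)
      mutate_seq(base[k], k %% 5 + 1L, seed = 2000 + rep_i * 50 + k), "")
    seqs <- c(base, mut)
    got <- find_similar_pairs(seqs, 4L)
    want <- brute_pairs(seqs, 4L)
    got_keys <- sort(paste(got[, 1], got[, 2], got[, 3]))
    want_keys <- if (is.null(want)) character(0) else sort(paste(want[, 1], want[, 2], want[, 3]))
    expect_identical(got_keys, want_keys)
  }
})

test_that("remove_source_leakage removes exactly the planted near-duplicates", {
  src_g <- random_guides21(60, seed = 11)
  tgt_g <- random_guides21(15, seed = 12)
  # plant k source records that are within distance 3 of target guides
  k <- 7L
  for (i in seq_len(k)) {
    src_g[i] <- substr(mutate_seq(paste0(tgt_g[i], "GG"), i %% 4, seed = 300 + i), 1, 21)
  }
  src <- dataset_from_guides(src_g, name = "src")
  tgt <- dataset_from_guides(tgt_g, name = "tgt")
  filtered <- remove_source_leakage(src, list(tgt), max_dist = 3L)
  expect_equal(n_guides(filtered), 60L - k)
  expect_setequal(attr(filtered, "removal_log")$id, src$records$id[seq_len(k)])
  # survivor invariant: no remaining record within distance 3 of any target
  for (s in guide23(filtered)) for (t in guide23(tgt))
    expect_gte(brute_hamming(s, t), 4L)
  # empty target list leaves the source unchanged
  same <- remove_source_leakage(src, list())
  expect_equal(n_guides(same), 60L)
})

test_that("cluster_guides matches brute-force transitive closure and is order-invariant", {
  # chain a-b (d=2), b-c (d=2), a-c (d=4) with threshold 5 -> one cluster
  a <- paste0(strrep("A", 21), "GG")
  b <- mutate_seq(a, 2, seed = 5)
  cvec <- strsplit(a, "")[[1]]; bvec <- strsplit(b, "")[[1]]
  diffpos <- which(cvec != bvec)
  cc <- bvec
  others <- setdiff(1:21, diffpos)[1:2]
  for (p in others) cc[p] <- "C"
  cseq <- paste(cc, collapse = "")
  stopifnot(brute_hamming(a, cseq) == 4L, brute_hamming(b, cseq) == 2L)
  ds <- guide_dataset(tibble::tibble(id = c("a", "b", "c"),
                                     guide21 = substr(c(a, b, cseq), 1, 21),
                                     eff_eff = c(0.1, 0.5, 0.9)))
  cl <- cluster_guides(ds, link_threshold = 5L)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]], c("a", "b", "c"))

  # random instance vs brute force components
  base <- random_guides21(60, seed = 21)
  extra <- vapply(1:40, function(k) substr(mutate_seq(paste0(base[k %% 60 + 1], "GG"),
                                                      k %% 4 + 1L, seed = 400 + k), 1, 21), "")
  guides <- c(base, extra)
  ds2 <- dataset_from_guides(guides, name = "cl")
  cl2 <- cluster_guides(ds2, link_threshold = 5L)
  comp <- brute_components(paste0(guides, "GG"), 5L)
  want <- unname(lapply(split(ds2$records$id, comp), sort))
  got <- unname(cl2)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))

  # shuffling records yields the identical partition (as id sets)
  perm <- with_seed(9, sample(n_guides(ds2)))
  ds3 <- ds2; ds3$records <- ds2$records[perm, ]
  cl3 <- cluster_guides(ds3, link_threshold = 5L)
  expect_setequal(unname(vapply(cl3, paste, "", collapse = ",")),
                  unname(vapply(cl2, paste, "", collapse = ",")))
})

test_that("split_by_clusters balances quotas and never splits a cluster", {
  # 100 singletons at 0.15 -> exactly 15 test
  singles <- lapply(1:100, function(i) sprintf("g%03d", i))
  plan <- split_by_clusters(singles, 0.15)
  expect_length(plan$test_ids, 15L)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0L)

  # one giant cluster -> all train plus a warning
  expect_warning(plan2 <- split_by_clusters(list(as.character(1:50)), 0.2),
                 "exceeds both set quotas")
  expect_length(plan2$test_ids, 0L)
  expect_length(plan2$train_ids, 50L)
})

test_that("emitted split plans have no cross-set pair below the link threshold", {
  base <- random_guides21(80, seed = 51)
  extra <- vapply(1:60, function(k) substr(mutate_seq(paste0(base[k %% 80 + 1], "GG"),
                                                      k %% 4 + 1L, seed = 800 + k), 1, 21), "")
  ds <- dataset_from_guides(c(base, extra), name = "sp")
  for (thr in c(4L, 5L)) for (ord in c("by_size_desc", "random")) {
    plan <- split_dataset(ds, 0.2, link_threshold = thr, ordering = ord, seed = 3L)
    tr <- paste0(ds$records$guide21[ds$records$id %in% plan$train_ids], "GG")
    te <- paste0(ds$records$guide21[ds$records$id %in% plan$test_ids], "GG")
    min_cross <- min(vapply(te, function(t) min(vapply(tr, function(s)
      brute_hamming(s, t), 0L)), 0L))
    expect_gte(min_cross, thr)
  }
})

test_that("constrain_test_complete moves incomplete records to train", {
  guides <- random_guides21(20, seed = 61)
  rec <- tibble::tibble(id = sprintf("g%02d", 1:20), guide21 = guides,
                        eff_WT = stats::runif(20), eff_Esp = stats::runif(20),
                        eff_HF = stats::runif(20))
  rec$eff_HF[c(2, 5, 8, 11)] <- NA  # 20% incomplete
  ds <- guide_dataset(rec, condition_labels = c("WT", "Esp", "HF"))
  plan <- split_dataset(ds, 0.5, link_threshold = 5L)
  n_te_before <- length(plan$test_ids)
  plan2 <- constrain_test_complete(plan, ds)
  rec_te <- ds$records[ds$records$id %in% plan2$test_ids, ]
  expect_true(all(!is.na(rec_te$eff_WT) & !is.na(rec_te$eff_Esp) & !is.na(rec_te$eff_HF)))
  moved <- n_te_before - length(plan2$test_ids)
  expect_equal(length(plan2$train_ids), length(plan$train_ids) + moved)
  # a fully complete plan is unchanged
  rec$eff_HF <- stats::runif(20)
  ds_c <- guide_dataset(rec, condition_labels = c("WT", "Esp", "HF"))
  plan3 <- split_dataset(ds_c, 0.5, link_threshold = 5L)
  expect_identical(constrain_test_complete(plan3, ds_c), plan3)
})

test_that("split plans serialize and round-trip through JSON", {
  ds <- dataset_from_guides(random_guides21(30, seed = 71))
  plan <- split_dataset(ds, 0.2, link_threshold = 5L, ordering = "random", seed = 8L)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_split_plan(plan, tmp)
  back <- read_split_plan(tmp)
  expect_identical(back$train_ids, plan$train_ids)
  expect_identical(back$test_ids, plan$test_ids)
  expect_identical(back$link_threshold, plan$link_threshold)
})
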