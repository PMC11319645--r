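# Shared fixtures: everything is generated programmatically at test time.

with_seed <- crisprtl:::with_seed

# small synthetic pair reused by several files (memoised per session)
tiny_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_pair(sim_config(n_source = 120L, n_target = 40L, seed = 404L))
    cache
  }
})

random_guides21 <- function(n, seed) {
  with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = ""), ""))
}

# minimal dataset straight from 21-nt guides
dataset_from_guides <- function(guides, eff = NULL, name = "toy") {
  n <- length(guides)
  if (is.null(eff)) eff <- seq(0, 1, length.out = n)
  guide_dataset(tibble::tibble(id = sprintf("%s_%03d", name, seq_len(n)),
                               guide21 = guides, eff_eff = eff), name = name)
}

# brute-force Hamming distance matrix via a naive position loop
brute_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  d <- 0L
  for (k in seq_along(av)) if (av[k] != bv[k]) d <- d + 1L
  d
}

brute_pairs <- function(seqs, max_dist) {
  out <- NULL
  n <- length(seqs)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- brute_hamming(seqs[i], seqs[j])
    if (d <= max_dist) out <- rbind(out, c(i, j, d))
  }
  out
}

# transitive closure components over a brute-force adjacency matrix
brute_components <- function(seqs, link_threshold) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- brute_hamming(seqs[i], seqs[j]) < link_threshold
  comp <- rep(0L, n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cid
      frontier <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & comp == 0L)
    }
  }
  comp
}

# mutate a 23-mer (or any sequence) at `k` distinct random positions
mutate_seq <- function(seq, k, seed) {
  crisprtl:::with_seed(seed, {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  })
}

# independent quadratic oracle for near-duplicate search: row-vs-matrix
# comparisons over a character matrix, no segmentation/hashing involved
quad_pairs <- function(seqs, max_dist) {
  n <- length(seqs)
  M <- do.call(rbind, strsplit(seqs, ""))
  out <- NULL
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    d <- rowSums(M[rest, , drop = FALSE] != matrix(M[i, ], length(rest),
                                                   ncol(M), byrow = TRUE))
    hit <- which(d <= max_dist)
    if (length(hit)) out <- rbind(out, cbind(i, rest[hit], d[hit]))
  }
  out
}

small_rnn_spec <- function() model_spec("rnn", hyper = list(
  embedding_dim = 4L, recurrent_units = 6L, dense_sizes = c(8L)))

small_cnn_spec <- function() model_spec("cnn", hyper = list(
  conv_filters = c(5L, 5L, 5L), branch_dense = 8L, dense_sizes = c(8L)))
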