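test_that("read_dataset ingests 23-nt sequences, rejects bad rows with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("seq,eff",
               "ACGTACGTACGTACGTACGTAGG,0.2",
               "TTTTACGTACGTACGTACGTAGG,0.9",
               "GGGGACGTACGTACGTACGTAGG,0.5"), tmp)
  ds <- read_dataset(tmp, schema = list(sequence = "seq", efficiencies = c(eff = "eff")))
  expect_equal(n_guides(ds), 3L)
  expect_equal(ds$records$guide21[1], "ACGTACGTACGTACGTACGTA")
  expect_equal(ds$records$eff_eff, c(0.2, 0.9, 0.5))

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("seq,eff",
               "ACGTACGTACGTACGTACGTAAG,0.2",   # ends AG, must be rejected
               "ACGTACGTACGTACGTACGTAGG,0.9",
               "ACGTACGTNCGTACGTACGTAGG,0.5"), tmp2)  # bad alphabet
  expect_warning(ds2 <- read_dataset(tmp2, schema = list(sequence = "seq",
                                                         efficiencies = c(eff = "eff"))),
                 "rejected")
  expect_equal(n_guides(ds2), 1L)
  rej <- attr(ds2, "rejected")
  expect_setequal(rej$line, c(2L, 4L))
  expect_match(rej$reason[rej$line == 2L], "GG")
})

test_that("30-nt contexts are stored with the guide derived from the fixed layout", {
  ctx <- paste0("TTTT", "ACGTACGTACGTACGTACGT", "AGG", "CCC")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tscore", paste0(ctx, "\t0.4"), paste0(ctx, "\tnot_a_number")), tmp)
  ds <- read_dataset(tmp, schema = list(sequence = "sequence",
                                        efficiencies = c(eff = "score")))
  expect_equal(ds$records$context30[1], ctx)
  expect_equal(ds$records$guide21[1], "ACGTACGTACGTACGTACGTA")
  expect_equal(substr(ds$records$context30[1], 26, 27), "GG")
  # unparseable efficiency becomes an absent entry, row is kept
  expect_true(is.na(ds$records$eff_eff[2]))
  expect_equal(n_guides(ds), 2L)
})

test_that("ingestion round-trips losslessly for valid rows", {
  pair <- tiny_pair()
  ds <- pair$target
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, tmp)
  back <- read_dataset(tmp, schema = list(sequence = "context30", id = "id",
                                          efficiencies = c(eff = "eff_eff")))
  expect_equal(back$records$guide21, ds$records$guide21)
  expect_equal(back$records$context30, ds$records$context30)
  expect_equal(back$records$eff_eff, ds$records$eff_eff, tolerance = 0)
})

test_that("zero valid rows is a hard error", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("seq,eff", "NNNN,0.5"), tmp)
  expect_error(
    read_dataset(tmp, schema = list(sequence = "seq", efficiencies = c(eff = "eff"))),
    "no valid rows")
})

test_that("minmax_normalize maps to [0,1], preserves ranks, is idempotent", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  v01 <- c(0, 0.25, 0.8, 1)
  expect_equal(minmax_normalize(v01), v01)
  v <- with_seed(7, stats::rnorm(50))
  out <- minmax_normalize(v)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_equal(stats::cor(v, out, method = "spearman"), 1)
  expect_equal(minmax_normalize(out), out)
  expect_error(minmax_normalize(rep(2, 5), name = "const_col"), "const_col")
})

test_that("normalize_dataset records per-condition raw min/max", {
  guides <- random_guides21(6, seed = 1)
  # raw-scale ingestion is allowed, but [0,1] is enforced by default
  raw <- tibble::tibble(id = as.character(1:6), guide21 = guides,
                        eff_a = c(2, 4, 6, 8, 10, NA))
  expect_error(guide_dataset(raw, condition_labels = "a"), "normalize")
  ds <- guide_dataset(raw, condition_labels = "a", check_range = FALSE)
  d2 <- normalize_dataset(ds)
  expect_equal(d2$norm$a$min, 2)
  expect_equal(d2$norm$a$max, 10)
  expect_equal(range(d2$records$eff_a, na.rm = TRUE), c(0, 1))
  expect_equal(d2$records$eff_a[1:5], (c(2, 4, 6, 8, 10) - 2) / 8)
})

test_that("rnn encoding is [START] + 21 tokens with correct indicator and round-trip", {
  guides <- c(strrep("A", 21), "ACGTACGTACGTACGTACGTA")
  ds <- dataset_from_guides(guides, eff = c(0.1, 0.9))
  ds <- attach_biofeatures(ds)
  b <- encode_rnn(ds)
  expect_equal(dim(b$tokens), c(2L, 22L))
  expect_equal(b$tokens[1, ], c(1L, rep(2L, 21)))  # START then A tokens
  expect_equal(decode_rnn(b$tokens), guides)

  # multi-task indicator follows the declared condition order
  rec <- tibble::tibble(id = c("g1", "g2"), guide21 = guides,
                        eff_WT = c(0.1, 0.4), eff_Esp = c(0.2, NA), eff_HF = c(NA, 0.6))
  mt <- attach_biofeatures(guide_dataset(rec, condition_labels = c("WT", "Esp", "HF")))
  bw <- encode_rnn(mt, condition = "WT")
  expect_equal(bw$enzyme[1, ], c(1, 0, 0))
  flat <- encode_rnn_multitask(mt)
  expect_equal(flat$n, 4L)  # observed (guide, enzyme) pairs only
  expect_equal(colSums(flat$enzyme), c(2, 1, 1))

  # round-trip over random guides
  g100 <- random_guides21(100, seed = 99)
  ds100 <- attach_biofeatures(dataset_from_guides(g100))
  expect_equal(decode_rnn(encode_rnn(ds100)$tokens), g100)
})

test_that("cnn encoding is a valid one-hot with energy side input, injective", {
  pair <- tiny_pair()
  ds <- pair$target
  b <- encode_cnn(ds)
  expect_equal(ncol(b$onehot), 120L)
  rows_ok <- apply(b$onehot, 1L, function(r) all(rowSums(matrix(r, 30, 4, byrow = TRUE)) == 1))
  expect_true(all(rows_ok))
  # all-A context maps to the A column within the variable positions
  ctxA <- paste0(strrep("A", 25), "GG", "AAA")
  dsA <- guide_dataset(tibble::tibble(id = "a", guide21 = substr(ctxA, 5, 25),
                                      context30 = ctxA, eff_eff = 0.5,
                                      energy_score = -1))
  bA <- encode_cnn(dsA)
  M <- matrix(bA$onehot[1, ], 30, 4, byrow = TRUE)
  expect_equal(sum(M[, 1]), 28)  # A everywhere except the two fixed Gs
  # injectivity on distinct contexts
  keys <- apply(b$onehot, 1L, paste, collapse = "")
  expect_equal(anyDuplicated(keys), 0L)
  # missing prerequisites are named errors
  ds_nog <- dataset_from_guides(random_guides21(3, 5))
  expect_error(encode_cnn(ds_nog), "context30")
  expect_error(encode_rnn(ds_nog), "bio-features")
})

test_that("encoders are deterministic", {
  pair <- tiny_pair()
  b1 <- encode_cnn(pair$target)
  b2 <- encode_cnn(pair$target)
  expect_identical(b1$onehot, b2$onehot)
  src <- pair$source
  expect_identical(encode_rnn(src)$tokens, encode_rnn(src)$tokens)
})
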