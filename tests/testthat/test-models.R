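test_that("builds are seed-deterministic and parameter groups partition all parameters", {
  spec <- small_rnn_spec()
  m1 <- build_model(spec, seed = 11)
  m2 <- build_model(spec, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(spec, seed = 12)
  expect_false(identical(m1$params, m3$params))
  for (m in list(m1, build_model(small_cnn_spec(), seed = 1))) {
    expect_setequal(names(m$groups), names(m$params))
    expect_true(all(m$groups %in% crisprtl:::PARAM_GROUPS))
    expect_true(any(m$groups == "last_hidden") || any(m$groups == "output"))
  }
})

test_that("parameter count matches the closed-form formula for a tiny rnn spec", {
  d <- 4L; h <- 8L; dn <- 8L
  spec <- model_spec("rnn", hyper = list(embedding_dim = d, recurrent_units = h,
                                         dense_sizes = c(dn)))
  m <- build_model(spec, seed = 1)
  flat <- 22L * 2L * h  # flattened bidirectional output sequence
  want <- 5L * d +                                  # embedding
    2L * (d * 4L * h + h * 4L * h + 4L * h) +       # two LSTM directions
    (flat + 11L) * dn + dn +                        # dense hidden
    dn * 1L + 1L                                    # output
  expect_equal(n_params(m), want)
})

test_that("forward pass is finite, deterministic, and batch-composition invariant", {
  pair <- tiny_pair()
  specs <- list(rnn = small_rnn_spec(), cnn = small_cnn_spec())
  batches <- list(rnn = encode_rnn(pair$target), cnn = encode_cnn(pair$target))
  for (kind in names(specs)) {
    m <- build_model(specs[[kind]], seed = 21)
    b <- batches[[kind]]
    p1 <- predict(m, b)
    expect_true(all(is.finite(p1)))
    expect_identical(p1, predict(m, b))
    # single-record prediction equals its value within the batch
    for (i in c(1L, 5L)) {
      pi <- predict(m, crisprtl:::batch_subset(b, i))
      expect_equal(pi, p1[i], tolerance = 1e-6)
    }
    # kind mismatch is an error
    other <- batches[[setdiff(names(batches), kind)]]
    expect_error(predict(m, other), "does not match")
  }
  # cnn forward on a zero tensor + zero energy is a finite scalar
  mc <- build_model(specs$cnn, seed = 2)
  zb <- structure(list(kind = "cnn", onehot = matrix(0, 1, 120),
                       energy = matrix(0, 1, 1), y = 0, ids = "z", n = 1L),
                  class = "encoded_batch")
  expect_true(is.finite(predict(mc, zb)))
})

test_that("ensembles average member predictions", {
  pair <- tiny_pair()
  b <- encode_cnn(pair$target)
  spec <- small_cnn_spec()
  m1 <- build_model(spec, seed = 1)
  # singleton ensemble is its member
  e1 <- ensemble_model(list(m1))
  expect_equal(predict(e1, b), predict(m1, b))
  # identical members equal any member
  ek <- ensemble_model(list(m1, m1, m1))
  expect_equal(predict(ek, b), predict(m1, b))
  # manual elementwise-mean oracle for distinct members
  ms <- lapply(1:3, function(s) build_model(spec, seed = s))
  e3 <- ensemble_model(ms)
  manual <- (predict(ms[[1]], b) + predict(ms[[2]], b) + predict(ms[[3]], b)) / 3
  expect_equal(predict(e3, b), manual)
  expect_error(ensemble_model(list(m1, build_model(small_rnn_spec(), 1))), "share")
})

test_that("freeze masks expose the contracted group sets", {
  spec_r <- small_rnn_spec(); spec_c <- small_cnn_spec()
  all_tags <- crisprtl:::PARAM_GROUPS
  expect_setequal(freeze_mask(spec_r, "full"), all_tags)
  expect_setequal(freeze_mask(spec_r, "gradual_phase2"), all_tags)
  expect_setequal(freeze_mask(spec_r, "last_layer"), c("last_hidden", "output"))
  expect_setequal(freeze_mask(spec_r, "gradual_phase1"), c("last_hidden", "output"))
  expect_setequal(freeze_mask(spec_c, "no_input_layer"),
                  setdiff(all_tags, "input_embedding_or_conv"))
  # on the cnn, no_input_layer excludes exactly the convolution-branch parameters
  m <- build_model(spec_c, seed = 1)
  frozen <- names(m$groups)[!m$groups %in% freeze_mask(spec_c, "no_input_layer")]
  expect_setequal(frozen, grep("^conv", names(m$params), value = TRUE))
  # on the rnn, last_layer excludes embedding and recurrent parameters
  mr <- build_model(spec_r, seed = 1)
  trainable <- names(mr$groups)[mr$groups %in% freeze_mask(spec_r, "last_layer")]
  expect_false(any(grepl("^(embedding|lstm)", trainable)))
})

test_that("multi-task spec wires the enzyme indicator and rejects mismatched batches", {
  guides <- random_guides21(8, seed = 33)
  rec <- tibble::tibble(id = sprintf("g%d", 1:8), guide21 = guides,
                        eff_WT = stats::runif(8), eff_Esp = stats::runif(8),
                        eff_HF = stats::runif(8))
  ds <- attach_biofeatures(guide_dataset(rec, condition_labels = c("WT", "Esp", "HF")))
  spec_mt <- model_spec("rnn", multi_task = TRUE,
                        hyper = list(embedding_dim = 4L, recurrent_units = 4L,
                                     dense_sizes = c(6L)))
  m <- build_model(spec_mt, seed = 3)
  b <- encode_rnn_multitask(ds)
  expect_length(predict(m, b), b$n)
  # single-task batch against a multi-task model fails loudly
  b1 <- encode_rnn(ds, condition = "WT")
  b1$enzyme <- NULL
  expect_error(predict(m, b1), "enzyme indicator")
  # and the converse
  ms <- build_model(small_rnn_spec(), seed = 3)
  expect_error(predict(ms, encode_rnn(ds, condition = "WT")), "not multi-task")
  expect_error(model_spec("cnn", multi_task = TRUE), "only defined")
})

test_that("checkpoints round-trip through per-group weight files", {
  pair <- tiny_pair()
  b <- encode_cnn(pair$target)
  ens <- ensemble_model(lapply(1:2, function(s) build_model(small_cnn_spec(), s)))
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "spec.json")))
  files <- list.files(file.path(dir, "member_01"))
  expect_setequal(tools::file_path_sans_ext(files),
                  unique(unname(ens$members[[1]]$groups)))
  back <- load_ensemble(dir)
  expect_equal(predict(back, b), predict(ens, b), tolerance = 1e-12)
})
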