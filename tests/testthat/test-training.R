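# Training behaviour at deliberately tiny scale: the learning protocols,
# early stopping, epoch determination, freeze contracts and baselines.

tiny_train_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pair <- simulate_pair(sim_config(n_source = 250L, n_target = 60L,
                                       noise_sd = 0.05, seed = 71L))
      spec <- model_spec("rnn", hyper = list(embedding_dim = 4L,
                                             recurrent_units = 8L,
                                             dense_sizes = c(8L)))
      cfg <- train_config("rnn", batch_size = 64L, learning_rate = 5e-3,
                          max_epochs = 8L, patience = 2L, ensemble_size = 2L,
                          seed = 5L, cv_folds = 3L)
      ens <- pretrain(spec, pair$source, NULL, cfg)
      cache <<- list(pair = pair, spec = spec, cfg = cfg, ens = ens)
    }
    cache
  }
})

test_that("pretraining reduces validation loss and logs per-epoch histories", {
  st <- tiny_train_setup()
  for (m in st$ens$members) {
    h <- m$history
    expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(h)))
    expect_lt(min(h$val_loss), h$val_loss[1] + 1e-12)
    expect_gte(m$best_epoch, 1L)
  }
  expect_equal(st$ens$member_count, 2L)
  # distinct seeds produce distinct members
  expect_false(identical(st$ens$members[[1]]$params, st$ens$members[[2]]$params))
})

test_that("patience 0 trains exactly one epoch", {
  st <- tiny_train_setup()
  b <- encode_rnn(st$pair$source)
  parts <- crisprtl:::carve_validation(b, frac = 0.2, seed = 1L)
  cfg0 <- st$cfg; cfg0$patience <- 0L
  m <- fit_model(build_model(st$spec, 1L), parts$train, parts$val, cfg0, seed = 2L)
  expect_equal(nrow(m$history), 1L)
  expect_equal(m$best_epoch, 1L)
})

test_that("training reproduces bit-identically under a fixed seed", {
  st <- tiny_train_setup()
  b <- encode_rnn(st$pair$target)
  run <- function() {
    m <- fit_model(build_model(st$spec, 9L), b, NULL, st$cfg, epochs = 2L, seed = 3L)
    predict(m, b)
  }
  expect_identical(run(), run())
})

test_that("freeze contract: only masked groups change during fine-tuning", {
  st <- tiny_train_setup()
  trd <- st$pair$target
  for (scheme in c("last_layer", "no_input_layer")) {
    tuned <- fine_tune(st$ens, trd, scheme = scheme, config = st$cfg, epochs = 2L)
    mask <- freeze_mask(st$spec, scheme)
    for (k in seq_along(tuned$members)) {
      before <- st$ens$members[[k]]$params
      after <- tuned$members[[k]]$params
      groups <- tuned$members[[k]]$groups
      frozen <- names(groups)[!groups %in% mask]
      trainable <- names(groups)[groups %in% mask]
      for (nm in frozen) expect_identical(after[[nm]], before[[nm]])
      expect_true(any(vapply(trainable, function(nm)
        !identical(after[[nm]], before[[nm]]), TRUE)))
    }
  }
})

test_that("zero-epoch fine-tune equals the no-TL baseline exactly", {
  st <- tiny_train_setup()
  b <- encode_rnn(st$pair$target)
  tuned0 <- fine_tune(st$ens, st$pair$target, scheme = "full", config = st$cfg,
                      epochs = 0L)
  notl <- baseline("no_tl", pretrained = st$ens)
  expect_identical(predict(tuned0, b), predict(notl, b))
  expect_identical(predict(notl, b), predict(st$ens, b))
})

test_that("gradual phase 1 matches last-layer fine-tuning under identical seeds", {
  st <- tiny_train_setup()
  trd <- st$pair$target
  cfg <- st$cfg
  # phase 1 of gradual and a last_layer run share mask, lr, data order
  m0 <- st$ens$members[[1]]
  b <- encode_rnn(trd)
  p1 <- fit_model(m0, b, NULL, cfg, trainable = freeze_mask(st$spec, "gradual_phase1"),
                  epochs = 3L, seed = 17L)
  ll <- fit_model(m0, b, NULL, cfg, trainable = freeze_mask(st$spec, "last_layer"),
                  epochs = 3L, seed = 17L)
  expect_identical(p1$params, ll$params)
  # gradual phase 2 then moves previously frozen groups at the reduced rate
  g <- fine_tune(ensemble_model(list(m0)), trd, scheme = "gradual", config = cfg,
                 epochs = 2L)
  expect_false(identical(g$members[[1]]$params$embedding, m0$params$embedding))
})

test_that("determine_epochs_cv averages fold optima with half-away rounding", {
  st <- tiny_train_setup()
  ep <- determine_epochs_cv(st$ens, st$pair$target, k = 3L, config = st$cfg,
                            scheme = "full")
  folds <- attr(ep, "fold_epochs")
  expect_length(folds, 3L)
  expect_gte(ep, min(folds))
  expect_lte(ep, max(folds))
  expect_equal(as.integer(ep),
               max(1L, as.integer(crisprtl:::round_half_away(mean(folds)))))
  # the rounding rule itself: mean of {3, 4} rounds up
  expect_equal(crisprtl:::round_half_away(mean(c(3, 4))), 4)
  expect_equal(crisprtl:::round_half_away(2.5), 3)
  expect_error(determine_epochs_cv(st$ens, st$pair$target, k = 1L,
                                   config = st$cfg), "k >= 2")
})

test_that("no_pretrain baseline trains fresh ensembles to completion", {
  st <- tiny_train_setup()
  cfg1 <- st$cfg; cfg1$ensemble_size <- 1L
  fresh <- baseline("no_pretrain", pretrained = st$ens,
                    target_train = st$pair$target, config = cfg1)
  expect_equal(fresh$member_count, 1L)
  b <- encode_rnn(st$pair$target)
  expect_true(all(is.finite(predict(fresh, b))))
  # fresh members do not inherit pre-trained weights
  expect_false(identical(fresh$members[[1]]$params, st$ens$members[[1]]$params))
})

test_that("hyper search returns the best trial and is seed-reproducible", {
  st <- tiny_train_setup()
  ds <- st$pair$source
  base_cfg <- train_config("cnn", batch_size = 64L, max_epochs = 5L,
                           patience = 2L, ensemble_size = 1L, seed = 2L)
  # a degenerate space: one sane point, one hopeless learning rate, and one
  # invalid activation whose trials fail and are recorded at -Inf
  space <- list(learning_rate = c(2e-3, 1e8),
                optimizer = c("sgd"),
                last_activation = c("linear", "not_an_activation"),
                n_trials = 8L, seed = 11L)
  res <- hyper_search(space, ds, kind = "cnn", config = base_cfg)
  expect_equal(nrow(res$trials), 8L)
  expect_equal(res$config$learning_rate, 2e-3)  # the sane point wins
  expect_equal(res$spec$hyper$last_activation, "linear")
  expect_true(any(res$trials$score == -Inf))
  res2 <- hyper_search(space, ds, kind = "cnn", config = base_cfg)
  expect_identical(res$trials, res2$trials)
  # n_trials = 1 returns that single point
  one <- hyper_search(list(learning_rate = c(1e-3), n_trials = 1L, seed = 1L),
                      ds, kind = "cnn", config = base_cfg)
  expect_equal(nrow(one$trials), 1L)
  expect_equal(one$config$learning_rate, 1e-3)
})

test_that("non-finite loss aborts a member with diagnostics", {
  st <- tiny_train_setup()
  # linear-output convolutional model + huge plain-gradient steps overflow
  b <- encode_cnn(st$pair$target)
  cfg_bad <- train_config("cnn", batch_size = 64L, learning_rate = 1e8,
                          optimizer = "sgd", max_epochs = 10L, patience = 10L)
  expect_error(fit_model(build_model(small_cnn_spec(), 1L), b, NULL, cfg_bad,
                         epochs = 10L, seed = 1L),
               "non-finite")
})
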