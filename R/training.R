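# Pre-training, fine-tuning under four layer-freezing schemes, and the two
# baseline protocols (no transfer / no pre-training).

#' Training configuration
#'
#' Defaults depend on the architecture: the convolutional model follows the
#' published recipe of its source study (Adam, learning rate 1e-4, batch size
#' 500, ensemble of 6; fine-tuning early-stops with patience 100 up to 5000
#' epochs), while the recurrent model's values are placeholders meant to be
#' replaced by [hyper_search()].
#'
#' @param kind `"rnn"` or `"cnn"`; selects the default set.
#' @param ... overrides for any field: `optimizer` ("adam" or "sgd"),
#'   `learning_rate`, `batch_size`, `max_epochs`, `patience`,
#'   `gradual_lr_factor` (learning-rate multiplier for the second phase of
#'   gradual fine-tuning), `ensemble_size`, `seed`, `cv_folds`,
#'   `ft_patience`, `ft_max_epochs` (fine-tuning early-stop settings for the
#'   cnn path).
#' @return a `train_config` list.
#' @export
train_config <- function(kind = c("rnn", "cnn"), ...) {
  kind <- match.arg(kind)
  cfg <- if (kind == "cnn") {
    list(optimizer = "adam", learning_rate = 1e-4, batch_size = 500L,
         max_epochs = 200L, patience = 20L, gradual_lr_factor = 0.1,
         ensemble_size = 6L, seed = 1L, cv_folds = 10L,
         ft_patience = 100L, ft_max_epochs = 5000L)
  } else {
    list(optimizer = "adam", learning_rate = 1e-3, batch_size = 128L,
         max_epochs = 100L, patience = 10L, gradual_lr_factor = 0.1,
         ensemble_size = 10L, seed = 1L, cv_folds = 10L,
         ft_patience = 100L, ft_max_epochs = 5000L)
  }
  over <- list(...)
  cfg <- utils::modifyList(cfg, over)
  stopifnot(cfg$learning_rate > 0, cfg$ensemble_size >= 1L,
            cfg$patience <= cfg$max_epochs)
  cfg$kind <- kind
  structure(cfg, class = "train_config")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr, trainable,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_update <- function(params, grads, lr, trainable) {
  for (nm in trainable) {
    if (is.null(grads[[nm]])) next
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  params
}

batch_loss_grads <- function(model, batch, dropout_seed = NULL, training = TRUE) {
  fw <- model_forward(model, batch, training = training, dropout_seed = dropout_seed)
  loss_id <- ad_mse(fw$tape, fw$pred, batch$y)
  pid_vec <- unlist(fw$params)
  grads_all <- ad_backward(fw$tape, loss_id, wanted = pid_vec)
  grads <- lapply(fw$params, function(id) grads_all[[id]])
  list(loss = ad_val(fw$tape, loss_id)[1L], grads = grads)
}

eval_loss <- function(model, batch) {
  p <- predict(model, batch)
  mean((p - batch$y)^2)
}

#' Train a single model
#'
#' Minibatch optimization with per-epoch reshuffling. When `epochs` is NULL,
#' training early-stops on the validation batch: the run halts once
#' `patience` epochs have passed without a new best validation loss (patience
#' 0 therefore trains exactly one epoch), and the best-epoch weights are
#' restored. When `epochs` is given, training runs exactly that many epochs
#' with no validation (0 epochs returns the model untouched). Members of an
#' ensemble are trained by independent calls with their own seeds.
#'
#' @param model a `crisprtl_model`.
#' @param train_batch,val_batch `encoded_batch`es; `val_batch` may be NULL in
#'   fixed-epoch mode.
#' @param config a `train_config`.
#' @param trainable character vector of trainable group tags
#'   (see [freeze_mask()]); parameters in other groups are never touched.
#' @param epochs fixed epoch count, or NULL for early stopping.
#' @param seed seed for shuffling and dropout; defaults to `config$seed`.
#' @return the trained model, with a `history` field: data frame of per-epoch
#'   train/validation losses, and `best_epoch`.
#' @export
fit_model <- function(model, train_batch, val_batch = NULL, config,
                      trainable = PARAM_GROUPS, epochs = NULL, seed = NULL) {
  seed <- seed %||% config$seed
  trainable_params <- names(model$groups)[model$groups %in% trainable]
  state <- adam_state(model$params)
  n <- train_batch$n
  bs <- min(config$batch_size, n)
  early <- is.null(epochs)
  if (early && is.null(val_batch)) stopf("early stopping requires a validation batch")
  max_ep <- if (early) config$max_epochs else epochs
  best_loss <- Inf; best_epoch <- 0L; best_params <- model$params
  hist <- list()
  if (max_ep >= 1L) for (ep in seq_len(max_ep)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(n))
    ep_losses <- numeric(0)
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      mb <- batch_subset(train_batch, idx)
      lg <- batch_loss_grads(model, mb, dropout_seed = derive_seed(seed, ep, start))
      if (!is.finite(lg$loss))
        stopf("non-finite training loss at epoch %d (member seed %d)", ep, seed)
      if (identical(config$optimizer, "sgd")) {
        model$params <- sgd_update(model$params, lg$grads, config$learning_rate, trainable_params)
      } else {
        upd <- adam_update(model$params, lg$grads, state, config$learning_rate, trainable_params)
        model$params <- upd$params; state <- upd$state
      }
      ep_losses <- c(ep_losses, lg$loss)
    }
    vl <- if (!is.null(val_batch)) eval_loss(model, val_batch) else NA_real_
    hist[[ep]] <- c(epoch = ep, train_loss = mean(ep_losses), val_loss = vl)
    if (early) {
      if (vl < best_loss) { best_loss <- vl; best_epoch <- ep; best_params <- model$params }
      if (ep - best_epoch >= config$patience) break
    }
  }
  if (early) {
    model$params <- best_params
    model$best_epoch <- best_epoch
  } else {
    model$best_epoch <- max_ep
  }
  model$history <- as.data.frame(do.call(rbind, hist))
  model
}

# carve a validation subset out of a training batch; cluster-aware when
# guides are provided
carve_validation <- function(batch, frac = 0.1, seed = 1L, cluster_aware = FALSE,
                             link_threshold = 5L) {
  n <- batch$n
  if (cluster_aware) {
    seqs <- if (!is.null(batch$tokens)) paste0(decode_rnn(batch$tokens), "GG")
            else decode_onehot30(batch$onehot)
    tmp_ids <- as.character(seq_len(n))
    clusters <- local({
      pairs <- find_similar_pairs(seqs, as.integer(link_threshold) - 1L)
      parent <- seq_len(n)
      find_root <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
      if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
        ri <- find_root(pairs[k, 1L]); rj <- find_root(pairs[k, 2L])
        if (ri != rj) parent[rj] <- ri
      }
      split(seq_len(n), vapply(seq_len(n), find_root, 0L))
    })
    clusters <- with_seed(seed, sample(clusters))
    target_val <- frac * n
    val_idx <- integer(0)
    for (cl in clusters) {
      if (length(val_idx) >= target_val) break
      val_idx <- c(val_idx, cl)
    }
  } else {
    val_idx <- with_seed(seed, sample.int(n, max(1L, round(frac * n))))
  }
  list(train = batch_subset(batch, setdiff(seq_len(n), val_idx)),
       val = batch_subset(batch, val_idx))
}

encode_for_model <- function(ds, spec, condition = NULL) {
  if (spec$kind == "cnn") encode_cnn(ds, condition = condition)
  else if (isTRUE(spec$multi_task)) encode_rnn_multitask(ds)
  else encode_rnn(ds, condition = condition)
}

#' Pre-train an ensemble on a source dataset
#'
#' Trains `config$ensemble_size` identically specified models from different
#' random initializations on the train side of `plan` (multi-task rnn models
#' flatten records into one sample per observed (guide, enzyme) pair). Each
#' member carves a random 10% validation subset out of its training data and
#' early-stops on it.
#'
#' @param spec a `model_spec`.
#' @param ds a `guide_dataset` with whatever the spec needs attached
#'   (bio-features for rnn; context + energy for cnn).
#' @param plan a `split_plan` covering `ds` (its test side is never touched),
#'   or NULL to train on the whole dataset.
#' @param config a `train_config`.
#' @param condition condition label for single-task models.
#' @return a `crisprtl_ensemble`; per-member training histories are kept on
#'   the members.
#' @export
pretrain <- function(spec, ds, plan = NULL, config, condition = NULL) {
  train_ds <- if (is.null(plan)) ds else subset_dataset(ds, plan$train_ids)
  full <- encode_for_model(train_ds, spec, condition = condition)
  members <- vector("list", config$ensemble_size)
  failed <- 0L
  for (m in seq_len(config$ensemble_size)) {
    mseed <- derive_seed(config$seed, m)
    parts <- carve_validation(full, frac = 0.1, seed = mseed)
    model <- build_model(spec, seed = mseed)
    members[[m]] <- tryCatch(
      fit_model(model, parts$train, parts$val, config, seed = mseed),
      error = function(e) { warnf("ensemble member %d failed: %s", m, conditionMessage(e)); NULL })
    if (is.null(members[[m]])) failed <- failed + 1L
  }
  members <- Filter(Negate(is.null), members)
  if (!length(members)) stopf("all %d ensemble members failed to train", config$ensemble_size)
  ensemble_model(members)
}

#' Random hyper-parameter search
#'
#' Samples `n_trials` points from the space, trains each briefly with a
#' random 10% validation carve-out, and returns the point with the best
#' validation Spearman correlation. Failed trials score `-Inf` and are kept
#' in the trial table.
#'
#' @param space named list of samplers; each element is a function(void) or a
#'   vector/list to sample from uniformly. Recognized names are any
#'   `model_spec` hyper field plus `learning_rate`, `batch_size`,
#'   `optimizer`. Also `n_trials` (integer) and `seed`.
#' @param ds training `guide_dataset`.
#' @param kind architecture kind.
#' @param config base `train_config`; sampled fields override it.
#' @param condition,multi_task forwarded to the encoders/spec.
#' @return list with `spec`, `config`, `trials` (data frame with one row per
#'   trial: sampled values + validation Spearman).
#' @export
hyper_search <- function(space, ds, kind = "rnn", config = NULL,
                         condition = NULL, multi_task = FALSE) {
  n_trials <- space$n_trials %||% 10L
  seed <- space$seed %||% 1L
  config <- config %||% train_config(kind)
  samplers <- space[setdiff(names(space), c("n_trials", "seed"))]
  draw <- function(s, trial_seed) {
    if (is.function(s)) with_seed(trial_seed, s())
    else with_seed(trial_seed, s[[sample.int(length(s), 1L)]])
  }
  spec_fields <- c("embedding_dim", "recurrent_units", "dense_sizes", "dropout",
                   "last_activation", "init", "conv_widths", "conv_filters",
                   "pool", "branch_dense")
  rows <- list(); best_score <- -Inf; best <- NULL
  for (tr in seq_len(n_trials)) {
    vals <- lapply(seq_along(samplers), function(k)
      draw(samplers[[k]], derive_seed(seed, tr, k)))
    names(vals) <- names(samplers)
    hy <- vals[names(vals) %in% spec_fields]
    cfg_over <- vals[names(vals) %in% c("learning_rate", "batch_size", "optimizer")]
    score <- tryCatch({
      spec_t <- model_spec(kind, multi_task = multi_task, hyper = hy)
      cfg_t <- do.call(train_config, c(list(kind = kind), as.list(config)[
        setdiff(names(unclass(config)), c("kind"))], cfg_over))
      batch <- encode_for_model(ds, spec_t, condition = condition)
      parts <- carve_validation(batch, frac = 0.1, seed = derive_seed(seed, tr))
      model <- build_model(spec_t, seed = derive_seed(seed, tr, 999L))
      model <- fit_model(model, parts$train, parts$val, cfg_t,
                         seed = derive_seed(seed, tr, 7L))
      spearman_cor(predict(model, parts$val), parts$val$y)
    }, error = function(e) -Inf)
    if (is.na(score)) score <- -Inf
    rows[[tr]] <- data.frame(trial = tr,
                             t(vapply(vals, function(v) paste(format(v), collapse = "/"), "")),
                             score = score, check.names = FALSE)
    if (score > best_score) {
      best_score <- score
      best <- list(hy = hy, cfg_over = cfg_over)
    }
  }
  trials <- do.call(rbind, rows)
  if (is.null(best)) stopf("all hyper-search trials failed")
  list(spec = model_spec(kind, multi_task = multi_task, hyper = best$hy),
       config = do.call(train_config, c(list(kind = kind), best$cfg_over)),
       trials = trials)
}

#' Determine the fine-tuning epoch budget by cross-validation
#'
#' Cluster-aware k-fold cross-validation over the target training set: each
#' fold fine-tunes a copy of the first ensemble member with early stopping
#' (validating on the held-out fold) and records the best epoch; the returned
#' budget is the mean best epoch rounded half away from zero, at least 1.
#'
#' @param pretrained a `crisprtl_ensemble` (its first member is used per fold).
#' @param train_ds target training `guide_dataset`.
#' @param k number of folds.
#' @param config a `train_config`.
#' @param scheme fine-tuning scheme whose freeze mask applies during the CV.
#' @param condition condition label for single-task encoding.
#' @param link_threshold Hamming link threshold for fold construction.
#' @return integer epoch budget; fold optima attached as attribute `"fold_epochs"`.
#' @export
determine_epochs_cv <- function(pretrained, train_ds, k = 10L, config,
                                scheme = "full", condition = NULL,
                                link_threshold = 5L) {
  stopifnot(k >= 2L)
  clusters <- cluster_guides(train_ds, link_threshold)
  folds <- clusters_to_folds(clusters, k, seed = config$seed)
  sizes <- lengths(folds)
  if (any(sizes == 0L))
    stopf("fold too small to split: fold sizes %s", paste(sizes, collapse = ","))
  trainable <- freeze_mask(pretrained$spec, if (scheme == "gradual") "gradual_phase1" else scheme)
  spec <- pretrained$spec
  best_epochs <- integer(k)
  for (f in seq_len(k)) {
    val_ids <- folds[[f]]
    tr_ids <- unlist(folds[-f])
    tb <- encode_for_model(subset_dataset(train_ds, tr_ids), spec, condition = condition)
    vb <- encode_for_model(subset_dataset(train_ds, val_ids), spec, condition = condition)
    m <- fit_model(pretrained$members[[1L]], tb, vb, config, trainable = trainable,
                   seed = derive_seed(config$seed, 1000L + f))
    best_epochs[f] <- max(1L, m$best_epoch)
  }
  out <- max(1L, as.integer(round_half_away(mean(best_epochs))))
  attr(out, "fold_epochs") <- best_epochs
  out
}

#' Fine-tune a pre-trained ensemble on a target dataset
#'
#' Each member is fine-tuned independently under the scheme's freeze mask:
#' \describe{
#'   \item{full}{all weights trainable.}
#'   \item{last_layer}{only the final hidden layer and the output layer.}
#'   \item{no_input_layer}{all weights except the input embedding (rnn) or
#'     convolution branches (cnn).}
#'   \item{gradual}{phase 1 trains the last layer at the configured learning
#'     rate, then phase 2 trains all weights at
#'     `learning_rate * gradual_lr_factor`.}
#' }
#' The rnn path trains for a fixed epoch budget from [determine_epochs_cv()]
#' (computed here when `epochs` is NULL) with no further early stopping; the
#' cnn path early-stops on a cluster-aware validation carve-out with
#' `ft_patience` / `ft_max_epochs`. `epochs = 0` returns predictions
#' identical to the pre-trained ensemble.
#'
#' @param pretrained a `crisprtl_ensemble`.
#' @param target_train target training `guide_dataset`.
#' @param scheme `"full"`, `"last_layer"`, `"gradual"`, or `"no_input_layer"`.
#' @param config a `train_config`.
#' @param epochs fixed epoch budget (rnn path); NULL to determine by CV.
#' @param condition condition label for single-task encoding.
#' @return the fine-tuned `crisprtl_ensemble`.
#' @export
fine_tune <- function(pretrained, target_train, scheme = c("full", "last_layer",
                                                           "gradual", "no_input_layer"),
                      config, epochs = NULL, condition = NULL) {
  scheme <- match.arg(scheme)
  spec <- pretrained$spec
  if (scheme == "no_input_layer" && !"input_embedding_or_conv" %in% unique(pretrained$members[[1L]]$groups))
    stopf("scheme 'no_input_layer' requires an input embedding/convolution group")
  full_batch <- encode_for_model(target_train, spec, condition = condition)

  is_rnn <- spec$kind == "rnn"
  if (is_rnn && is.null(epochs)) {
    epochs <- determine_epochs_cv(pretrained, target_train, k = config$cv_folds,
                                  config = config,
                                  scheme = scheme, condition = condition)
  }
  tune_member <- function(model, mseed, trainable, lr_factor = 1, ep = epochs) {
    cfg <- config
    cfg$learning_rate <- cfg$learning_rate * lr_factor
    if (is_rnn) {
      fit_model(model, full_batch, NULL, cfg, trainable = trainable,
                epochs = ep, seed = mseed)
    } else {
      if (!is.null(ep)) return(fit_model(model, full_batch, NULL, cfg,
                                         trainable = trainable, epochs = ep, seed = mseed))
      cfg$patience <- cfg$ft_patience; cfg$max_epochs <- cfg$ft_max_epochs
      parts <- carve_validation(full_batch, frac = 0.1, seed = mseed,
                                cluster_aware = TRUE, link_threshold = 5L)
      fit_model(model, parts$train, parts$val, cfg, trainable = trainable, seed = mseed)
    }
  }
  members <- lapply(seq_along(pretrained$members), function(m) {
    mseed <- derive_seed(config$seed, 500L + m)
    model <- pretrained$members[[m]]
    if (scheme == "gradual") {
      model <- tune_member(model, mseed, freeze_mask(spec, "gradual_phase1"), 1)
      tune_member(model, derive_seed(mseed, 2L), freeze_mask(spec, "gradual_phase2"),
                  config$gradual_lr_factor)
    } else {
      tune_member(model, mseed, freeze_mask(spec, scheme), 1)
    }
  })
  ensemble_model(members)
}

#' Baseline models for transfer-learning comparisons
#'
#' `no_tl` returns the pre-trained ensemble untouched (predictions on the
#' target come straight from the source-trained model); `no_pretrain` trains
#' fresh, randomly initialized ensembles on the target training data only.
#'
#' @param kind `"no_tl"` or `"no_pretrain"`.
#' @param pretrained the pre-trained `crisprtl_ensemble` (used by `no_tl`,
#'   and for its spec by `no_pretrain`).
#' @param target_train target training `guide_dataset` (`no_pretrain`).
#' @param config a `train_config` (`no_pretrain`).
#' @param condition condition label for single-task encoding.
#' @return a `crisprtl_ensemble`.
#' @export
baseline <- function(kind = c("no_tl", "no_pretrain"), pretrained = NULL,
                     target_train = NULL, config = NULL, condition = NULL) {
  kind <- match.arg(kind)
  if (kind == "no_tl") {
    if (is.null(pretrained)) stopf("no_tl baseline needs the pretrained ensemble")
    return(pretrained)
  }
  stopifnot(!is.null(pretrained), !is.null(target_train), !is.null(config))
  pretrain(pretrained$spec, target_train, plan = NULL, config = config,
           condition = condition)
}
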