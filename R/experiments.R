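# Desk-scale experiment protocols over the synthetic simulator: the
# transfer-learning benefit study and the planted-signal saliency recovery
# study. These functions are what the acceptance script and the package's
# own protocol tests run; the vignette documents the problem sizes.

#' Desk-scale transfer-learning benefit study
#'
#' Pre-trains a small recurrent ensemble on a simulated high-throughput
#' source dataset, then, over several independent cluster-aware 80/20 target
#' splits, compares held-out Spearman correlation of (a) full fine-tuning of
#' the pre-trained ensemble, (b) the untouched pre-trained ensemble (no
#' transfer), and (c) fresh ensembles trained on the target alone (no
#' pre-training). With correlated source and target effects, transfer should
#' win; with uncorrelated effects (`rho = 0`) its advantage over
#' target-only training should vanish.
#'
#' @param rho source-target effect correlation for the simulated pair.
#' @param n_seeds number of independent target splits.
#' @param sim_seed simulator seed (source and planted effects derive from it).
#' @param spec model spec; defaults to the desk-scale recurrent spec
#'   (embedding 8, recurrent units 16, one dense layer of 16).
#' @param pre_config,ft_config training configurations for the pre-training
#'   and fine-tuning stages; desk-scale defaults are used when NULL.
#' @param pretrained optionally, a pre-trained ensemble to reuse (it must
#'   come from the same source; used to share one pre-training run across
#'   `rho` arms, which plant the same source effects under one `sim_seed`).
#' @param scheme fine-tuning scheme for the transfer arm.
#' @return list with `scores` (data frame: seed, method, spearman),
#'   `pretrained` (the ensemble, for reuse), and `pair`.
#' @export
#' @param share_epoch_budget determine the fine-tuning epoch budget by
#'   cross-validation once (on the first split) and reuse it across splits;
#'   the desk-scale default. Set FALSE to re-run the epoch CV per split.
#' @param source_test_fraction when > 0 (and no `pretrained` is supplied),
#'   hold out this cluster-aware fraction of the source during pre-training
#'   and report the ensemble's held-out source Spearman as `source_heldout`.
tl_benefit_experiment <- function(rho = 0.6, n_seeds = 5L, sim_seed = 1L,
                                  spec = NULL, pre_config = NULL,
                                  ft_config = NULL, pretrained = NULL,
                                  scheme = "full", share_epoch_budget = TRUE,
                                  source_test_fraction = 0) {
  spec <- spec %||% model_spec("rnn", hyper = list(embedding_dim = 8L,
                                                   recurrent_units = 16L,
                                                   dense_sizes = c(16L)))
  pre_config <- pre_config %||% train_config("rnn", batch_size = 500L,
                                             learning_rate = 5e-3,
                                             max_epochs = 25L, patience = 4L,
                                             ensemble_size = 3L,
                                             seed = derive_seed(sim_seed, 77L))
  ft_config <- ft_config %||% train_config("rnn", batch_size = 128L,
                                           learning_rate = 2e-3,
                                           max_epochs = 20L, patience = 4L,
                                           ensemble_size = pre_config$ensemble_size,
                                           cv_folds = 5L,
                                           seed = derive_seed(sim_seed, 78L))
  pair <- simulate_pair(sim_config(rho = rho, seed = sim_seed))
  source_heldout <- NA_real_
  if (is.null(pretrained)) {
    plan <- NULL
    if (source_test_fraction > 0) {
      plan <- split_dataset(pair$source, source_test_fraction, link_threshold = 5L)
    }
    pretrained <- pretrain(spec, pair$source, plan, pre_config)
    if (!is.null(plan)) {
      sb <- encode_rnn(subset_dataset(pair$source, plan$test_ids))
      source_heldout <- spearman_cor(predict(pretrained, sb), sb$y)
    }
  }
  rows <- list()
  shared_epochs <- NULL
  for (s in seq_len(n_seeds)) {
    plan <- split_dataset(pair$target, 0.2, link_threshold = 5L,
                          ordering = "random", seed = derive_seed(sim_seed, 30L, s))
    trd <- subset_dataset(pair$target, plan$train_ids)
    ted <- subset_dataset(pair$target, plan$test_ids)
    tb <- encode_rnn(ted)
    cfg_s <- ft_config; cfg_s$seed <- derive_seed(ft_config$seed, s)
    ep <- NULL
    if (share_epoch_budget) {
      if (is.null(shared_epochs))
        shared_epochs <- determine_epochs_cv(pretrained, trd, k = ft_config$cv_folds,
                                             config = cfg_s, scheme = scheme)
      ep <- as.integer(shared_epochs)
    }
    tuned <- fine_tune(pretrained, trd, scheme = scheme, config = cfg_s, epochs = ep)
    fresh <- baseline("no_pretrain", pretrained = pretrained, target_train = trd,
                      config = cfg_s)
    sc <- c(full_tl = spearman_cor(predict(tuned, tb), tb$y),
            no_tl = spearman_cor(predict(pretrained, tb), tb$y),
            no_pretrain = spearman_cor(predict(fresh, tb), tb$y))
    rows[[s]] <- data.frame(seed = s, method = names(sc), spearman = unname(sc))
  }
  list(scores = do.call(rbind, rows), pretrained = pretrained, pair = pair,
       source_heldout = source_heldout)
}

#' Effective planted per-letter effects of a simulated dataset
#'
#' The marginal effect of placing letter l at position p in the simulator is
#' the planted weight plus the GC-content contribution (gc_effect / 20 for G
#' or C within the protospacer). Rows are centered, matching the
#' identifiability of attribution up to per-position constants.
#'
#' @param w planted 30 x 4 weight matrix.
#' @param config the `sim_config` used.
#' @return 30 x 4 matrix of centered effective letter effects.
#' @export
effective_effects <- function(w, config) {
  weff <- w
  weff[5:24, c(2L, 3L)] <- weff[5:24, c(2L, 3L)] + config$gc_effect / 20
  weff - rowMeans(weff)
}

#' Planted-signal saliency recovery study
#'
#' Trains the convolutional model on a simulated source dataset and asks
#' whether the gradient-saliency attribution ranks the largest planted
#' (effective, position-centered) position-letter effect among its top
#' `top_k` attributions by absolute value, repeated over independent
#' simulator seeds.
#'
#' @param n_seeds number of independent simulations.
#' @param top_k rank cutoff counted as a recovery.
#' @param base_seed seed from which per-run seeds are derived.
#' @param n_source simulated dataset size.
#' @param noise_sd observation noise for the recovery study.
#' @return list with `ranks` (integer vector, rank of the largest planted
#'   effect per seed), `hits` (count of ranks <= top_k), `n_seeds`.
#' @export
saliency_recovery_experiment <- function(n_seeds = 5L, top_k = 3L, base_seed = 1L,
                                         n_source = 2000L, noise_sd = 0.05) {
  spec <- model_spec("cnn", hyper = list(conv_filters = c(16L, 16L, 16L),
                                         branch_dense = 32L, dense_sizes = c(24L),
                                         pool = "avg"))
  ranks <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    seed_s <- derive_seed(base_seed, 600L, s)
    cfgs <- sim_config(n_source = n_source, n_target = 50L,
                       noise_sd = noise_sd, seed = seed_s)
    pair <- simulate_pair(cfgs)
    cfg <- train_config("cnn", batch_size = 500L, learning_rate = 2e-3,
                        max_epochs = 100L, patience = 10L, ensemble_size = 2L,
                        seed = seed_s)
    ens <- pretrain(spec, pair$source, NULL, cfg)
    batch <- encode_cnn(pair$source)
    I <- saliency(ens, batch)$I
    weff <- effective_effects(pair$w_source, cfgs)
    rownames(weff) <- as.character(0:29)
    weff <- weff[rownames(I), ]
    Ic <- I - rowMeans(I)
    target_cell <- which(abs(weff) == max(abs(weff)))[1L]
    ranks[s] <- which(order(-abs(Ic)) == target_cell)
  }
  list(ranks = ranks, hits = sum(ranks <= top_k), n_seeds = n_seeds)
}
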