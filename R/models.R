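# Model architectures as computation-graph contracts.
#
# Two kinds:
#  rnn  token embedding -> bidirectional LSTM (full output sequence,
#       flattened) -> concat(bio-features [, enzyme indicator]) -> dense
#       cascade -> scalar efficiency.
#  cnn  30x4 one-hot -> three parallel 1-D convolution branches of distinct
#       widths -> max pool + flatten + concat -> dense -> concat(energy
#       score) -> dense cascade -> scalar efficiency.
#
# Every trainable parameter carries exactly one group tag from
# {input_embedding_or_conv, sequence_encoder, dense_hidden, last_hidden,
# output}; transfer-learning freeze masks are defined over these tags.

PARAM_GROUPS <- c("input_embedding_or_conv", "sequence_encoder",
                  "dense_hidden", "last_hidden", "output")

#' Describe a model architecture
#'
#' @param kind `"rnn"` (guide-sequence bidirectional LSTM with bio-features)
#'   or `"cnn"` (30-nt context convolutional model with an energy side input).
#' @param multi_task for the rnn: add a 3-long one-hot enzyme indicator input
#'   so a single shared output head serves all enzyme variants.
#' @param hyper named list of hyper-parameters overriding the defaults.
#'   rnn: `embedding_dim` (44), `recurrent_units` (128), `dense_sizes`
#'   (c(128, 64)), `dropout` (c(embedding=0, recurrent=0, dense=0)),
#'   `last_activation` ("sigmoid"), `init` ("glorot_uniform").
#'   cnn: `conv_widths` (c(3,5,7)), `conv_filters` (c(100,100,100)),
#'   `pool` ("max"), `branch_dense` (80), `dense_sizes` (c(80, 60)),
#'   `last_activation` ("linear"), `init` ("glorot_uniform").
#' @return a `model_spec` object.
#' @export
model_spec <- function(kind = c("rnn", "cnn"), multi_task = FALSE, hyper = list()) {
  kind <- match.arg(kind)
  defaults <- if (kind == "rnn") {
    list(embedding_dim = 44L, recurrent_units = 128L, dense_sizes = c(128L, 64L),
         dropout = c(embedding = 0, recurrent = 0, dense = 0),
         last_activation = "sigmoid", init = "glorot_uniform")
  } else {
    list(conv_widths = c(3L, 5L, 7L), conv_filters = c(100L, 100L, 100L),
         pool = "max", pool_size = 2L, branch_dense = 80L, dense_sizes = c(80L, 60L),
         last_activation = "linear", init = "glorot_uniform")
  }
  if (isTRUE(multi_task) && kind != "rnn")
    stopf("multi_task is only defined for the rnn architecture")
  hy <- utils::modifyList(defaults, hyper)
  if (kind == "rnn") {
    # canonicalize dropout to a named length-3 vector (serialization through
    # JSON may strip names)
    dr <- unlist(hy$dropout)
    if (is.null(names(dr)) || !any(nzchar(names(dr))))
      names(dr) <- c("embedding", "recurrent", "dense")[seq_along(dr)]
    full <- c(embedding = 0, recurrent = 0, dense = 0)
    full[names(dr)] <- dr
    hy$dropout <- full
  }
  structure(list(kind = kind, multi_task = multi_task, hyper = hy),
            class = "model_spec")
}

init_matrix <- function(nr, nc, scheme, fan_in = nr, fan_out = nc) {
  switch(scheme,
         glorot_uniform = {
           lim <- sqrt(6 / (fan_in + fan_out))
           matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
         },
         he_normal = matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc),
         normal = matrix(stats::rnorm(nr * nc, 0, 0.05), nr, nc),
         stopf("unknown init scheme '%s'", scheme))
}

dense_group_tags <- function(n_dense) {
  # cascade of n_dense hidden layers: all but the final one are dense_hidden,
  # the final hidden layer before the output unit is last_hidden
  if (n_dense == 0L) character(0)
  else c(rep("dense_hidden", n_dense - 1L), "last_hidden")
}

#' Build a model with randomly initialized parameters
#'
#' Two builds with the same spec and seed are bit-identical. Every parameter
#' is assigned exactly one freeze-group tag.
#'
#' @param spec a `model_spec`.
#' @param seed integer seed controlling initialization.
#' @return a `crisprtl_model`: list with `spec`, `params` (named list of
#'   matrices), `groups` (named character: parameter -> group tag), `seed`.
#' @export
build_model <- function(spec, seed) {
  seed <- as.integer(seed)
  hy <- spec$hyper
  params <- list(); groups <- character(0)
  add <- function(name, m, tag) {
    params[[name]] <<- m
    groups[name] <<- tag
  }
  with_seed(seed, {
    if (spec$kind == "rnn") {
      d <- hy$embedding_dim; h <- hy$recurrent_units
      add("embedding", init_matrix(5L, d, hy$init), "input_embedding_or_conv")
      for (dir in c("fwd", "bwd")) {
        add(paste0("lstm_W_", dir), init_matrix(d, 4L * h, hy$init), "sequence_encoder")
        add(paste0("lstm_U_", dir), init_matrix(h, 4L * h, hy$init, fan_in = h), "sequence_encoder")
        b <- matrix(0, 1L, 4L * h)
        b[1L, (h + 1L):(2L * h)] <- 1  # forget-gate bias
        add(paste0("lstm_b_", dir), b, "sequence_encoder")
      }
      in_dim <- 22L * 2L * h + 11L + if (spec$multi_task) 3L else 0L
      tags <- dense_group_tags(length(hy$dense_sizes))
      for (k in seq_along(hy$dense_sizes)) {
        out_dim <- hy$dense_sizes[k]
        add(paste0("dense", k, "_W"), init_matrix(in_dim, out_dim, hy$init), tags[k])
        add(paste0("dense", k, "_b"), matrix(0, 1L, out_dim), tags[k])
        in_dim <- out_dim
      }
      add("out_W", init_matrix(in_dim, 1L, hy$init), "output")
      add("out_b", matrix(0, 1L, 1L), "output")
    } else {
      nb <- length(hy$conv_widths)
      for (k in seq_len(nb)) {
        w <- hy$conv_widths[k]; f <- hy$conv_filters[k]
        add(paste0("conv", k, "_W"), init_matrix(4L * w, f, hy$init), "input_embedding_or_conv")
        add(paste0("conv", k, "_b"), matrix(0, 1L, f), "input_embedding_or_conv")
      }
      pool_out <- sum(ceiling((30L - hy$conv_widths + 1L) / hy$pool_size) * hy$conv_filters)
      add("branch_W", init_matrix(pool_out, hy$branch_dense, hy$init),
          "sequence_encoder")
      add("branch_b", matrix(0, 1L, hy$branch_dense), "sequence_encoder")
      in_dim <- hy$branch_dense + 1L  # + energy score
      tags <- dense_group_tags(length(hy$dense_sizes))
      for (k in seq_along(hy$dense_sizes)) {
        out_dim <- hy$dense_sizes[k]
        add(paste0("dense", k, "_W"), init_matrix(in_dim, out_dim, hy$init), tags[k])
        add(paste0("dense", k, "_b"), matrix(0, 1L, out_dim), tags[k])
        in_dim <- out_dim
      }
      add("out_W", init_matrix(in_dim, 1L, hy$init), "output")
      add("out_b", matrix(0, 1L, 1L), "output")
    }
  })
  structure(list(spec = spec, params = params, groups = groups, seed = seed),
            class = "crisprtl_model")
}

#' Total trainable parameter count
#' @param model a `crisprtl_model`.
#' @return integer.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 0L))

#' @export
print.crisprtl_model <- function(x, ...) {
  cat(sprintf("<crisprtl_model %s%s>: %d parameters in %d tensors\n",
              x$spec$kind, if (isTRUE(x$spec$multi_task)) " multi-task" else "",
              n_params(x), length(x$params)))
  invisible(x)
}

activation_node <- function(tape, id, act) {
  switch(act,
         sigmoid = ad_sigmoid(tape, id),
         relu = ad_relu(tape, id),
         tanh = ad_tanh(tape, id),
         linear = id,
         stopf("unknown activation '%s'", act))
}

# one LSTM direction over a list of per-timestep input node ids; returns the
# list of hidden-state nodes (each B x h), one per timestep
lstm_direction <- function(tape, x_ids, W, U, b, h) {
  B <- nrow(ad_val(tape, x_ids[[1L]]))
  h_prev <- ad_leaf(tape, matrix(0, B, h))
  c_prev <- ad_leaf(tape, matrix(0, B, h))
  hs <- vector("list", length(x_ids))
  for (t in seq_along(x_ids)) {
    x <- x_ids[[t]]
    z <- ad_add_bias(tape, ad_add(tape, ad_mm(tape, x, W), ad_mm(tape, h_prev, U)), b)
    i_g <- ad_sigmoid(tape, ad_slice_cols(tape, z, 1:h))
    f_g <- ad_sigmoid(tape, ad_slice_cols(tape, z, (h + 1L):(2L * h)))
    g_g <- ad_tanh(tape, ad_slice_cols(tape, z, (2L * h + 1L):(3L * h)))
    o_g <- ad_sigmoid(tape, ad_slice_cols(tape, z, (3L * h + 1L):(4L * h)))
    c_prev <- ad_add(tape, ad_mul(tape, f_g, c_prev), ad_mul(tape, i_g, g_g))
    h_prev <- ad_mul(tape, o_g, ad_tanh(tape, c_prev))
    hs[[t]] <- h_prev
  }
  hs
}

dense_cascade <- function(tape, x, params_ids, spec) {
  hy <- spec$hyper
  for (k in seq_along(hy$dense_sizes)) {
    x <- ad_relu(tape, ad_add_bias(tape, ad_mm(tape, x, params_ids[[paste0("dense", k, "_W")]]),
                                   params_ids[[paste0("dense", k, "_b")]]))
  }
  out <- ad_add_bias(tape, ad_mm(tape, x, params_ids[["out_W"]]), params_ids[["out_b"]])
  activation_node(tape, out, hy$last_activation)
}

# Build the forward graph for one batch. Returns tape, prediction node, the
# input leaf ids (for saliency), and the parameter leaf ids (for training).
model_forward <- function(model, batch, training = FALSE, dropout_seed = NULL) {
  spec <- model$spec
  hy <- spec$hyper
  if (!identical(spec$kind, batch$kind))
    stopf("batch encoding '%s' does not match model kind '%s'", batch$kind, spec$kind)
  tape <- ad_tape()
  pids <- lapply(model$params, function(p) ad_leaf(tape, p))

  drop_mask <- function(dim_r, dim_c, rate, k) {
    if (!training || is.null(dropout_seed) || rate <= 0) return(NULL)
    with_seed(derive_seed(dropout_seed, k),
              matrix(stats::rbinom(dim_r * dim_c, 1L, 1 - rate) / (1 - rate), dim_r, dim_c))
  }

  if (spec$kind == "rnn") {
    B <- batch$n
    # single one-hot input leaf (B x 110): 22 positions x 5-letter alphabet
    X <- matrix(0, B, 22L * 5L)
    for (t in 1:22) X[cbind(seq_len(B), (t - 1L) * 5L + batch$tokens[, t])] <- 1
    x_id <- ad_leaf(tape, X)
    dr <- hy$dropout
    emb_all <- vector("list", 22L)
    for (t in 1:22) {
      xt <- ad_slice_cols(tape, x_id, ((t - 1L) * 5L + 1L):(t * 5L))
      emb <- ad_mm(tape, xt, pids$embedding)
      m <- drop_mask(B, hy$embedding_dim, dr[["embedding"]] %||% 0, t)
      if (!is.null(m)) emb <- ad_mul_const(tape, emb, m)
      emb_all[[t]] <- emb
    }
    h <- hy$recurrent_units
    # full output sequence of both directions, flattened (the bwd sequence is
    # re-reversed so timesteps align)
    h_fwd <- lstm_direction(tape, emb_all, pids$lstm_W_fwd, pids$lstm_U_fwd, pids$lstm_b_fwd, h)
    h_bwd <- rev(lstm_direction(tape, rev(emb_all), pids$lstm_W_bwd, pids$lstm_U_bwd, pids$lstm_b_bwd, h))
    enc <- ad_cbindn(tape, c(unlist(h_fwd), unlist(h_bwd)))
    m <- drop_mask(B, 22L * 2L * h, hy$dropout[["recurrent"]] %||% 0, 100L)
    if (!is.null(m)) enc <- ad_mul_const(tape, enc, m)
    bio_id <- ad_leaf(tape, batch$biofeat)
    z <- ad_cbind(tape, enc, bio_id)
    enz_id <- NULL
    if (isTRUE(spec$multi_task)) {
      if (is.null(batch$enzyme)) stopf("multi-task model requires an enzyme indicator in the batch")
      enz_id <- ad_leaf(tape, batch$enzyme)
      z <- ad_cbind(tape, z, enz_id)
    } else if (!is.null(batch$enzyme)) {
      stopf("batch carries an enzyme indicator but the model is not multi-task")
    }
    pred <- dense_cascade(tape, z, pids, spec)
    list(tape = tape, pred = pred, x = x_id, bio = bio_id, enzyme = enz_id,
         params = pids)
  } else {
    B <- batch$n
    x_id <- ad_leaf(tape, batch$onehot)
    # per branch: 1-D convolution over positions, windowed pooling
    # (non-overlapping windows of pool_size), flatten, concat branches
    pooled_all <- list()
    for (k in seq_along(hy$conv_widths)) {
      w <- hy$conv_widths[k]
      Wk <- pids[[paste0("conv", k, "_W")]]; bk <- pids[[paste0("conv", k, "_b")]]
      P <- 30L - w + 1L
      pos_nodes <- vector("list", P)
      for (p in seq_len(P)) {
        cols <- ((p - 1L) * 4L + 1L):((p + w - 1L) * 4L)
        pos_nodes[[p]] <- ad_relu(tape, ad_add_bias(tape, ad_mm(tape, ad_slice_cols(tape, x_id, cols), Wk), bk))
      }
      ps <- hy$pool_size
      for (j in seq_len(ceiling(P / ps))) {
        win <- unlist(pos_nodes[((j - 1L) * ps + 1L):min(j * ps, P)])
        pooled_all[[length(pooled_all) + 1L]] <-
          if (identical(hy$pool, "avg")) ad_meann(tape, win) else ad_maxn(tape, win)
      }
    }
    z <- ad_cbindn(tape, unlist(pooled_all))
    z <- ad_relu(tape, ad_add_bias(tape, ad_mm(tape, z, pids$branch_W), pids$branch_b))
    e_id <- ad_leaf(tape, batch$energy)
    z <- ad_cbind(tape, z, e_id)
    pred <- dense_cascade(tape, z, pids, spec)
    list(tape = tape, pred = pred, x = x_id, energy = e_id, params = pids)
  }
}

#' Predict editing efficiencies
#'
#' Forward pass in inference mode (dropout off); deterministic for identical
#' inputs. For an ensemble the prediction is the arithmetic mean of the
#' member predictions.
#'
#' @param object a `crisprtl_model` or `crisprtl_ensemble`.
#' @param batch an `encoded_batch` matching the model kind.
#' @param ... unused.
#' @return numeric vector of predicted efficiencies.
#' @export
predict.crisprtl_model <- function(object, batch, ...) {
  fw <- model_forward(object, batch, training = FALSE)
  as.vector(ad_val(fw$tape, fw$pred))
}

#' Bundle independently initialized models into an ensemble
#'
#' @param members list of `crisprtl_model`s sharing one spec.
#' @return a `crisprtl_ensemble`.
#' @export
ensemble_model <- function(members) {
  stopifnot(length(members) >= 1L)
  specs <- lapply(members, function(m) m$spec)
  for (s in specs[-1L]) if (!identical(s, specs[[1L]]))
    stopf("ensemble members must share one model spec")
  structure(list(members = members, member_count = length(members),
                 seeds = vapply(members, function(m) m$seed, 0L),
                 spec = specs[[1L]]),
            class = "crisprtl_ensemble")
}

#' @rdname predict.crisprtl_model
#' @export
predict.crisprtl_ensemble <- function(object, batch, ...) {
  preds <- vapply(object$members, function(m) predict(m, batch), numeric(batch$n))
  if (batch$n == 1L) preds <- matrix(preds, 1L)
  rowMeans(preds)
}

#' @export
print.crisprtl_ensemble <- function(x, ...) {
  cat(sprintf("<crisprtl_ensemble>: %d x %s model(s), seeds %s\n",
              x$member_count, x$spec$kind, paste(x$seeds, collapse = ",")))
  invisible(x)
}

#' Trainable parameter groups under a transfer-learning scheme
#'
#' `full` and `gradual_phase2` train everything; `last_layer` and
#' `gradual_phase1` train only the final hidden layer and the output layer;
#' `no_input_layer` trains everything except the input embedding (rnn) or
#' convolution branches (cnn).
#'
#' @param spec a `model_spec` (checked for group availability).
#' @param scheme one of `"full"`, `"last_layer"`, `"gradual_phase1"`,
#'   `"gradual_phase2"`, `"no_input_layer"`.
#' @return character vector of trainable group tags.
#' @export
freeze_mask <- function(spec, scheme = c("full", "last_layer", "gradual_phase1",
                                         "gradual_phase2", "no_input_layer")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         full = PARAM_GROUPS,
         gradual_phase2 = PARAM_GROUPS,
         last_layer = c("last_hidden", "output"),
         gradual_phase1 = c("last_hidden", "output"),
         no_input_layer = setdiff(PARAM_GROUPS, "input_embedding_or_conv"))
}

# ---- checkpoints --------------------------------------------------------

#' Save an ensemble checkpoint
#'
#' Writes a directory with the spec as JSON and, per member, one JSON weight
#' file per parameter group (so a fine-tuning scheme's footprint is visible
#' as which group files changed).
#'
#' @param ens a `crisprtl_ensemble`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- ens$spec
  jsonlite::write_json(list(kind = spec$kind, multi_task = spec$multi_task,
                            hyper = spec$hyper, seeds = ens$seeds),
                       file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  for (m in seq_along(ens$members)) {
    mdir <- file.path(dir, sprintf("member_%02d", m))
    dir.create(mdir, showWarnings = FALSE)
    mod <- ens$members[[m]]
    for (tag in unique(mod$groups)) {
      keep <- names(mod$groups)[mod$groups == tag]
      jsonlite::write_json(mod$params[keep], file.path(mdir, paste0(tag, ".json")),
                           digits = NA, matrix = "rowmajor")
    }
  }
  invisible(dir)
}

#' Load an ensemble checkpoint
#' @param dir directory written by [save_ensemble()].
#' @return a `crisprtl_ensemble`.
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  hyper <- meta$hyper
  for (f in c("dense_sizes", "conv_widths", "conv_filters"))
    if (!is.null(hyper[[f]])) hyper[[f]] <- as.integer(hyper[[f]])
  spec <- model_spec(meta$kind, multi_task = isTRUE(meta$multi_task), hyper = hyper)
  mdirs <- sort(list.dirs(dir, recursive = FALSE))
  members <- lapply(seq_along(mdirs), function(m) {
    proto <- build_model(spec, seed = as.integer(meta$seeds[m]))
    for (tag in unique(proto$groups)) {
      w <- jsonlite::read_json(file.path(mdirs[m], paste0(tag, ".json")),
                               simplifyVector = TRUE)
      for (nm in names(w)) {
        pm <- w[[nm]]
        if (!is.matrix(pm)) pm <- matrix(pm, nrow = nrow(proto$params[[nm]]), byrow = TRUE)
        dimnames(pm) <- NULL
        proto$params[[nm]] <- pm
      }
    }
    proto
  })
  ensemble_model(members)
}
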