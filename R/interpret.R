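# Gradient-saliency attribution and sequence-logo export.
#
# The attribution of nucleotide feature j is the average over samples of the
# gradient of the model output with respect to that input feature,
#   I_j = (1/n) sum_i dY_i / dX_{i,j},
# computed per ensemble member and averaged over members. For the recurrent
# model gradients are taken with respect to the one-hot layer feeding the
# embedding lookup (the embedding is one-hot x embedding-matrix, so the
# nucleotide features are exposed to differentiation); the start symbol is
# dropped. For the convolutional model the two fixed PAM GG positions are
# dropped. Bio-feature / energy / enzyme-indicator inputs are not part of the
# logo; their mean attributions are reported in a sidecar.

#' Saliency attribution of a trained model or ensemble
#'
#' @param object a `crisprtl_model` or `crisprtl_ensemble`.
#' @param batch an `encoded_batch` of the samples the model was trained or
#'   fine-tuned on.
#' @return an `attribution_matrix`: list with `I` (position x letter matrix;
#'   21 x 4 for the rnn, 28 x 4 for the cnn with PAM-GG columns removed;
#'   rownames are 0-based positions in the model's input coordinates),
#'   `n_samples`, and `extras` (named mean attributions of the non-nucleotide
#'   inputs).
#' @export
saliency <- function(object, batch) {
  if (inherits(object, "crisprtl_ensemble")) {
    per <- lapply(object$members, saliency, batch = batch)
    I <- Reduce(`+`, lapply(per, `[[`, "I")) / length(per)
    ex_names <- names(per[[1L]]$extras)
    extras <- if (length(ex_names))
      colMeans(do.call(rbind, lapply(per, `[[`, "extras"))) else numeric(0)
    return(structure(list(I = I, n_samples = batch$n, extras = extras),
                     class = "attribution_matrix"))
  }
  fw <- model_forward(object, batch, training = FALSE)
  s <- ad_sum_all(fw$tape, fw$pred)
  wanted <- c(fw$x, fw$bio %||% integer(0), fw$enzyme %||% integer(0),
              fw$energy %||% integer(0))
  grads <- ad_backward(fw$tape, s, wanted = wanted)
  gX <- grads[[fw$x]]
  if (is.null(gX)) stopf("no differentiable path from input features to output")
  Ivec <- colMeans(gX)
  extras <- numeric(0)
  if (object$spec$kind == "rnn") {
    I <- matrix(Ivec, nrow = 22L, ncol = 5L, byrow = TRUE)
    I <- I[-1L, 2:5, drop = FALSE]  # drop START position and START letter-slot
    rownames(I) <- as.character(0:20)
    gB <- grads[[fw$bio]]
    if (!is.null(gB)) {
      bx <- colMeans(gB); names(bx) <- BIOFEATURE_NAMES
      extras <- bx
    }
    if (!is.null(fw$enzyme)) {
      gE <- grads[[fw$enzyme]]
      if (!is.null(gE)) {
        ex <- colMeans(gE); names(ex) <- paste0("enzyme_", seq_along(ex))
        extras <- c(extras, ex)
      }
    }
  } else {
    I <- matrix(Ivec, nrow = 30L, ncol = 4L, byrow = TRUE)
    I <- I[-c(26L, 27L), , drop = FALSE]  # fixed GG at 0-based positions 25-26
    rownames(I) <- as.character(setdiff(0:29, c(25L, 26L)))
    gEn <- grads[[fw$energy]]
    if (!is.null(gEn)) extras <- c(energy_score = mean(gEn))
  }
  colnames(I) <- NUCLEOTIDES
  structure(list(I = I, n_samples = batch$n, extras = extras),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix>: %d positions x 4 letters over %d samples\n",
              nrow(x$I), x$n_samples))
  invisible(x)
}

#' Export an attribution matrix as a logo table
#'
#' Writes a position-weight-style tab-separated table (one row per position,
#' columns A/C/G/T, full double precision) consumable by standard sequence
#' logo renderers. Signed attributions are written by default; `absolute`
#' writes `|I|`. Non-nucleotide attributions go to a `<path>.extras.tsv`
#' sidecar when present.
#'
#' @param attr an `attribution_matrix` (or a bare numeric matrix).
#' @param path output TSV path.
#' @param absolute write absolute attributions.
#' @return `path`, invisibly.
#' @export
export_logo <- function(attr, path, absolute = FALSE) {
  I <- if (inherits(attr, "attribution_matrix")) attr$I else attr
  if (absolute) I <- abs(I)
  df <- data.frame(position = rownames(I) %||% as.character(seq_len(nrow(I)) - 1L),
                   apply(I, 2L, function(col) sprintf("%.17g", col)))
  names(df) <- c("position", colnames(I) %||% NUCLEOTIDES)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (inherits(attr, "attribution_matrix") && length(attr$extras)) {
    utils::write.table(data.frame(feature = names(attr$extras),
                                  attribution = sprintf("%.17g", attr$extras)),
                       paste0(path, ".extras.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a logo table written by [export_logo()]
#' @param path TSV path.
#' @return numeric matrix, positions x letters.
#' @export
read_logo <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(df[[1L]])
  M
}
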