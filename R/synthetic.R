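# Synthetic source/target dataset pairs with planted, tunably correlated
# position-letter effects.
#
# The generator stands in for the relationship between large high-throughput
# screens (synthetic genomic context, tens of thousands of guides) and small
# functional or endogenous datasets (hundreds of guides) whose readouts
# correlate only partially with the screens. The knob `rho` sets the
# correlation between the source and target effect matrices, so transfer
# learning has a tunable amount of shareable signal.

#' Simulator configuration
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' protocols: a 5000-guide source, a 300-guide target, source-target effect
#' correlation 0.6, moderate per-position effects with a GC-content effect,
#' and Gaussian observation noise.
#'
#' @param n_source,n_target dataset sizes.
#' @param effect_scale standard deviation of the planted per-position,
#'   per-letter effects.
#' @param gc_effect coefficient of `(GC fraction - 0.5)` in the true score.
#' @param noise_sd standard deviation of additive observation noise.
#' @param rho source-target effect correlation in `[0, 1]`.
#' @param seed integer seed; the whole pair is reproducible from the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_source = 5000L, n_target = 300L, effect_scale = 0.3,
                       gc_effect = 0.5, noise_sd = 0.1, rho = 0.6, seed = 1L) {
  stopifnot(rho >= 0, rho <= 1, noise_sd >= 0, effect_scale >= 0)
  structure(list(n_source = as.integer(n_source), n_target = as.integer(n_target),
                 seq_len = 30L, effect_scale = effect_scale, gc_effect = gc_effect,
                 noise_sd = noise_sd, rho = rho, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate unique random 30-nt contexts
#'
#' Uniform random letters except 0-based positions 25-26, which are fixed to
#' the GG of the PAM. Duplicates are redrawn until all sequences are unique.
#'
#' @param n number of contexts.
#' @param seed integer seed.
#' @return character vector of n unique 30-nt strings.
#' @export
generate_guides <- function(n, seed) {
  with_seed(seed, {
    draw <- function(k) {
      M <- matrix(sample(NUCLEOTIDES, k * 30L, replace = TRUE), k, 30L)
      M[, 26L] <- "G"; M[, 27L] <- "G"
      apply(M, 1L, paste, collapse = "")
    }
    out <- unique(draw(n))
    while (length(out) < n) out <- unique(c(out, draw(n - length(out))))
    out[seq_len(n)]
  })
}

#' Plant correlated source/target effect matrices
#'
#' Draws a 30 x 4 source effect matrix with iid normal(0, effect_scale^2)
#' entries and a target matrix
#' `w_target = rho * w_source + sqrt(1 - rho^2) * independent draw`, so the
#' expected entrywise correlation is `rho` (`rho = 1` gives identical
#' matrices). Each position's four letter effects are centered to mean zero:
#' an uncentered per-position offset would shift every sequence equally and
#' be unidentifiable, which would make attribution-recovery checks ill-posed.
#' Rows for the two fixed GG positions are zeroed (no sequence variation
#' exists there to express an effect).
#'
#' @param config a `sim_config`.
#' @return list with `w_source` and `w_target` (30 x 4 matrices, columns
#'   A,C,G,T).
#' @export
plant_effects <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    ws <- matrix(stats::rnorm(120L, 0, config$effect_scale), 30L, 4L)
    wi <- matrix(stats::rnorm(120L, 0, config$effect_scale), 30L, 4L)
    center <- function(w) {
      w <- w - rowMeans(w)
      w[c(26L, 27L), ] <- 0
      colnames(w) <- NUCLEOTIDES
      w
    }
    ws <- center(ws); wi <- center(wi)
    wt <- config$rho * ws + sqrt(1 - config$rho^2) * wi
    list(w_source = ws, w_target = wt)
  })
}

#' Simulate a dataset from planted effects
#'
#' True score = logistic(sum_j w[j, letter_j] + gc_effect * (GC fraction -
#' 0.5)) over the 30-nt context; the observed efficiency is the true score
#' plus normal(0, noise_sd) noise, min-max normalized per dataset (mirroring
#' the per-dataset normalization real datasets get). Bio-features and a
#' GC-proxy energy score are attached so both architectures can consume the
#' dataset directly.
#'
#' @param guides character vector of 30-nt contexts.
#' @param w 30 x 4 effect matrix.
#' @param config a `sim_config`.
#' @param name dataset name; also the single condition label is `"eff"`.
#' @param seed noise seed; defaults to the config seed.
#' @return a `guide_dataset` with attribute `"true_score"` (the noise-free
#'   scores, for oracle checks).
#' @export
simulate_dataset <- function(guides, w, config, name = "sim", seed = NULL) {
  n <- length(guides)
  letters_idx <- matrix(match(unlist(strsplit(guides, "")), NUCLEOTIDES),
                        nrow = n, byrow = TRUE)
  lin <- vapply(seq_len(n), function(i) sum(w[cbind(1:30, letters_idx[i, ])]), 0)
  proto_idx <- letters_idx[, 5:24, drop = FALSE]
  gc_frac <- rowMeans(proto_idx == 2L | proto_idx == 3L)
  true_score <- stats::plogis(lin + config$gc_effect * (gc_frac - 0.5))
  observed <- with_seed(derive_seed(seed %||% config$seed, 2L),
                        true_score + stats::rnorm(n, 0, config$noise_sd))
  eff <- minmax_normalize(observed, name = "simulated efficiency")
  rec <- tibble::tibble(id = sprintf("%s_%05d", name, seq_len(n)),
                        guide21 = substr(guides, 5, 25),
                        context30 = guides, eff_eff = eff)
  ds <- guide_dataset(rec, name = name, condition_labels = "eff",
                      provenance = "synthetic simulator")
  ds <- attach_biofeatures(ds)
  ds <- attach_energy_scores(ds, gc_proxy_energy)
  attr(ds, "true_score") <- true_score
  ds
}

#' Simulate a correlated source/target dataset pair
#'
#' @param config a `sim_config`.
#' @return list with `source` and `target` (`guide_dataset`s, each with its
#'   own normalization), and the planted `w_source` / `w_target` matrices.
#' @export
simulate_pair <- function(config) {
  w <- plant_effects(config)
  src_guides <- generate_guides(config$n_source, derive_seed(config$seed, 10L))
  tgt_guides <- generate_guides(config$n_target, derive_seed(config$seed, 11L))
  src <- simulate_dataset(src_guides, w$w_source, config, name = "source",
                          seed = derive_seed(config$seed, 20L))
  tgt <- simulate_dataset(tgt_guides, w$w_target, config, name = "target",
                          seed = derive_seed(config$seed, 21L))
  list(source = src, target = tgt, w_source = w$w_source, w_target = w$w_target)
}
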