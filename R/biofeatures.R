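# The 11 sequence-derived bio-features consumed by the recurrent model, and
# the pluggable binding-energy feature consumed by the convolutional model.
#
# Feature layout (length exactly 11, in this order):
#   acc_1_7, acc_8_14, acc_15_20   mean predicted unpaired probability over
#                                  protospacer positions 1-7, 8-14, 15-20
#   stem_loop                      fraction of seed positions predicted paired
#                                  in a hairpin stem
#   tm_full, tm_1_5, tm_6_13, tm_14_20
#                                  nearest-neighbor melting temperature of the
#                                  full 20-mer and three sub-segments
#   gc_count, gc_frac, gc_seed_frac
#                                  GC count and fraction over the protospacer,
#                                  GC fraction over the seed (positions 13-20)
#
# Segment boundaries are 1-based on the 20-nt protospacer and are exposed via
# the `boundaries` argument. The exact formulas are deliberately simple,
# deterministic defaults (documented as non-canonical): downstream training
# depends only on the contract of 11 finite reals per guide.

BIOFEATURE_NAMES <- c("acc_1_7", "acc_8_14", "acc_15_20", "stem_loop",
                      "tm_full", "tm_1_5", "tm_6_13", "tm_14_20",
                      "gc_count", "gc_frac", "gc_seed_frac")

# SantaLucia & Hicks (2004) unified DNA/DNA nearest-neighbor parameters:
# dH (kcal/mol), dS (cal/mol/K) per stacked dinucleotide + initiation terms.
NN_DH <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
           "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
           "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
           "CG" = -10.6, "GC" = -9.8, "GG" = -8.0, "CC" = -8.0)
NN_DS <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
           "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
           "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
           "CG" = -27.2, "GC" = -24.4, "GG" = -19.9, "CC" = -19.9)
NN_INIT_AT <- c(dh = 2.3, ds = 4.1)
NN_INIT_GC <- c(dh = 0.1, ds = -2.8)

#' Nearest-neighbor DNA melting temperature
#'
#' Two-state nearest-neighbor Tm with unified thermodynamic parameters,
#' terminal initiation corrections, a monovalent-salt entropy correction
#' (`dS + 0.368 (N-1) ln[Na+]`), and Tm = 1000 dH / (dS + R ln CT) - 273.15
#' for non-self-complementary duplexes at strand concentrations `dnac1`,
#' `dnac2` (nM).
#'
#' @param seq DNA string (>= 2 nt).
#' @param dnac1,dnac2 strand concentrations in nM.
#' @param Na monovalent cation concentration in mM.
#' @return Tm in degrees Celsius.
#' @export
tm_nn <- function(seq, dnac1 = 25, dnac2 = 25, Na = 50) {
  seq <- clean_seq(seq)
  n <- nchar(seq)
  if (n < 2L) stopf("tm_nn(): need at least 2 nt")
  letters <- strsplit(seq, "")[[1]]
  dn <- paste0(letters[-n], letters[-1L])
  dh <- sum(NN_DH[dn]); ds <- sum(NN_DS[dn])
  for (term in c(letters[1L], letters[n])) {
    if (term %in% c("A", "T")) { dh <- dh + NN_INIT_AT["dh"]; ds <- ds + NN_INIT_AT["ds"] }
    else { dh <- dh + NN_INIT_GC["dh"]; ds <- ds + NN_INIT_GC["ds"] }
  }
  ds <- ds + 0.368 * (n - 1) * log(Na * 1e-3)
  k <- (dnac1 - dnac2 / 2) * 1e-9
  unname(1000 * dh / (ds + 1.987 * log(k)) - 273.15)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Deterministic hairpin-heuristic folding backend
#'
#' Predicts at most one hairpin in the 21-nt guide: the stem maximizing
#' length (then 5'-most) among exact reverse-complement matches with stem
#' length >= 3 and loop length >= 3. Returns per-position unpaired
#' probabilities (0/1 under this single-structure model) and a dot-bracket
#' string. It requires no external tool; an external folding engine can be
#' substituted via the backend protocol of [compute_biofeatures()].
#'
#' @param seq nucleotide string.
#' @return list with `unpaired` (numeric vector, one per position) and
#'   `structure` (dot-bracket string).
#' @export
builtin_fold <- function(seq) {
  seq <- clean_seq(seq)
  n <- nchar(seq)
  best <- NULL
  for (L in seq(min(8L, (n - 3L) %/% 2L), 3L)) {
    for (i in 1:(n - 2L * L - 3L + 1L)) {
      left <- substr(seq, i, i + L - 1L)
      for (j in seq(i + L + 3L, n - L + 1L)) {
        if (substr(seq, j, j + L - 1L) == revcomp(left)) {
          best <- c(i = i, j = j, L = L); break
        }
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) break
  }
  paired <- rep(FALSE, n)
  db <- rep(".", n)
  if (!is.null(best)) {
    li <- best["i"]:(best["i"] + best["L"] - 1L)
    ri <- best["j"]:(best["j"] + best["L"] - 1L)
    paired[c(li, ri)] <- TRUE
    db[li] <- "("; db[ri] <- ")"
  }
  list(unpaired = as.numeric(!paired), structure = paste(db, collapse = ""))
}

#' Parse a dot-bracket structure string into a pairing indicator
#'
#' Adapter for external RNA-folding CLI output: any of `(`, `)`, `[`, `]`
#' counts as paired.
#'
#' @param structure dot-bracket string.
#' @return list with `unpaired` and `structure`, the backend protocol shape.
#' @export
parse_dot_bracket <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  list(unpaired = as.numeric(!ch %in% c("(", ")", "[", "]")), structure = structure)
}

#' Compute the 11 bio-features of one guide
#'
#' Secondary-structure features (accessibility over three protospacer
#' windows, a seed stem-loop score) are delegated to the folding backend;
#' melting temperatures use [tm_nn()]; GC features are direct counts. Pure:
#' the same guide and backend always yield the identical vector.
#'
#' @param guide21 21-nt guide string (20-nt protospacer + first PAM base).
#' @param folding_backend `"builtin"` or a callable
#'   `function(seq) -> list(unpaired=, structure=)`.
#' @param boundaries list overriding the segment boundaries: fields
#'   `acc` (3 x 2 matrix), `tm` (3 x 2 matrix), `seed` (length-2 vector),
#'   all 1-based inclusive on the protospacer.
#' @return named numeric vector of length 11 (see [BIOFEATURE_NAMES]).
#' @export
compute_biofeatures <- function(guide21, folding_backend = "builtin",
                                boundaries = NULL) {
  guide21 <- clean_seq(guide21)
  if (!grepl("^[ACGT]{21}$", guide21)) stopf("compute_biofeatures(): need a 21-nt ACGT guide")
  proto <- substr(guide21, 1, 20)
  b <- list(acc = rbind(c(1, 7), c(8, 14), c(15, 20)),
            tm = rbind(c(1, 5), c(6, 13), c(14, 20)),
            seed = c(13, 20))
  if (!is.null(boundaries)) b[names(boundaries)] <- boundaries

  backend <- if (identical(folding_backend, "builtin")) builtin_fold else folding_backend
  fold <- tryCatch(backend(guide21), error = function(e)
    stopf("folding backend failed on '%s': %s", guide21, conditionMessage(e)))
  unp <- fold$unpaired
  if (length(unp) < 20L) stopf("folding backend returned %d positions for '%s'",
                               length(unp), guide21)
  acc <- vapply(1:3, function(k) mean(unp[b$acc[k, 1]:b$acc[k, 2]]), 0)
  seed_idx <- b$seed[1]:b$seed[2]
  stem_loop <- mean(1 - unp[seed_idx])

  tms <- c(tm_nn(proto),
           vapply(1:3, function(k) tm_nn(substr(proto, b$tm[k, 1], b$tm[k, 2])), 0))

  letters <- strsplit(proto, "")[[1]]
  gc_count <- sum(letters %in% c("G", "C"))
  gc_seed <- mean(letters[seed_idx] %in% c("G", "C"))

  out <- c(acc, stem_loop, tms, gc_count, gc_count / 20, gc_seed)
  names(out) <- BIOFEATURE_NAMES
  out
}

#' Compute and attach bio-features for every guide in a dataset
#'
#' By default the attached matrix is z-scored per column within the dataset
#' (constant columns are left centered at 0): melting temperatures and GC
#' counts live on very different numeric scales than the one-hot sequence
#' inputs, and standardization keeps them from dominating early optimization.
#' The raw per-guide vectors are available via [compute_biofeatures()]; the
#' column means/sds used are stored as attributes `"bio_center"` /
#' `"bio_scale"` on the matrix.
#'
#' @param ds a `guide_dataset`.
#' @param folding_backend see [compute_biofeatures()].
#' @param standardize z-score the attached matrix per column.
#' @return the dataset with an n x 11 `biofeatures` matrix attached.
#' @export
attach_biofeatures <- function(ds, folding_backend = "builtin", standardize = TRUE) {
  M <- t(vapply(ds$records$guide21, compute_biofeatures, numeric(11L),
                folding_backend = folding_backend, USE.NAMES = FALSE))
  colnames(M) <- BIOFEATURE_NAMES
  if (standardize) {
    mu <- colMeans(M)
    sdv <- apply(M, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    M <- sweep(sweep(M, 2L, mu), 2L, sdv, "/")
    attr(M, "bio_center") <- mu
    attr(M, "bio_scale") <- sdv
  }
  ds$biofeatures <- M
  ds
}

#' GC-proxy binding-energy score
#'
#' A documented, deliberately simple stand-in for an external
#' binding-free-energy model (such as a Cas9-gRNA-DNA dG estimate): more
#' negative for GC-rich protospacers, with a small PAM-context adjustment
#' when the 30-nt context is available. Synthetic runs and tests use it so
#' the convolutional model's scalar side-input is always populated; real
#' analyses should inject precomputed scores instead.
#'
#' @param record one row of a `guide_dataset`'s records (list-like with
#'   `guide21` and optional `context30`).
#' @return a single finite numeric score.
#' @export
gc_proxy_energy <- function(record) {
  proto <- substr(record$guide21, 1, 20)
  letters <- strsplit(proto, "")[[1]]
  gc <- sum(letters %in% c("G", "C"))
  e <- -(0.35 * gc + 0.1 * 20)
  ctx <- record$context30
  if (!is.null(ctx) && !is.na(ctx)) {
    up <- substr(ctx, 1, 4)
    e <- e - 0.05 * sum(strsplit(up, "")[[1]] %in% c("G", "C"))
  }
  unname(e)
}

#' Attach binding-energy scores to a dataset
#'
#' Populates `energy_score` either from an existing numeric column of the
#' records table or by applying a callable to each record. The score source
#' is recorded in the dataset provenance.
#'
#' @param ds a `guide_dataset`.
#' @param source a column name present in `ds$records`, or a callable
#'   `function(record) -> numeric`.
#' @param allow_missing if TRUE, records whose score is missing/non-finite
#'   are dropped with a count in the provenance; otherwise they abort the run.
#' @return the dataset with `energy_score` populated.
#' @export
attach_energy_scores <- function(ds, source, allow_missing = FALSE) {
  if (is.character(source)) {
    if (!source %in% names(ds$records))
      stopf("energy column '%s' not found", source)
    scores <- as.numeric(ds$records[[source]])
    label <- paste("column", source)
  } else if (is.function(source)) {
    scores <- vapply(seq_len(n_guides(ds)), function(i)
      tryCatch(as.numeric(source(as.list(ds$records[i, ]))),
               error = function(e) NA_real_), 0)
    label <- "callable"
  } else stopf("source must be a column name or a callable")
  bad <- !is.finite(scores)
  if (any(bad)) {
    if (!allow_missing)
      stopf("%d record(s) with unresolvable energy score (first: %s)",
            sum(bad), ds$records$id[bad][1])
    ds$records <- ds$records[!bad, , drop = FALSE]
    if (!is.null(ds$biofeatures)) ds$biofeatures <- ds$biofeatures[!bad, , drop = FALSE]
    scores <- scores[!bad]
    ds$provenance <- paste0(ds$provenance, sprintf(" [dropped %d records lacking energy]", sum(bad)))
  }
  ds$records$energy_score <- scores
  ds$provenance <- paste0(ds$provenance, " [energy from ", label, "]")
  ds
}
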