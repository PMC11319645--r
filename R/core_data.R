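# Domain types and encodings shared by both model architectures.
#
# Coordinates are 0-based half-open throughout. The 30-nt extended context is
# laid out as [0,4) upstream, [4,24) protospacer, [24,27) PAM, [27,30)
# downstream; the last two PAM bases are fixed GG, so the 23-nt guide+PAM
# string is guide21 + "GG" and models only ever see the first 21 nt of it.


#' Construct a guide-efficiency dataset
#'
#' A `guide_dataset` holds one tabular CRISPR efficiency dataset: one row per
#' guide with its 21-nt sequence (20-nt protospacer + first PAM base), an
#' optional 30-nt extended context, per-condition editing efficiencies in
#' `[0,1]` (a condition is an enzyme variant such as WT/Esp/HF, or simply the
#' dataset's single readout), an optional binding-energy score, and optional
#' sequence-derived bio-features.
#'
#' @param records a data frame with columns `id`, `guide21`, and optionally
#'   `context30`, `energy_score`, plus one `eff_<label>` column per condition.
#' @param name dataset name.
#' @param condition_labels ordered character vector of condition labels; the
#'   order fixes the one-hot enzyme indicator. Defaults to labels found in
#'   `records`.
#' @param provenance free-text provenance note.
#' @param biofeatures optional numeric matrix (rows aligned to `records`) of
#'   11 bio-features.
#' @param norm optional named list recording per-condition normalization
#'   `list(min=, max=)` so predictions can be mapped back to the raw scale.
#' @param check_range enforce efficiencies in `[0,1]`; disable for raw-scale
#'   data that [normalize_dataset()] has not yet processed.
#' @return an object of class `guide_dataset`.
#' @export
guide_dataset <- function(records, name = "dataset", condition_labels = NULL,
                          provenance = "", biofeatures = NULL, norm = NULL,
                          check_range = TRUE) {
  records <- tibble::as_tibble(records)
  if (!all(c("id", "guide21") %in% names(records)))
    stopf("records must have 'id' and 'guide21' columns")
  if (anyDuplicated(records$id))
    stopf("record ids must be unique within a dataset")
  if (is.null(condition_labels)) {
    effcols <- grep("^eff_", names(records), value = TRUE)
    condition_labels <- sub("^eff_", "", effcols)
  }
  if (!"context30" %in% names(records)) records$context30 <- NA_character_
  if (!"energy_score" %in% names(records)) records$energy_score <- NA_real_
  ds <- structure(list(records = records, name = name,
                       condition_labels = condition_labels,
                       provenance = provenance,
                       biofeatures = biofeatures, norm = norm),
                  class = "guide_dataset")
  validate_guide_dataset(ds, check_range = check_range)
  ds
}

validate_guide_dataset <- function(ds, check_range = TRUE) {
  r <- ds$records
  bad <- !grepl("^[ACGT]{21}$", r$guide21)
  if (any(bad))
    stopf("invalid guide21 at rows: %s", paste(which(bad)[1:min(5, sum(bad))], collapse = ", "))
  has_ctx <- !is.na(r$context30)
  if (any(has_ctx)) {
    ctx <- r$context30[has_ctx]
    ok <- grepl("^[ACGT]{30}$", ctx) &
      substr(ctx, 5, 25) == r$guide21[has_ctx] &
      substr(ctx, 26, 27) == "GG"
    if (!all(ok))
      stopf("context30 inconsistent with guide21/GG PAM for ids: %s",
            paste(r$id[has_ctx][!ok][1:min(5, sum(!ok))], collapse = ", "))
  }
  for (cond in ds$condition_labels) {
    v <- r[[paste0("eff_", cond)]]
    if (is.null(v)) stopf("missing efficiency column for condition '%s'", cond)
    vv <- v[!is.na(v)]
    if (check_range && length(vv) && (min(vv) < 0 || max(vv) > 1))
      stopf("efficiencies for condition '%s' outside [0,1]; normalize first", cond)
  }
  if (!is.null(ds$biofeatures)) {
    stopifnot(nrow(ds$biofeatures) == nrow(r), ncol(ds$biofeatures) == 11L)
  }
  invisible(ds)
}

#' @export
print.guide_dataset <- function(x, ...) {
  cat(sprintf("<guide_dataset '%s'>: %d guides, conditions: %s\n",
              x$name, nrow(x$records),
              paste(x$condition_labels, collapse = ", ")))
  if (!is.null(x$biofeatures)) cat("  bio-features: attached (11 per guide)\n")
  if (!is.null(x$norm)) cat("  normalization: recorded (min/max per condition)\n")
  invisible(x)
}

#' Number of guides in a dataset
#' @param ds a `guide_dataset`.
#' @return integer count.
#' @export
n_guides <- function(ds) nrow(ds$records)

#' Subset a dataset by record ids
#' @param ds a `guide_dataset`.
#' @param ids character vector of record ids to keep (order preserved as in `ds`).
#' @return a `guide_dataset` with the matching records.
#' @export
subset_dataset <- function(ds, ids) {
  keep <- ds$records$id %in% ids
  ds$records <- ds$records[keep, , drop = FALSE]
  if (!is.null(ds$biofeatures)) ds$biofeatures <- ds$biofeatures[keep, , drop = FALSE]
  ds
}

#' The 23-nt guide+PAM sequences of a dataset
#'
#' Reconstructs guide21 + "GG"; all Hamming-distance comparisons operate on
#' these 23-mers.
#' @param ds a `guide_dataset`.
#' @return character vector of 23-nt strings.
#' @export
guide23 <- function(ds) paste0(ds$records$guide21, "GG")

clean_seq <- function(s) {
  s <- toupper(trimws(s))
  gsub("U", "T", s, fixed = TRUE)
}

#' Read a guide-efficiency table
#'
#' Ingests a CSV/TSV with a sequence column of length 21, 23, or 30 and one or
#' more numeric efficiency columns. 23-nt inputs must end in "GG" (the fixed
#' PAM dinucleotide) and are truncated to 21 nt; 30-nt inputs are stored as
#' extended context with the guide derived from offsets `[4,24)` + first PAM
#' base. Rows with an invalid alphabet (or a 23-mer not ending in GG) are
#' rejected and reported with their line numbers; rows whose efficiency does
#' not parse under a condition get an absent (`NA`) entry for that condition.
#'
#' @param path file path (.csv or .tsv/.txt; delimiter inferred).
#' @param schema list with `sequence` (column name), `efficiencies` (named
#'   character vector: condition label -> column name), optional `id` and
#'   `energy` column names.
#' @param name dataset name; defaults to the file name.
#' @return a `guide_dataset`; rejected rows are attached as attribute
#'   `"rejected"` (a data frame of line numbers and reasons) and reported via
#'   a warning.
#' @export
read_dataset <- function(path, schema, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "", quote = "\"")
  seqcol <- schema$sequence
  if (is.null(seqcol) || !seqcol %in% names(raw))
    stopf("schema$sequence column '%s' not found in %s", seqcol %||% "<NULL>", path)
  effmap <- schema$efficiencies
  if (is.null(effmap) || is.null(names(effmap)))
    stopf("schema$efficiencies must be a named vector: condition -> column")
  missing_eff <- setdiff(unname(effmap), names(raw))
  if (length(missing_eff))
    stopf("efficiency columns not found: %s", paste(missing_eff, collapse = ", "))

  seqs <- clean_seq(raw[[seqcol]])
  n <- length(seqs)
  lines <- seq_len(n) + 1L  # header is line 1
  reject_reason <- rep(NA_character_, n)

  len <- nchar(seqs)
  valid_alpha <- grepl("^[ACGT]+$", seqs)
  reject_reason[!valid_alpha] <- "non-ACGT characters in sequence"
  ok_len <- len %in% c(21L, 23L, 30L)
  reject_reason[valid_alpha & !ok_len] <- "sequence length not 21/23/30"
  is23 <- valid_alpha & len == 23L
  bad_pam <- is23 & substr(seqs, 22, 23) != "GG"
  reject_reason[bad_pam] <- "23-nt sequence does not end in GG"
  is30 <- valid_alpha & len == 30L
  bad_pam30 <- is30 & substr(seqs, 26, 27) != "GG"
  reject_reason[bad_pam30] <- "30-nt context lacks GG at PAM positions 25-26 (0-based)"

  keep <- is.na(reject_reason)
  if (!any(keep)) stopf("no valid rows in %s", path)
  rejected <- data.frame(line = lines[!keep], reason = reject_reason[!keep])
  if (nrow(rejected))
    warnf("%d row(s) rejected in %s (first at line %d: %s)",
          nrow(rejected), basename(path), rejected$line[1], rejected$reason[1])

  seqs <- seqs[keep]
  len <- len[keep]
  guide21 <- ifelse(len == 21L, seqs,
             ifelse(len == 23L, substr(seqs, 1, 21), substr(seqs, 5, 25)))
  context30 <- ifelse(len == 30L, seqs, NA_character_)
  ids <- if (!is.null(schema$id) && schema$id %in% names(raw))
    as.character(raw[[schema$id]][keep]) else sprintf("%s_%d", name, seq_len(sum(keep)))

  rec <- tibble::tibble(id = ids, guide21 = guide21, context30 = context30)
  for (cond in names(effmap)) {
    rec[[paste0("eff_", cond)]] <- suppressWarnings(as.numeric(raw[[effmap[[cond]]]][keep]))
  }
  rec$energy_score <- if (!is.null(schema$energy) && schema$energy %in% names(raw))
    suppressWarnings(as.numeric(raw[[schema$energy]][keep])) else NA_real_

  ds <- guide_dataset(rec, name = name, condition_labels = names(effmap),
                      provenance = paste("read from", path),
                      check_range = FALSE)  # raw scales allowed at ingestion
  attr(ds, "rejected") <- rejected
  ds
}

#' Write a guide-efficiency table
#'
#' Inverse of [read_dataset()]: writes sequences and efficiencies at full
#' precision, plus (optionally) a JSON sidecar with the recorded per-condition
#' normalization min/max so predictions can be mapped back to the raw scale.
#'
#' @param ds a `guide_dataset`.
#' @param path output CSV path.
#' @param sidecar write `<path>.norm.json` when normalization is recorded.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, sidecar = TRUE) {
  out <- as.data.frame(ds$records)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (sidecar && !is.null(ds$norm)) {
    jsonlite::write_json(ds$norm, paste0(path, ".norm.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Min-max normalize a numeric vector to [0,1]
#'
#' `(v - min) / (max - min)`, the per-dataset normalization applied to every
#' efficiency readout before any filtering or splitting. Rank order is
#' preserved; `NA`s pass through.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @param name label used in error messages (e.g. the column name).
#' @return numeric vector in `[0,1]`.
#' @export
minmax_normalize <- function(values, name = deparse(substitute(values))) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    stopf("cannot min-max normalize '%s': fewer than 2 distinct finite values", name)
  (values - min(v)) / (max(v) - min(v))
}

#' Min-max normalize every efficiency column of a dataset
#'
#' Applies [minmax_normalize()] per condition and records the raw min/max in
#' `ds$norm`. Normalization is per-dataset and happens before any
#' leakage filtering or splitting; it is not recomputed afterwards.
#'
#' @param ds a `guide_dataset` (efficiencies on any scale).
#' @return the dataset with efficiencies in `[0,1]` and `norm` recorded.
#' @export
normalize_dataset <- function(ds) {
  norm <- list()
  for (cond in ds$condition_labels) {
    col <- paste0("eff_", cond)
    v <- ds$records[[col]]
    fin <- v[is.finite(v)]
    norm[[cond]] <- list(min = min(fin), max = max(fin))
    ds$records[[col]] <- minmax_normalize(v, name = col)
  }
  ds$norm <- norm
  ds
}

# ---- encodings ----------------------------------------------------------

tokens_from_guides <- function(guides) {
  n <- length(guides)
  toks <- matrix(1L, n, 22L)  # column 1 = START
  letters_mat <- matrix(match(unlist(strsplit(guides, "")), NUCLEOTIDES) + 1L,
                        nrow = n, byrow = TRUE)
  toks[, 2:22] <- letters_mat
  toks
}

#' Encode guides for the recurrent model
#'
#' Token sequence = start symbol + 21 nucleotides over an integer alphabet of
#' size 5, concatenated (at the model's dense stage) with the 11 bio-features
#' and, for the multi-task model, a 3-long one-hot enzyme indicator in the
#' dataset's frozen condition order.
#'
#' @param ds a `guide_dataset` with bio-features attached (see
#'   [compute_biofeatures()]).
#' @param condition a condition label for the multi-task model (sets the
#'   enzyme indicator and the response), or `NULL` for a single-condition
#'   dataset. Rows with an absent efficiency under the chosen condition are
#'   dropped.
#' @param indicator_levels labels defining the indicator one-hot order;
#'   defaults to `ds$condition_labels`.
#' @return an `encoded_batch` with fields `tokens` (n x 22 integer),
#'   `biofeat` (n x 11), `enzyme` (n x 3 or NULL), `y`, `ids`, `n`.
#' @export
encode_rnn <- function(ds, condition = NULL, indicator_levels = NULL) {
  if (is.null(ds$biofeatures))
    stopf("dataset has no bio-features; run compute_biofeatures() first")
  if (is.null(condition)) {
    if (length(ds$condition_labels) != 1L)
      stopf("condition must be given for a multi-condition dataset")
    cond <- ds$condition_labels[1L]
    enzyme <- NULL
  } else {
    cond <- condition
    levels <- indicator_levels %||% ds$condition_labels
    k <- match(condition, levels)
    if (is.na(k)) stopf("unknown condition '%s'", condition)
  }
  y <- ds$records[[paste0("eff_", cond)]]
  keep <- !is.na(y)
  rec <- ds$records[keep, , drop = FALSE]
  toks <- tokens_from_guides(rec$guide21)
  bio <- ds$biofeatures[keep, , drop = FALSE]
  enzyme <- NULL
  if (!is.null(condition)) {
    levels <- indicator_levels %||% ds$condition_labels
    enzyme <- matrix(0, nrow(rec), length(levels))
    enzyme[, match(condition, levels)] <- 1
  }
  structure(list(kind = "rnn", tokens = toks, biofeat = bio, enzyme = enzyme,
                 y = y[keep], ids = rec$id, n = nrow(rec)),
            class = "encoded_batch")
}

#' Flatten a multi-condition dataset into one multi-task batch
#'
#' One training sample per observed (guide, condition) pair; conditions with
#' absent efficiencies contribute nothing.
#'
#' @param ds a `guide_dataset` with bio-features attached.
#' @return an `encoded_batch` with a 3-column enzyme indicator.
#' @export
encode_rnn_multitask <- function(ds) {
  parts <- lapply(ds$condition_labels, function(cond)
    encode_rnn(ds, condition = cond, indicator_levels = ds$condition_labels))
  structure(list(kind = "rnn",
                 tokens = do.call(rbind, lapply(parts, `[[`, "tokens")),
                 biofeat = do.call(rbind, lapply(parts, `[[`, "biofeat")),
                 enzyme = do.call(rbind, lapply(parts, `[[`, "enzyme")),
                 y = unlist(lapply(parts, `[[`, "y")),
                 ids = unlist(lapply(parts, `[[`, "ids")),
                 n = sum(vapply(parts, `[[`, 0L, "n"))),
            class = "encoded_batch")
}

#' Decode RNN token rows back to guide sequences
#' @param tokens integer matrix as produced by [encode_rnn()].
#' @return character vector of 21-nt guides.
#' @export
decode_rnn <- function(tokens) {
  apply(tokens[, -1L, drop = FALSE], 1L, function(r)
    paste(NUCLEOTIDES[r - 1L], collapse = ""))
}

onehot30 <- function(contexts) {
  n <- length(contexts)
  idx <- matrix(match(unlist(strsplit(contexts, "")), NUCLEOTIDES),
                nrow = n, byrow = TRUE)  # n x 30
  X <- matrix(0, n, 120L)
  for (p in 1:30) {
    X[cbind(seq_len(n), (p - 1L) * 4L + idx[, p])] <- 1
  }
  X
}

decode_onehot30 <- function(X) {
  apply(X, 1L, function(r) {
    idx <- max.col(matrix(r, 30L, 4L, byrow = TRUE))
    paste(NUCLEOTIDES[idx], collapse = "")
  })
}

#' Encode 30-nt contexts for the convolutional model
#'
#' One-hot 30 x 4 matrix per record (position-major, letter order A,C,G,T)
#' flattened to a 120-long row, plus the binding-energy score as a scalar side
#' input.
#'
#' @param ds a `guide_dataset` whose records all have `context30` and
#'   `energy_score`.
#' @param condition condition label for the response; defaults to the
#'   dataset's single condition.
#' @return an `encoded_batch` with fields `onehot` (n x 120), `energy`
#'   (n x 1), `y`, `ids`, `n`.
#' @export
encode_cnn <- function(ds, condition = NULL) {
  rec <- ds$records
  bad <- is.na(rec$context30)
  if (any(bad)) stopf("records missing context30: %s",
                      paste(rec$id[bad][1:min(5, sum(bad))], collapse = ", "))
  bad_e <- !is.finite(rec$energy_score)
  if (any(bad_e)) stopf("records missing energy_score: %s",
                        paste(rec$id[bad_e][1:min(5, sum(bad_e))], collapse = ", "))
  cond <- condition %||% ds$condition_labels[1L]
  y <- rec[[paste0("eff_", cond)]]
  keep <- !is.na(y)
  rec <- rec[keep, , drop = FALSE]
  structure(list(kind = "cnn", onehot = onehot30(rec$context30),
                 energy = matrix(rec$energy_score, ncol = 1L),
                 y = y[keep], ids = rec$id, n = nrow(rec)),
            class = "encoded_batch")
}

# row-subset an encoded batch (minibatching, splits)
batch_subset <- function(batch, idx) {
  out <- batch
  for (f in c("tokens", "biofeat", "enzyme", "onehot", "energy")) {
    if (!is.null(out[[f]])) out[[f]] <- out[[f]][idx, , drop = FALSE]
  }
  out$y <- batch$y[idx]
  out$ids <- batch$ids[idx]
  out$n <- length(idx)
  out
}
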