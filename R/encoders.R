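#' Construct an encoded dataset
#'
#' Container aligning a feature matrix with class labels and per-row
#' provenance.  Usually produced by [encode_properties()],
#' [encode_blosum()] or [encode_pssm()].
#'
#' @param features Numeric M x D matrix.
#' @param labels Logical vector of length M (TRUE = binding residue).
#' @param provenance Data frame with columns `chain_id`, `seq_index`
#'   (one row per example).
#' @param attribute_names Character vector of length D.
#' @return Object of class `encoded_dataset`.
#' @export
encoded_dataset <- function(features, labels, provenance,
                            attribute_names = colnames(features)) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (is.null(attribute_names)) {
    attribute_names <- sprintf("f%d", seq_len(ncol(features)))
  }
  stopifnot(nrow(features) == length(labels),
            nrow(features) == nrow(provenance),
            ncol(features) == length(attribute_names))
  colnames(features) <- attribute_names
  structure(list(features = features, labels = labels,
                 provenance = provenance,
                 attribute_names = attribute_names),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("encoded_dataset: ", nrow(x$features), " examples x ",
      ncol(x$features), " attributes (", sum(x$labels),
      " positive)\n", sep = "")
  invisible(x)
}

#' Combine encoded datasets by row
#'
#' @param ... `encoded_dataset` objects with identical attributes.
#' @return A single `encoded_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]]) &&
      !inherits(ds[[1]], "encoded_dataset")) ds <- ds[[1]]
  an <- ds[[1]]$attribute_names
  for (d in ds) stopifnot(identical(d$attribute_names, an))
  encoded_dataset(do.call(rbind, lapply(ds, `[[`, "features")),
                  unlist(lapply(ds, `[[`, "labels")),
                  do.call(rbind, lapply(ds, `[[`, "provenance")),
                  an)
}

# sliding-window concatenation of a per-residue representation matrix
# (N x P) into an N x ((2k+1)*P) feature matrix; out-of-range flank slots
# are filled with the per-attribute mean of `rep_mat` (neutral under a
# Gaussian likelihood) or with zeros
window_encode <- function(rep_mat, k, padding = c("mean", "zero")) {
  padding <- match.arg(padding)
  stopifnot(k >= 0, k == round(k))
  n <- nrow(rep_mat)
  p <- ncol(rep_mat)
  pad <- if (padding == "mean") colMeans(rep_mat) else rep(0, p)
  offs <- seq.int(-k, k)
  blocks <- lapply(offs, function(o) {
    src <- seq_len(n) + o
    out <- matrix(pad, n, p, byrow = TRUE)
    ok <- src >= 1L & src <= n
    out[ok, ] <- rep_mat[src[ok], , drop = FALSE]
    out
  })
  feat <- do.call(cbind, blocks)
  base <- colnames(rep_mat)
  if (is.null(base)) base <- paste0("f", seq_len(p))
  colnames(feat) <- unlist(lapply(offs, function(o)
    paste0("w", ifelse(o > 0, paste0("+", o), o), ".", base)))
  feat
}

residue_rep_properties <- function(sequence, table) {
  aa <- strsplit(sequence, "")[[1]]
  table <- validate_property_table(table)
  bad <- setdiff(unique(aa), c(rownames(table), "X"))
  if (length(bad) > 0L) {
    stop("residue code(s) not in property table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rep_mat <- matrix(NA_real_, length(aa), ncol(table),
                    dimnames = list(NULL, colnames(table)))
  known <- aa %in% rownames(table)
  rep_mat[known, ] <- table[aa[known], , drop = FALSE]
  if (any(!known)) {
    # 'X' (non-standard residue): neutral value = mean over the 20 residues
    rep_mat[!known, ] <- matrix(colMeans(table), sum(!known),
                                ncol(table), byrow = TRUE)
  }
  rep_mat
}

residue_rep_blosum <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  B <- blosum62_matrix()
  bad <- setdiff(unique(aa), c(rownames(B), "X"))
  if (length(bad) > 0L) {
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rep_mat <- matrix(0, length(aa), 20, dimnames = list(NULL, PSSM_COLS))
  known <- aa %in% rownames(B)
  rep_mat[known, ] <- B[aa[known], , drop = FALSE]   # 'X' -> zero vector
  rep_mat
}

check_labels <- function(labels, n, what) {
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") does not match ", what,
         " length (", n, ")", call. = FALSE)
  }
  as.logical(labels)
}

#' Encode a sequence with windowed amino-acid properties
#'
#' Each residue is represented by its row of the property table; the
#' feature vector of a residue is the concatenation of the `2k+1`
#' per-residue property vectors across the window centred on it, giving
#' `D = (2k+1) * P` attributes.  Window slots falling outside the chain
#' are filled by the padding rule.
#'
#' @param sequence One-letter amino-acid string; `"X"` is allowed for
#'   non-standard residues and maps to the per-property mean.
#' @param labels Logical binding labels, one per residue.
#' @param table A `property_table` (default [default_property_table()],
#'   48 properties).
#' @param k Number of neighbours on each side of the target residue
#'   (default 2, i.e. window size 5).
#' @param padding `"mean"` (per-attribute mean of the chain
#'   representation; default) or `"zero"`.
#' @param chain_id Identifier recorded in the provenance column.
#' @return An [encoded_dataset()] with one row per residue.
#' @export
encode_properties <- function(sequence, labels,
                              table = default_property_table(),
                              k = 2, padding = c("mean", "zero"),
                              chain_id = "chain") {
  labels <- check_labels(labels, nchar(sequence), "sequence")
  rep_mat <- residue_rep_properties(sequence, table)
  feat <- window_encode(rep_mat, k, padding)
  encoded_dataset(feat, labels,
                  data.frame(chain_id = chain_id,
                             seq_index = seq_along(labels)))
}

#' Encode a sequence with windowed BLOSUM62 rows
#'
#' Each residue is represented by its 20-entry BLOSUM62 row (`"X"` maps
#' to the zero vector); windows as in [encode_properties()], giving
#' `D = (2k+1) * 20` attributes.
#'
#' @inheritParams encode_properties
#' @return An [encoded_dataset()] with one row per residue.
#' @export
encode_blosum <- function(sequence, labels, k = 2,
                          padding = c("mean", "zero"),
                          chain_id = "chain") {
  labels <- check_labels(labels, nchar(sequence), "sequence")
  feat <- window_encode(residue_rep_blosum(sequence), k, padding)
  encoded_dataset(feat, labels,
                  data.frame(chain_id = chain_id,
                             seq_index = seq_along(labels)))
}

#' Encode a PSSM profile with sliding windows
#'
#' Each residue is represented by its 20-score profile row; the window
#' of `2k+1` rows centred on the target residue is flattened into a
#' `(2k+1) * 20` feature vector (the 20 x s profile window in row-major
#' order), with flank padding as in [encode_properties()].
#'
#' @param profile A [pssm_profile()].
#' @inheritParams encode_properties
#' @return An [encoded_dataset()] with one row per profile position.
#' @export
encode_pssm <- function(profile, labels, k = 2,
                        padding = c("mean", "zero"),
                        chain_id = "chain") {
  stopifnot(inherits(profile, "pssm_profile"))
  labels <- check_labels(labels, nrow(profile$scores), "profile")
  feat <- window_encode(profile$scores, k, padding)
  encoded_dataset(feat, labels,
                  data.frame(chain_id = chain_id,
                             seq_index = seq_along(labels)))
}

#' Fit a min-max normalizer on training data
#'
#' Learns per-attribute minima and maxima from the training features so
#' that [apply_normalizer()] can map attributes into `[0, 1]`.  Fit on
#' the training fold only - never on held-out chains.
#'
#' @param train An [encoded_dataset()] (non-empty).
#' @return Object of class `normalizer`.
#' @export
fit_normalizer <- function(train) {
  stopifnot(inherits(train, "encoded_dataset"),
            nrow(train$features) > 0L)
  structure(list(min = apply(train$features, 2, min),
                 max = apply(train$features, 2, max),
                 attribute_names = train$attribute_names),
            class = "normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' Maps each attribute by `(x - min) / (max - min)` using the training
#' extremes; attributes constant in training map to 0 and out-of-range
#' test values are clipped into `[0, 1]`.
#'
#' @param state A `normalizer` from [fit_normalizer()].
#' @param data An [encoded_dataset()] with the same attributes.
#' @return The normalized [encoded_dataset()].
#' @export
apply_normalizer <- function(state, data) {
  if (!inherits(state, "normalizer")) {
    stop("apply_normalizer() needs a fitted normalizer; got ",
         class(state)[1], call. = FALSE)
  }
  stopifnot(inherits(data, "encoded_dataset"),
            identical(state$attribute_names, data$attribute_names))
  rng <- state$max - state$min
  feat <- sweep(data$features, 2, state$min, "-")
  pos <- rng > 0
  feat[, pos] <- sweep(feat[, pos, drop = FALSE], 2, rng[pos], "/")
  feat[, !pos] <- 0
  feat[feat < 0] <- 0
  feat[feat > 1] <- 1
  encoded_dataset(feat, data$labels, data$provenance,
                  data$attribute_names)
}

#' Write an encoded dataset to TSV
#'
#' Provenance columns (`chain_id`, `seq_index`, `label`) followed by one
#' column per attribute.
#'
#' @param data An [encoded_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(data, path) {
  df <- data.frame(data$provenance,
                   label = as.integer(data$labels),
                   data$features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
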