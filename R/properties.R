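# AAindex three-letter residue order used by seqinr's aaindex data
AAINDEX_ORDER <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                   "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                   "Thr", "Trp", "Tyr", "Val")

# classic per-residue scales anchoring the default property set:
# hydropathy/hydrophobicity, polarity, bulk, charge-related and
# conformational-propensity indices widely used for residue encoding
CORE_AAINDEX <- c(
  "KYTJ820101",  # Kyte-Doolittle hydropathy
  "HOPT810101",  # Hopp-Woods hydrophilicity
  "EISD840101",  # Eisenberg consensus hydrophobicity
  "GRAR740102",  # Grantham polarity
  "ZIMJ680104",  # isoelectric point
  "FASG760101",  # molecular weight
  "KLEP840101",  # net charge
  "CHOC760101",  # accessible surface area in tripeptide
  "BIGC670101",  # residue volume
  "CHOP780201",  # alpha-helix propensity (Chou-Fasman)
  "CHOP780202",  # beta-sheet propensity
  "CHOP780203",  # beta-turn propensity
  "BHAR880101",  # flexibility (B-values)
  "JANJ780101",  # average accessible surface area
  "GRAR740103",  # Grantham volume
  "FAUJ880103"   # normalized van der Waals volume
)

#' Default per-residue amino-acid property table
#'
#' Builds a 20 x P table of per-amino-acid property values from the
#' AAindex collection shipped with seqinr: a curated core of classic
#' scales (Kyte-Doolittle hydropathy, Grantham polarity, molecular
#' weight, net charge, secondary-structure propensities, ...) topped up
#' deterministically, in accession order, with further NA-free AAindex
#' entries until `n_properties` columns are reached.  The table is an
#' ordinary input: substitute your own with [read_property_table()] if a
#' specific property set is required.
#'
#' @param n_properties Number of property columns (default 48).
#' @return A `property_table`: numeric matrix with one row per standard
#'   amino acid (one-letter rownames) and one column per property
#'   (AAindex accession colnames).
#' @export
default_property_table <- function(n_properties = 48) {
  stopifnot(n_properties >= 1)
  aaindex <- NULL # note: filled by data(); keeps R CMD check quiet
  utils::data("aaindex", package = "seqinr", envir = environment())
  complete <- names(aaindex)[vapply(aaindex, function(a)
    !any(is.na(a$I)), logical(1))]
  core <- CORE_AAINDEX[CORE_AAINDEX %in% complete]
  extra <- setdiff(sort(complete), core)
  take <- c(core, extra)[seq_len(min(n_properties, length(complete)))]
  one <- unname(AA_321[toupper(AAINDEX_ORDER)])
  vals <- vapply(take, function(acc) aaindex[[acc]]$I, numeric(20))
  rownames(vals) <- one
  vals <- vals[STANDARD_AA, , drop = FALSE]
  structure(vals, class = c("property_table", "matrix", "array"))
}

#' Read an amino-acid property table from TSV
#'
#' Expected layout: first column `aa` holding the 20 one-letter residue
#' codes, remaining columns one property each.
#'
#' @param path TSV file.
#' @return A `property_table` (20 x P numeric matrix).
#' @export
read_property_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df)[1], "aa")) {
    stop("property table must have 'aa' as its first column",
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$aa
  validate_property_table(m)
}

#' Write an amino-acid property table to TSV
#'
#' @param table A `property_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(table, path) {
  df <- data.frame(aa = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_property_table <- function(m) {
  if (!all(STANDARD_AA %in% rownames(m))) {
    stop("property table must cover all 20 standard amino acids; missing: ",
         paste(setdiff(STANDARD_AA, rownames(m)), collapse = ", "),
         call. = FALSE)
  }
  m <- m[STANDARD_AA, , drop = FALSE]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    stop("property table contains non-finite values", call. = FALSE)
  }
  structure(m, class = c("property_table", "matrix", "array"))
}
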