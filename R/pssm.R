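#' Construct a PSSM profile object
#'
#' @param sequence One-letter amino-acid string (or character vector).
#' @param scores Numeric N x 20 matrix of position-specific scores,
#'   columns in [PSSM_COLS] order.
#' @return Object of class `pssm_profile`: list with `sequence` (single
#'   string) and `scores`.
#' @export
pssm_profile <- function(sequence, scores) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (nrow(scores) != nchar(sequence)) {
    stop("profile has ", nrow(scores), " score rows but sequence length ",
         nchar(sequence), call. = FALSE)
  }
  if (ncol(scores) != 20L) {
    stop("PSSM scores must have 20 columns, got ", ncol(scores),
         call. = FALSE)
  }
  colnames(scores) <- PSSM_COLS
  rownames(scores) <- NULL
  structure(list(sequence = sequence, scores = scores),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("pssm_profile: ", nchar(x$sequence), " residues x 20 scores\n",
      sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard `-out_ascii_pssm` dump: the first 20-column block
#' (position-specific log-odds scores) of each data row is kept, in the
#' fixed `A R N D C Q E G H I L K M F P S T W Y V` column order; the
#' weighted-percentage block and trailing statistics are ignored.  The
#' sequence column is retained and validated against the row count.
#'
#' @param path Path to the PSSM file.
#' @return A [pssm_profile()].
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) stop("cannot read PSSM file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l)
    strsplit(trimws(l), "[[:space:]]+")[[1]])
  hdr <- which(vapply(toks, function(tk)
    length(tk) >= 20L && all(tk[1:20] == PSSM_COLS), logical(1)))
  if (length(hdr) == 0L) {
    stop("not a PSI-BLAST ASCII PSSM (no amino-acid header line): ", path,
         call. = FALSE)
  }
  hdr <- hdr[1]
  seq_chr <- character()
  rows <- list()
  pos <- 0L
  for (i in seq(hdr + 1L, length(lines))) {
    tk <- toks[[i]]
    if (length(tk) == 0L) break                       # end of matrix block
    if (is.na(suppressWarnings(as.integer(tk[1])))) break   # footer
    pos <- pos + 1L
    if (as.integer(tk[1]) != pos) {
      stop("PSSM line ", i, ": expected position ", pos, ", found '",
           tk[1], "'", call. = FALSE)
    }
    if (length(tk) < 22L) {
      stop("PSSM line ", i, ": truncated row (", length(tk) - 2L,
           " of 20 scores present)", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(v)) {
      stop("PSSM line ", i, ": non-numeric score field", call. = FALSE)
    }
    seq_chr[pos] <- tk[2]
    rows[[pos]] <- v
  }
  if (pos == 0L) stop("PSSM file has no data rows: ", path, call. = FALSE)
  pssm_profile(paste(seq_chr, collapse = ""), do.call(rbind, rows))
}

#' Write a profile in PSI-BLAST ASCII PSSM format
#'
#' Emits a file [parse_pssm()] accepts: header line with the 40
#' amino-acid column labels, one row per position with the 20 log-odds
#' scores followed by a zero percentage block and zero statistics.
#' Non-integer scores (e.g. synthetic profiles) are written with full
#' precision so that write/parse round-trips are exact.
#'
#' @param profile A [pssm_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  fmt1 <- function(v) {
    vapply(v, function(x) {
      if (is.finite(x) && x == round(x)) sprintf("%4d", as.integer(x))
      else sprintf("%s", format(x, digits = 17))
    }, "")
  }
  n <- nrow(profile$scores)
  aa <- strsplit(profile$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("          ", paste(sprintf("%3s", c(PSSM_COLS, PSSM_COLS)),
                               collapse = " "))), con)
  for (i in seq_len(n)) {
    writeLines(paste0(sprintf("%5d %s ", i, aa[i]),
                      paste(fmt1(profile$scores[i, ]), collapse = " "),
                      "  ", paste(rep("0", 20), collapse = "   "),
                      "  0.00 0.00"), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read amino-acid sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase one-letter sequences.
#' @export
read_fasta_sequences <- function(path) {
  sq <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  out <- toupper(vapply(sq, `[[`, "", 1))
  names(out) <- names(sq)
  out
}
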