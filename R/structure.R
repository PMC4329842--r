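#' Parse a PDB file into chains and ligand groups
#'
#' Reads ATOM/HETATM records and returns the polymer chains (ordered
#' residues with all deposited atoms, hydrogens included if present) and
#' the heteroatom groups.  Waters (HOH, DOD, WAT) are discarded.  When an
#' atom is deposited in alternate locations only the highest-occupancy
#' conformer is kept (ties resolved alphabetically by altloc).
#'
#' Residues arriving as ATOM records form the polymer chains; their
#' one-letter codes come from the standard 20-residue alphabet, with
#' non-standard residues mapped to `"X"` (their atoms still participate in
#' distance calculations).  Every HETATM residue that is not water becomes
#' one [ligand group][identify_ligands] - ions and crystallisation
#' additives included, since the binding-site definition places no
#' exclusion list beyond water.
#'
#' @param path Path to a PDB-format file.
#' @param model_index Which MODEL of a multi-model file to use (1-based,
#'   default 1, i.e. the first model).
#' @return An object of class `structure_record`: a list with `entry_id`,
#'   `chains` (named list, see Details) and `ligands` (list of
#'   `ligand_group`).  Each chain is a list with `chain_id`, `sequence`
#'   (character vector of one-letter codes, one per residue), `resno`
#'   (author residue numbering, metadata only) and `atoms` (data frame
#'   with `seq_index` (1-based, contiguous), `elety`, `x`, `y`, `z`,
#'   `o`).
#' @seealso [identify_ligands()], [label_binding_residues()]
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' sim <- simulate_structure(chain_length = 8, pocket_positions = 4:5,
#'                           seed = 1, path = pdb)
#' rec <- parse_structure(pdb)
#' length(rec$chains[[1]]$sequence)
parse_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) {
    stop("cannot read structure file: ", path, call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                     multi = model_index > 1,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (model_index > 1) {
    xyz <- pdb$xyz
    if (is.null(dim(xyz)) || nrow(xyz) < model_index) {
      stop("model_index ", model_index, " not present in '", path, "'",
           call. = FALSE)
    }
    co <- matrix(xyz[model_index, seq_len(3L * nrow(at))], ncol = 3,
                 byrow = TRUE)
    at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
  }
  at <- at[!(at$resid %in% WATER_CODES), , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  at <- keep_best_altloc(at)

  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0L) {
    stop("no polymer chains found in '", path, "'", call. = FALSE)
  }

  chains <- lapply(split(seq_len(nrow(prot)), prot$chain), function(idx) {
    ca <- prot[idx, , drop = FALSE]
    rkey <- paste(ca$resno, ca$insert)
    # residue order = order of first appearance in the file
    ukey <- rkey[!duplicated(rkey)]
    seq_index <- match(rkey, ukey)
    first <- !duplicated(rkey)
    code <- unname(AA_321[ca$resid[first]])
    code[is.na(code)] <- "X"
    list(chain_id = ca$chain[1],
         sequence = code,
         resno = ca$resno[first],
         atoms = data.frame(seq_index = seq_index,
                            elety = ca$elety,
                            x = ca$x, y = ca$y, z = ca$z, o = ca$o,
                            stringsAsFactors = FALSE))
  })
  chains <- chains[order(names(chains))]

  het <- at[at$type == "HETATM", , drop = FALSE]
  ligands <- list()
  if (nrow(het) > 0L) {
    gkey <- paste(het$chain, het$resno, het$insert, het$resid)
    ligands <- lapply(split(seq_len(nrow(het)), gkey), function(idx) {
      ha <- het[idx, , drop = FALSE]
      structure(list(het_code = ha$resid[1],
                     chain_id = ha$chain[1],
                     resno = ha$resno[1],
                     atoms = data.frame(elety = ha$elety,
                                        x = ha$x, y = ha$y, z = ha$z,
                                        o = ha$o,
                                        stringsAsFactors = FALSE)),
                class = "ligand_group")
    })
    names(ligands) <- NULL
  }

  structure(list(entry_id = sub("\\.(pdb|ent)$", "",
                                basename(path), ignore.case = TRUE),
                 chains = chains,
                 ligands = ligands),
            class = "structure_record")
}

# one row per deposited atom: among altloc copies of the same atom keep the
# highest occupancy (ties -> first altloc alphabetically)
keep_best_altloc <- function(at) {
  key <- paste(at$type, at$chain, at$resno, at$insert, at$resid, at$elety)
  if (!anyDuplicated(key)) return(at)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- at$o[idx]
    best <- idx[o == max(o)]
    best[order(at$alt[best])][1]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' @export
print.structure_record <- function(x, ...) {
  cat("structure_record '", x$entry_id, "': ",
      length(x$chains), " chain(s) [",
      paste(vapply(x$chains, function(ch)
        paste0(ch$chain_id, ":", length(ch$sequence)), ""), collapse = ", "),
      "], ", length(x$ligands), " ligand group(s)\n", sep = "")
  invisible(x)
}

lig_coords <- function(ligands) {
  if (length(ligands) == 0L) return(matrix(numeric(), 0, 3))
  do.call(rbind, lapply(ligands, function(l)
    cbind(l$atoms$x, l$atoms$y, l$atoms$z)))
}

chain_coords <- function(chain) {
  cbind(chain$atoms$x, chain$atoms$y, chain$atoms$z)
}

# minimum Euclidean distance from each row of A (n x 3) to any row of B
min_cross_dist <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(rep(Inf, nrow(A)))
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Keep only heteroatom groups in contact with the protein
#'
#' A heteroatom group counts as a bound ligand when at least one of its
#' atoms lies within the distance cutoff of at least one protein atom
#' (any chain); groups farther away - e.g. isolated additives from a
#' neighbouring asymmetric unit - are dropped.
#'
#' @param record A `structure_record` from [parse_structure()].
#' @param cutoff Contact distance in Angstrom (default 4.5).
#' @param inclusive Use `<=` instead of the default strict `<` at the
#'   cutoff.
#' @return List of `ligand_group` objects (possibly empty).
#' @export
identify_ligands <- function(record, cutoff = 4.5, inclusive = FALSE) {
  stopifnot(inherits(record, "structure_record"), cutoff > 0)
  P <- do.call(rbind, lapply(record$chains, chain_coords))
  keep <- vapply(record$ligands, function(l) {
    d <- min(min_cross_dist(cbind(l$atoms$x, l$atoms$y, l$atoms$z), P))
    if (inclusive) d <= cutoff else d < cutoff
  }, logical(1))
  record$ligands[keep]
}

#' Label the binding residues of a chain
#'
#' A residue is labelled as ligand-binding when the distance between any
#' of its atoms and any atom of any ligand group is lower than the cutoff
#' (strict `<`; 4.5 Angstrom by default).  An empty ligand list yields
#' all-FALSE labels.
#'
#' @param chain One chain of a `structure_record`.
#' @param ligands List of `ligand_group` objects (e.g. from
#'   [identify_ligands()]).
#' @param cutoff Contact distance in Angstrom (default 4.5).
#' @param inclusive Use `<=` instead of strict `<` at the cutoff.
#' @param method `"prefilter"` (default) screens residues against the
#'   ligand bounding box expanded by the cutoff before the exact scan;
#'   `"exhaustive"` computes every atom pair.  Both are exact and must
#'   agree; the exhaustive scan is retained as the reference path.
#' @return Object of class `binding_label_set`: list with `chain_id`,
#'   `labels` (logical, one per residue), `cutoff`.
#' @export
label_binding_residues <- function(chain, ligands, cutoff = 4.5,
                                   inclusive = FALSE,
                                   method = c("prefilter", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(cutoff > 0, length(chain$sequence) >= 1L)
  n_res <- length(chain$sequence)
  L <- lig_coords(ligands)
  labels <- rep(FALSE, n_res)
  if (nrow(L) > 0L) {
    P <- chain_coords(chain)
    idx <- chain$atoms$seq_index
    if (method == "prefilter") {
      lo <- apply(L, 2, min) - cutoff
      hi <- apply(L, 2, max) + cutoff
      inbox <- P[, 1] >= lo[1] & P[, 1] <= hi[1] &
        P[, 2] >= lo[2] & P[, 2] <= hi[2] &
        P[, 3] >= lo[3] & P[, 3] <= hi[3]
      P <- P[inbox, , drop = FALSE]
      idx <- idx[inbox]
    }
    if (nrow(P) > 0L) {
      d <- min_cross_dist(P, L)
      hit <- if (inclusive) d <= cutoff else d < cutoff
      labels[unique(idx[hit])] <- TRUE
    }
  }
  structure(list(chain_id = chain$chain_id, labels = labels,
                 cutoff = cutoff),
            class = "binding_label_set")
}

#' @export
print.binding_label_set <- function(x, ...) {
  cat("binding_label_set chain ", x$chain_id, ": ",
      sum(x$labels), "/", length(x$labels),
      " binding residues at cutoff ", x$cutoff, " A\n", sep = "")
  invisible(x)
}

#' Label every chain of a structure
#'
#' Convenience wrapper: runs [identify_ligands()] then
#' [label_binding_residues()] for each chain.
#'
#' @inheritParams identify_ligands
#' @inheritParams label_binding_residues
#' @return Named list of `binding_label_set`, one per chain.
#' @export
label_structure <- function(record, cutoff = 4.5, inclusive = FALSE,
                            method = c("prefilter", "exhaustive")) {
  method <- match.arg(method)
  ligs <- identify_ligands(record, cutoff = cutoff, inclusive = inclusive)
  out <- lapply(record$chains, label_binding_residues, ligands = ligs,
                cutoff = cutoff, inclusive = inclusive, method = method)
  names(out) <- names(record$chains)
  out
}

#' Write per-residue binding labels to TSV
#'
#' Columns: `chain_id`, `seq_index` (1-based), `residue_code`, `label`
#' (0/1).
#'
#' @param record A `structure_record`.
#' @param labelsets Named list of `binding_label_set` as returned by
#'   [label_structure()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(record, labelsets, path) {
  rows <- lapply(names(labelsets), function(cid) {
    ch <- record$chains[[cid]]
    ls <- labelsets[[cid]]
    stopifnot(length(ls$labels) == length(ch$sequence))
    data.frame(chain_id = cid,
               seq_index = seq_along(ch$sequence),
               residue_code = ch$sequence,
               label = as.integer(ls$labels),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue label TSV
#'
#' @param path File written by [write_labels_tsv()] (or any TSV with
#'   `chain_id` and 0/1 `label` columns ordered by residue).
#' @return Named list of logical label vectors, one per chain.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(split(df, df$chain_id), function(d)
    as.logical(d$label[order(d$seq_index)]))
}

#' Write the extracted chain sequences to FASTA
#'
#' @param record A `structure_record`.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(record, path) {
  seqs <- lapply(record$chains, function(ch) ch$sequence)
  nm <- paste(record$entry_id, names(record$chains), sep = "_")
  seqinr::write.fasta(seqs, names = nm, file.out = path)
  invisible(path)
}
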