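#' Simulate a toy structure with an implanted ligand pocket
#'
#' Emits PDB-format text for a poly-alanine chain (one CA atom per
#' residue) plus a single one-atom het group placed at the origin.
#' Pocket residues sit at `pocket_distance` Angstrom from the ligand
#' atom, all other residues at `decoy_distance`, each on its own
#' direction drawn uniformly on the sphere, so the ground-truth binding
#' labels at the default 4.5 Angstrom cutoff are exactly the pocket
#' positions.  Output is byte-identical for identical arguments and
#' seed.
#'
#' Coordinates are rounded to the PDB's three decimals, perturbing each
#' placed distance by less than 0.002 Angstrom - keep `pocket_distance`
#' and `decoy_distance` clear of the cutoff.
#'
#' @param chain_length Number of residues (>= 1).
#' @param pocket_positions 1-based residue indices forming the pocket.
#' @param pocket_distance Ligand-to-pocket-residue distance in Angstrom
#'   (default 3.0).
#' @param decoy_distance Distance for all other residues (default 20.0;
#'   must exceed `pocket_distance`).
#' @param seed Integer seed for the direction draws.
#' @param cutoff Cutoff the caller intends to label with; only used to
#'   warn when `pocket_distance >= cutoff` (which would make the
#'   expected positive labels unreachable).
#' @param path Optional file to write the PDB text to.
#' @return List with `pdb_text` (character vector of lines), `labels`
#'   (a `binding_label_set` holding the ground truth) and `path` (NULL
#'   unless written).
#' @export
simulate_structure <- function(chain_length = 10,
                               pocket_positions = integer(),
                               pocket_distance = 3.0,
                               decoy_distance = 20.0,
                               seed = 1, cutoff = 4.5, path = NULL) {
  stopifnot(chain_length >= 1,
            all(pocket_positions >= 1),
            all(pocket_positions <= chain_length),
            pocket_distance < decoy_distance)
  if (length(pocket_positions) > 0L && pocket_distance >= cutoff) {
    warning("pocket_distance (", pocket_distance,
            ") is not below the cutoff (", cutoff,
            "); pocket residues will not label as binding")
  }
  dirs <- withr::with_seed(seed, {
    z <- stats::runif(chain_length, -1, 1)
    phi <- stats::runif(chain_length, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(r * cos(phi), r * sin(phi), z)
  })
  is_pocket <- seq_len(chain_length) %in% pocket_positions
  radius <- ifelse(is_pocket, pocket_distance, decoy_distance)
  xyz <- round(dirs * radius, 3)
  atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                        record = "ATOM", elem = substr(name, 1, 1)) {
    sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name, " ", resn, chain, resno, " ",
            x, y, z, 1.0, 0.0, elem)
  }
  lines <- vapply(seq_len(chain_length), function(i)
    atom_line(i, "CA", "ALA", "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3],
              elem = "C"), "")
  lines <- c(lines,
             atom_line(chain_length + 1L, "C1", "LIG", "A",
                       chain_length + 1L, 0, 0, 0, record = "HETATM",
                       elem = "C"),
             "END")
  if (!is.null(path)) writeLines(lines, path)
  list(pdb_text = lines,
       labels = structure(list(chain_id = "A", labels = is_pocket,
                               cutoff = cutoff),
                          class = "binding_label_set"),
       path = path)
}

#' Simulate per-chain PSSM profiles with a class-conditional signal
#'
#' Generates a synthetic dataset mimicking the shape of a
#' PSSM-profile-encoded binding-residue problem: each chain gets a
#' random amino-acid sequence, binding labels drawn independently at
#' `binding_fraction` prevalence (default 0.1343, the class imbalance
#' typical of ligand-binding residues in membrane-protein chains), and a
#' 20-column Gaussian score matrix.  Non-binding rows are
#' `Normal(0, noise_sd^2)` in every column; binding rows are shifted by
#' `effect_size` on `shifted_cols`.  Because the columns are Gaussian,
#' the Bayes-optimal accuracy of the equal-prior two-class problem has
#' the closed form `Phi(effect_size * sqrt(length(shifted_cols)) /
#' (2 * noise_sd))`, which parameter-recovery tests exploit.
#'
#' @param n_chains Number of chains (default 20).
#' @param chain_length Residues per chain (default 500).
#' @param binding_fraction Label prevalence in `(0, 1)` (default
#'   0.1343).
#' @param effect_size Mean shift added to binding rows on the designated
#'   columns (default 1).
#' @param shifted_cols Indices (1-20) of the shifted profile columns
#'   (default 1:4).
#' @param noise_sd Column standard deviation (> 0, default 1).
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   dataset exactly.
#' @param heavy_tails If TRUE, draw the noise from a scaled Student-t
#'   with 3 degrees of freedom (same standard deviation) instead of a
#'   Gaussian - a robustness mode that breaks the closed forms on
#'   purpose.
#' @return List of chain inputs as consumed by [lopo_cv()]: each element
#'   has `chain_id`, `profile` (a [pssm_profile()]) and `labels`.
#' @export
simulate_profiles <- function(n_chains = 20, chain_length = 500,
                              binding_fraction = 0.1343,
                              effect_size = 1, shifted_cols = 1:4,
                              noise_sd = 1, seed = 1,
                              heavy_tails = FALSE) {
  stopifnot(n_chains >= 1, chain_length >= 1,
            binding_fraction > 0, binding_fraction < 1, noise_sd > 0,
            all(shifted_cols >= 1), all(shifted_cols <= 20))
  withr::with_seed(seed, {
    lapply(seq_len(n_chains), function(ci) {
      labels <- stats::runif(chain_length) < binding_fraction
      noise <- if (heavy_tails) {
        matrix(stats::rt(chain_length * 20, df = 3) / sqrt(3) * noise_sd,
               chain_length, 20)
      } else {
        matrix(stats::rnorm(chain_length * 20, 0, noise_sd),
               chain_length, 20)
      }
      noise[labels, shifted_cols] <-
        noise[labels, shifted_cols] + effect_size
      seqs <- paste(sample(PSSM_COLS, chain_length, replace = TRUE),
                    collapse = "")
      list(chain_id = sprintf("sim%02d", ci),
           profile = pssm_profile(seqs, noise),
           labels = labels)
    })
  })
}
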