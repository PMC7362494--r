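#' Standard atomic weights
#'
#' IUPAC standard atomic weights (unified atomic mass units) for the elements
#' of the SMILES organic subset.  Override entries to use another convention.
#'
#' @param ... Named numeric overrides, e.g. `atomic_weights(S = 32.065)`.
#' @return A named numeric vector of atomic weights.
#' @examples
#' atomic_weights()[["C"]]
#' @export
atomic_weights <- function(...) {
  w <- c(
    H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
    F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
  )
  dots <- c(...)
  if (length(dots) > 0) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      abort("Overrides to `atomic_weights()` must be named.")
    }
    w[names(dots)] <- dots
  }
  if (any(w <= 0)) abort("Atomic weights must be positive.")
  w
}

#' Constitutional descriptors of a molecule
#'
#' Computes the formula-level (constitutional) descriptors used for QSAR
#' tables: total atom count, heavy (non-hydrogen) atom count, the relative
#' number of atoms of each element present, molecular weight, and relative
#' (average per-atom) molecular weight.
#'
#' @param mol A `qw_molecule` from [parse_smiles()], or a SMILES string.
#' @param weights Named atomic-weight table, see [atomic_weights()].
#' @return A one-row tibble with columns `n_atoms`, `n_heavy`, `mol_weight`,
#'   `rel_mol_weight`, and one `rel_<element>` column per element present
#'   (e.g. `rel_H`).  The `rel_` columns sum to 1.
#' @examples
#' parse_smiles("C") |> constitutional_descriptors()
#' @export
constitutional_descriptors <- function(mol, weights = atomic_weights()) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "qw_molecule"))
  counts <- mol$element_counts
  n_atoms <- sum(counts)
  if (n_atoms < 1) abort("Molecule has no atoms.")
  missing <- setdiff(names(counts), names(weights))
  if (length(missing) > 0) {
    abort(sprintf("No atomic weight for element(s): %s.",
                  paste(sQuote(missing), collapse = ", ")),
          class = "qw_weight_error")
  }
  n_h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  mw <- sum(counts * weights[names(counts)])
  rel <- as.list(counts / n_atoms) |> setNames(paste0("rel_", names(counts)))
  tibble(
    n_atoms = as.integer(n_atoms),
    n_heavy = as.integer(n_atoms - n_h),
    !!!rel,
    mol_weight = mw,
    rel_mol_weight = mw / n_atoms
  )
}

# Column-name mapping onto the conventional constitutional descriptor codes.
QW_DESCRIPTOR_CODES <- c(
  D1 = "n_atoms", D2 = "rel_C", D3 = "rel_H", D4 = "rel_O",
  D5 = "rel_N", D6 = "rel_S", D15 = "mol_weight", D16 = "rel_mol_weight",
  D30 = "n_heavy"
)

#' Constitutional descriptor table for a set of compounds
#'
#' Data-frame-first wrapper around [constitutional_descriptors()]: takes a
#' table with a SMILES column and appends the descriptor columns, one row per
#' compound.
#'
#' @param data A data frame with a character SMILES column.
#' @param smiles_col Name of the SMILES column (default `"smiles"`).
#' @param weights Atomic-weight table.
#' @param codes If `TRUE`, name the descriptor columns by their conventional
#'   codes (`D1` total atoms, `D2`–`D6` relative C/H/O/N/S fractions, `D15`
#'   molecular weight, `D16` relative molecular weight, `D30` non-H atoms)
#'   instead of the descriptive names.
#' @return `data` with the descriptor columns appended.
#' @examples
#' tibble::tibble(smiles = c("C", "O=C=O")) |> constitutional_table()
#' @export
constitutional_table <- function(data, smiles_col = "smiles",
                                 weights = atomic_weights(), codes = FALSE) {
  stopifnot(is.data.frame(data))
  if (!smiles_col %in% names(data)) {
    abort(sprintf("Column %s not found in `data`.", sQuote(smiles_col)))
  }
  recs <- purrr::map(data[[smiles_col]], function(s) {
    constitutional_descriptors(parse_smiles(s), weights = weights)
  })
  desc <- dplyr::bind_rows(recs)
  rel_cols <- grep("^rel_(?!mol_weight)", names(desc), value = TRUE, perl = TRUE)
  desc[rel_cols] <- lapply(desc[rel_cols], function(x) tidyr::replace_na(x, 0))
  if (codes) {
    # fractions of elements absent everywhere appear as 0 columns when coded
    for (col in setdiff(unname(QW_DESCRIPTOR_CODES), names(desc))) desc[[col]] <- 0
    desc <- desc[unname(QW_DESCRIPTOR_CODES)]
    names(desc) <- names(QW_DESCRIPTOR_CODES)
  }
  dplyr::bind_cols(as_tibble(data), desc)
}
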