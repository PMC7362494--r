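#' Parse an organic-subset SMILES string into a molecule
#'
#' Parses the bracketless "organic subset" of SMILES — the dialect used for
#' neutral drug-like molecules such as the sulfonamides: elements
#' B, C, N, O, P, S, F, Cl, Br, I, aromatic lowercase atoms (`c`, `n`, `o`,
#' `s`, ...), branches in parentheses, single-digit ring closures, and the
#' explicit bonds `-`, `=`, `#`.  Implicit hydrogens are assigned by standard
#' valence rules (C = 4; N = 3 or 5; O = 2; S = 2, 4 or 6, so sulfonyl
#' `S(=O)(=O)` carries no hydrogen), and aromatic carbons / pyridine-type
#' nitrogens account for one ring double bond, so substituted aromatic
#' carbons carry no hydrogen.
#'
#' Charged species, isotopes, stereo bonds and bracket atoms are outside the
#' supported dialect and raise a parse error, as do unmatched ring-closure
#' digits and unknown element symbols.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `qw_molecule`: a list with elements `smiles`
#'   and `element_counts`, a named integer vector of the molecular formula
#'   (hydrogens included).
#' @examples
#' mol <- parse_smiles("Cc2cc(C)nc(NS(=O)(=O)c1ccc(N)cc1)n2") # sulfadimidine
#' mol$element_counts
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) || !nzchar(smiles)) {
    abort("`smiles` must be a single non-empty string.", class = "qw_parse_error")
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  atoms <- list()        # each: list(element, aromatic, bond_order_sum, degree)
  prev <- NA_integer_    # index of the atom a new atom bonds to
  pending_bond <- NA_real_  # explicit bond order for the next bond
  branch_stack <- integer(0)
  ring_open <- list()    # digit -> list(atom, order)

  add_bond <- function(i, j, order) {
    atoms[[i]]$bond_order_sum <<- atoms[[i]]$bond_order_sum + order
    atoms[[j]]$bond_order_sum <<- atoms[[j]]$bond_order_sum + order
    atoms[[i]]$degree <<- atoms[[i]]$degree + 1L
    atoms[[j]]$degree <<- atoms[[j]]$degree + 1L
  }

  add_atom <- function(element, aromatic) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic,
      bond_order_sum = 0, degree = 0L
    )
    idx <- length(atoms)
    if (!is.na(prev)) {
      order <- if (is.na(pending_bond)) 1 else pending_bond
      add_bond(prev, idx, order)
    }
    pending_bond <<- NA_real_
    prev <<- idx
    invisible(idx)
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE)
      i <- i + 2L
      next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE)
    } else if (ch == "=") {
      pending_bond <- 2
    } else if (ch == "#") {
      pending_bond <- 3
    } else if (ch == "-") {
      pending_bond <- 1
    } else if (ch == "(") {
      if (is.na(prev)) {
        abort("Branch opened before any atom.", class = "qw_parse_error")
      }
      branch_stack <- c(branch_stack, prev)
    } else if (ch == ")") {
      if (length(branch_stack) == 0) {
        abort("Unmatched closing parenthesis.", class = "qw_parse_error")
      }
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
    } else if (grepl("[1-9]", ch)) {
      if (is.na(prev)) {
        abort("Ring-closure digit before any atom.", class = "qw_parse_error")
      }
      if (!is.null(ring_open[[ch]])) {
        open <- ring_open[[ch]]
        order <- if (!is.na(pending_bond)) pending_bond else open$order
        if (is.na(order)) order <- 1
        add_bond(open$atom, prev, order)
        ring_open[[ch]] <- NULL
        pending_bond <- NA_real_
      } else {
        ring_open[[ch]] <- list(atom = prev, order = pending_bond)
        pending_bond <- NA_real_
      }
    } else if (ch == "[") {
      abort("Bracket atoms (charges, isotopes, explicit H) are not supported.",
            class = "qw_parse_error")
    } else {
      abort(sprintf("Unsupported character %s at position %d.", sQuote(ch), i),
            class = "qw_parse_error")
    }
    i <- i + 1L
  }

  if (length(ring_open) > 0) {
    abort(sprintf("Unmatched ring closure digit(s): %s.",
                  paste(names(ring_open), collapse = ", ")),
          class = "qw_parse_error")
  }
  if (length(branch_stack) > 0) {
    abort("Unclosed branch parenthesis.", class = "qw_parse_error")
  }
  if (length(atoms) == 0) {
    abort("No atoms parsed.", class = "qw_parse_error")
  }

  elements <- vapply(atoms, function(a) a$element, character(1))
  n_h <- sum(vapply(atoms, implicit_hydrogens, integer(1)))
  counts <- c(table(elements))
  if (n_h > 0) {
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + n_h
  }
  counts <- as.integer(counts[order(names(counts))]) |>
    setNames(sort(names(counts)))

  structure(
    list(smiles = smiles, element_counts = counts),
    class = "qw_molecule"
  )
}

# Standard valences of the organic subset; for multivalent elements the
# smallest valence not smaller than the bond-order sum is used.
QW_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

implicit_hydrogens <- function(atom) {
  bos <- atom$bond_order_sum
  if (atom$aromatic) {
    # Aromatic carbon always contributes one ring double bond; pyridine-type
    # nitrogen (two ring connections) does too; aromatic O/S donate a lone
    # pair instead, and 3-connected aromatic N is pyrrole-type/substituted.
    pi_extra <- switch(atom$element,
      C = 1,
      N = if (atom$degree <= 2L) 1 else 0,
      0
    )
    bos <- bos + pi_extra
  }
  valences <- QW_VALENCES[[atom$element]]
  if (is.null(valences)) {
    abort(sprintf("Element %s has no valence model.", sQuote(atom$element)),
          class = "qw_parse_error")
  }
  ok <- valences[valences >= bos]
  if (length(ok) == 0) {
    abort(sprintf("Valence %s exceeds the maximum (%d) for element %s.",
                  format(bos), max(valences), sQuote(atom$element)),
          class = "qw_parse_error")
  }
  as.integer(min(ok) - bos)
}

#' @export
print.qw_molecule <- function(x, ...) {
  cat("<qw_molecule> ", x$smiles, "\n", sep = "")
  cat("  formula: ", molecular_formula(x), "\n", sep = "")
  invisible(x)
}

#' Molecular formula in Hill order
#'
#' @param mol A `qw_molecule` from [parse_smiles()].
#' @return A single string such as `"C12H14N4O2S"`.
#' @export
molecular_formula <- function(mol) {
  stopifnot(inherits(mol, "qw_molecule"))
  counts <- mol$element_counts
  hill <- c(
    intersect(c("C", "H"), names(counts)),
    sort(setdiff(names(counts), c("C", "H")))
  )
  paste0(vapply(hill, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}
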