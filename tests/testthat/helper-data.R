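# Shared fixtures, built in code.

# Well-separated 3-class synthetic table, normalized, small enough for fast
# classifier fits.
sep_data <- function(n = 30, d = 15, n_inf = 9, classes = 3, sep = 6, seed = 1) {
  minmax_normalize(generate_synthetic(
    n_compounds = n, n_descriptors = d, n_informative = n_inf,
    n_classes = classes, class_separation = sep, noise_sd = 1, seed = seed
  ))
}

# Tiny labeled table with known values for I/O and normalization tests.
toy_table <- function() {
  tibble::tibble(
    compound_id = c("a", "b", "c"),
    label = c("short", "medium", "long"),
    d1 = c(2, 4, 6),
    d2 = c(5, 5, 5),
    d3 = c(0.25, 1, 0.5),
    d4 = c(-1, 0, 1)
  )
}

descriptor_cols_for_test <- function(ds) {
  setdiff(names(ds), c("compound_id", "smiles", "label"))
}

# The five sulfonamide SMILES with their printed molecular formulas.
sulfonamide_smiles <- function() {
  tibble::tribble(
    ~smiles, ~formula,
    "COc2cc(NS(=O)(=O)c1ccc(N)cc1)nc(OC)n2", "C12H14N4O4S",
    "Cc2cc(C)nc(NS(=O)(=O)c1ccc(N)cc1)n2", "C12H14N4O2S",
    "Cc2noc(NS(=O)(=O)c1ccc(N)cc1)c2C", "C11H13N3O3S",
    "Cc2nnc(NS(=O)(=O)c1ccc(N)cc1)s2", "C9H10N4O2S2",
    "Cc2cc(NS(=O)(=O)c1ccc(N)cc1)no2", "C10H11N3O3S"
  )
}
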