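# Static component registry mirroring the ontological component tuples of
# the surrounding smart-system design: descriptor-optimization components
# and recognition components, each either implemented here or a stub that
# names its ontology class.

QW_REGISTRY <- tibble::tribble(
  ~name,      ~kind,        ~ontology_class, ~status,
  "none",     "selector",   "OM_NONE",       "implemented",
  "gwo",      "selector",   "OM_GWO",        "implemented",
  "rf",       "selector",   "OM_RF",         "implemented",
  "pso",      "selector",   "OM_PSO",        "stub",
  "aco",      "selector",   "OM_ACO",        "stub",
  "abc",      "selector",   "OM_ABC",        "stub",
  "pca",      "selector",   "OM_PCA",        "stub",
  "nb",       "classifier", "OM_NB",         "implemented",
  "lr",       "classifier", "OM_LR",         "implemented",
  "dt",       "classifier", "OM_DT",         "implemented",
  "rf",       "classifier", "OM_RF",         "implemented",
  "svm",      "classifier", "OM_SVM",        "implemented",
  "airs",     "classifier", "OM_AIRS",       "implemented",
  "clonalg",  "classifier", "OM_ClS",        "implemented",
  "ins",      "classifier", "OM_IsM",        "implemented",
  "negsel",   "classifier", "OM_NgS",        "stub"
)

#' List the selector and classifier components
#'
#' Returns the static component registry: each descriptor-selection and
#' classification component, the ontology class it instantiates, and whether
#' it is implemented or a stub (stubs raise a uniform not-implemented error
#' when requested).
#'
#' @param as_json If `TRUE`, return the listing as a JSON string instead of
#'   a tibble.
#' @return A tibble (or JSON string) with columns `name`, `kind`,
#'   `ontology_class`, `status`.
#' @examples
#' describe_registry()
#' @export
describe_registry <- function(as_json = FALSE) {
  if (as_json) {
    return(jsonlite::toJSON(QW_REGISTRY, dataframe = "rows", pretty = TRUE))
  }
  QW_REGISTRY
}

registry_check <- function(kind, name) {
  rows <- QW_REGISTRY[QW_REGISTRY$kind == kind, ]
  if (!name %in% rows$name) {
    abort(sprintf(
      "Unknown %s %s. Registered %ss: %s.",
      kind, sQuote(name), kind, paste(rows$name, collapse = ", ")
    ), class = "qw_registry_error")
  }
  row <- rows[rows$name == name, ]
  if (row$status == "stub") {
    abort(sprintf(
      "%s %s (ontology class %s) is registered but not implemented.",
      tools::toTitleCase(kind), sQuote(name), row$ontology_class
    ), class = "qw_not_implemented")
  }
  invisible(TRUE)
}

#' Fit a descriptor selector by registry name
#'
#' Uniform entry point over the selection components: `"none"` keeps all
#' descriptors, `"gwo"` runs [gwo_select()], `"rf"` ranks descriptors by
#' random-forest importance (mean decrease in Gini) and keeps the top `k`.
#' Stub selectors (`pso`, `aco`, `abc`, `pca`) raise a not-implemented
#' error.
#'
#' @param name Registry name of the selector.
#' @param data A normalized descriptor tibble (training rows only — fit the
#'   selector inside each cross-validation fold to avoid leakage).
#' @param k Number of descriptors to keep (ignored by `"none"`).
#' @param seed Integer RNG seed.
#' @param args Named list of extra arguments for the underlying selector.
#' @return Sorted integer indices into the descriptor columns.
#' @export
fit_selector <- function(name, data, k = 200, seed = 1, args = list()) {
  registry_check("selector", name)
  data <- as_descriptor_table(data)
  d <- length(descriptor_cols(data))
  k <- min(k, d)
  switch(name,
    none = seq_len(d),
    gwo = do.call(gwo_select,
                  c(list(data = data, k = k, seed = seed), args))$selected_indices,
    rf = {
      m <- ds_matrix(data)
      imp <- withr::with_seed(seed, {
        randomForest::randomForest(x = m$X, y = droplevels(m$y),
                                   ntree = 200, importance = FALSE)
      })$importance[, "MeanDecreaseGini"]
      subset_from_weights(as.numeric(imp), k)
    }
  )
}
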