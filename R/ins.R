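#' Per-class standard matrices and their singular decompositions
#'
#' Builds the class "standards" of the immune-network model: for each class,
#' the descriptor vectors of its training compounds (the formal peptides)
#' are unit-normalized and stacked into a matrix `M`; the singular value
#' decomposition of `M` is taken and the leading `rank` triplets
#' (singular value, left vector, right vector) are retained.  The right
#' singular vectors span the class's recognition subspace.
#'
#' @param data A descriptor tibble (every class needs at least one row; rows
#'   must be non-zero vectors).
#' @param rank Number of singular triplets to keep per class; `NULL` keeps
#'   the full rank `min(class size, n_descriptors)`.
#' @return A list of `qw_class_standard` objects (fields `label`, `M`,
#'   `singular_values`, `right_vectors` (columns), `left_vectors`,
#'   `rank_used`), ordered short < medium < long.
#' @export
build_standards <- function(data, rank = NULL) {
  data <- as_descriptor_table(data)
  m <- ds_matrix(data)
  classes <- intersect(QW_CLASSES, levels(droplevels(m$y)))
  lapply(classes, function(cl) {
    M <- m$X[m$y == cl, , drop = FALSE]
    norms <- sqrt(rowSums(M^2))
    if (any(norms == 0)) {
      abort(sprintf("Class %s contains an all-zero descriptor row.", sQuote(cl)))
    }
    M <- M / norms
    full_rank <- min(dim(M))
    r <- rank %||% full_rank
    if (r < 1 || r > full_rank) {
      abort(sprintf("`rank` must satisfy 1 <= rank <= %d for class %s.",
                    full_rank, sQuote(cl)))
    }
    s <- svd(M, nu = r, nv = r)
    structure(
      list(
        label = cl,
        M = M,
        singular_values = s$d[seq_len(r)],
        right_vectors = s$v,
        left_vectors = s$u,
        rank_used = r,
        descriptors = m$descriptors
      ),
      class = "qw_class_standard"
    )
  })
}

#' Binding energy between a class standard and a query pattern
#'
#' The energy is the negative sum of singular-value-weighted absolute
#' projections of the unit query onto the standard's right singular vectors:
#' `E = -sum_i sigma_i * |<v_i, x / ||x||>|`.  It is always <= 0, invariant
#' under positive rescaling of `x`, and most negative when the query lies in
#' the class subspace — the class with minimal energy claims the pattern.
#'
#' @param std A `qw_class_standard` from [build_standards()].
#' @param x A non-zero numeric query vector of matching dimension.
#' @return The binding energy (a non-positive number).
#' @export
binding_energy <- function(std, x) {
  stopifnot(inherits(std, "qw_class_standard"))
  if (length(x) != nrow(std$right_vectors)) {
    abort("`x` must have the standard's descriptor dimension.")
  }
  nx <- sqrt(sum(x^2))
  if (nx == 0) abort("`x` must be a non-zero vector.")
  -sum(std$singular_values * abs(crossprod(std$right_vectors, x / nx)))
}

#' Immune-network classifier
#'
#' Wraps [build_standards()] and [binding_energy()] into a fitted model:
#' a query is assigned the class whose standard yields the minimal binding
#' energy; exact ties break to the lowest class index
#' (short < medium < long).  `type = "score"` returns the negated energies
#' (higher = more that class), and `energy_margin()` the gap between the two
#' lowest class energies — a confidence used to rank candidate compounds.
#'
#' @param data A normalized descriptor tibble.
#' @param rank Singular triplets kept per class (`NULL` = full rank).
#' @return An object of class `qw_ins`.
#' @export
ins <- function(data, rank = NULL) {
  data <- as_descriptor_table(data)
  standards <- build_standards(data, rank = rank)
  structure(
    list(
      standards = standards,
      classes = vapply(standards, function(s) s$label, character(1)),
      descriptors = standards[[1]]$descriptors,
      config = list(rank = rank)
    ),
    class = c("qw_ins", "qw_model")
  )
}

ins_energies <- function(object, X) {
  E <- vapply(object$standards, function(std) {
    apply(X, 1, function(x) binding_energy(std, x))
  }, numeric(nrow(X)))
  matrix(E, nrow = nrow(X), dimnames = list(NULL, object$classes))
}

#' @describeIn ins Predict classes, per-class scores (negated energies), or
#'   the raw energy matrix (`type = "energy"`).
#' @param object A fitted `qw_ins` model.
#' @param newdata A descriptor tibble, matrix, or single vector of non-zero
#'   rows.
#' @param type `"class"`, `"score"`, or `"energy"`.
#' @param ... Unused.
#' @export
predict.qw_ins <- function(object, newdata,
                           type = c("class", "score", "energy"), ...) {
  type <- match.arg(type)
  X <- query_matrix(newdata, object$descriptors)
  E <- ins_energies(object, X)
  if (type == "energy") return(E)
  if (type == "score") return(-E)
  # minimal energy wins; ties to the lowest class index (columns are already
  # in short < medium < long order)
  pred <- object$classes[apply(E, 1, which.min)]
  qw_class_factor(pred)
}

#' @describeIn ins Energy margin between the two lowest class energies for
#'   each row of `newdata` (0 when only one class exists).
#' @export
energy_margin <- function(object, newdata) {
  stopifnot(inherits(object, "qw_ins"))
  X <- query_matrix(newdata, object$descriptors)
  E <- ins_energies(object, X)
  if (ncol(E) < 2) return(rep(0, nrow(E)))
  apply(E, 1, function(e) {
    s <- sort(e)
    s[2] - s[1]
  })
}

#' @export
print.qw_ins <- function(x, ...) {
  cat(sprintf("<qw_ins> immune-network standards for %s (rank %s)\n",
              paste(x$classes, collapse = "/"),
              paste(vapply(x$standards, function(s) s$rank_used, integer(1)),
                    collapse = "/")))
  invisible(x)
}

#' @describeIn ins `tidy()` returns one row per retained singular triplet.
#' @param x A fitted `qw_ins` model.
#' @export
tidy.qw_ins <- function(x, ...) {
  purrr::map_dfr(x$standards, function(std) {
    tibble(
      label = std$label,
      component = seq_len(std$rank_used),
      singular_value = std$singular_values
    )
  })
}

#' @describeIn ins `glance()` returns a one-row fit summary.
#' @export
glance.qw_ins <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_descriptors = length(x$descriptors),
    total_rank = sum(vapply(x$standards, function(s) s$rank_used, integer(1)))
  )
}
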