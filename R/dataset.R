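#' Labeled descriptor tables
#'
#' A labeled descriptor table is an ordinary tibble with one row per compound:
#' a `compound_id` character column, an optional `smiles` column, a `label`
#' factor with levels `short`, `medium`, `long` (duration of pharmacological
#' action: <10 h, 10-24 h, 24-48 h), and numeric descriptor columns.  All
#' package functions accept and return this shape.
#'
#' @param data A data frame to validate.
#' @return `data` as a tibble with `label` coerced to the class factor,
#'   invisibly checked: no missing values, numeric descriptors.
#' @export
as_descriptor_table <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)
  if (!"label" %in% names(data)) {
    abort("A descriptor table requires a `label` column.", class = "qw_load_error")
  }
  if (!"compound_id" %in% names(data)) {
    data <- dplyr::mutate(data, compound_id = sprintf("cmp%03d", dplyr::row_number()),
                          .before = 1)
  }
  data$compound_id <- as.character(data$compound_id)
  data$label <- qw_class_factor(data$label)
  desc <- descriptor_cols(data)
  if (length(desc) == 0) {
    abort("A descriptor table requires at least one descriptor column.",
          class = "qw_load_error")
  }
  for (col in desc) {
    x <- data[[col]]
    if (!is.numeric(x)) {
      abort(sprintf("Descriptor column %s is not numeric.", sQuote(col)),
            class = "qw_load_error")
    }
    if (anyNA(x)) {
      abort(sprintf("Missing value in descriptor column %s (row %d).",
                    sQuote(col), which(is.na(x))[1]),
            class = "qw_load_error")
    }
  }
  if (anyNA(data$label)) {
    abort(sprintf("Missing class label in row %d.", which(is.na(data$label))[1]),
          class = "qw_load_error")
  }
  data
}

descriptor_cols <- function(data) {
  setdiff(names(data), c("compound_id", "smiles", "label"))
}

# matrix view of the descriptor columns
ds_matrix <- function(data) {
  cols <- descriptor_cols(data)
  X <- as.matrix(data[cols])
  rownames(X) <- data$compound_id
  list(X = X, y = data$label, descriptors = cols, ids = data$compound_id)
}

#' Read / write a labeled descriptor CSV
#'
#' CSV dialect: comma separator, `.` decimal, UTF-8, mandatory header.
#' Expected columns: `compound_id`, optional `smiles`, `label` (one of
#' `short`, `medium`, `long`), then numeric descriptor columns.  Missing
#' values and unknown labels are rejected with an error naming the offending
#' row/column; there is no imputation.
#'
#' @param path File path.
#' @return A validated descriptor tibble.
#' @export
read_descriptor_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  desc <- descriptor_cols(raw)
  for (col in desc) {
    if (is.character(raw[[col]])) {
      x <- suppressWarnings(as.numeric(raw[[col]]))
      if (anyNA(x) && !anyNA(raw[[col]])) {
        abort(sprintf("Non-numeric descriptor value in column %s (row %d).",
                      sQuote(col), which(is.na(x))[1]),
              class = "qw_load_error")
      }
      raw[[col]] <- x
    }
  }
  as_descriptor_table(raw)
}

#' @rdname read_descriptor_csv
#' @param data A descriptor tibble.
#' @export
write_descriptor_csv <- function(data, path) {
  data <- as_descriptor_table(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Min-max normalize descriptor columns to \[0, 1\]
#'
#' Maps every descriptor column through `(x - min) / (max - min)`; constant
#' columns map to 0.  Applying it twice is a no-op.  This is the
#' initialization/normalization stage every classifier in the package
#' assumes.
#'
#' @param data A descriptor tibble.
#' @return The normalized tibble.
#' @export
minmax_normalize <- function(data) {
  data <- as_descriptor_table(data)
  dplyr::mutate(data, dplyr::across(
    dplyr::all_of(descriptor_cols(data)),
    function(x) {
      rng <- range(x)
      if (rng[1] == rng[2]) return(rep(0, length(x)))
      (x - rng[1]) / (rng[2] - rng[1])
    }
  ))
}

#' Stratified train/test split
#'
#' Splits a descriptor table into train and test sets preserving class
#' proportions within one compound per class.  Deterministic for a fixed
#' seed.
#'
#' @param data A descriptor tibble.
#' @param test_fraction Fraction of each class assigned to the test set,
#'   strictly between 0 and 1.
#' @param seed Integer RNG seed.
#' @return A list with elements `train` and `test`.
#' @export
split_stratified <- function(data, test_fraction = 1 / 3, seed = 1) {
  data <- as_descriptor_table(data)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be strictly between 0 and 1.")
  }
  sizes <- table(droplevels(data$label))
  if (any(sizes < 2)) {
    abort(sprintf("Class %s has fewer than 2 members; cannot stratify.",
                  sQuote(names(sizes)[sizes < 2][1])))
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(levels(droplevels(data$label)), function(cl) {
      rows <- which(data$label == cl)
      n_test <- max(1L, round_half_up(length(rows) * test_fraction))
      sample(rows, min(n_test, length(rows) - 1L))
    }))
  })
  list(
    train = data[-sort(test_idx), , drop = FALSE],
    test  = data[sort(test_idx), , drop = FALSE]
  )
}

#' Cross-validation fold assignment, stratified by class
#' @noRd
qw_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      rows <- which(y == cl)
      rows <- sample(rows)
      assign[rows] <- rep_len(seq_len(folds), length(rows))
    }
  })
  assign
}

#' Generate a synthetic labeled descriptor table
#'
#' Emulates the statistical shape of a large QSAR descriptor database:
#' `n_descriptors` numeric columns of which `n_informative` carry a class
#' signal and the rest are pure Gaussian noise.  The informative columns are
#' assigned round-robin to the classes as class-specific markers (mirroring
#' substructure descriptors characteristic of one duration class): rows of
#' class `j` are shifted upward on the columns of block `j` by
#' `class_separation * noise_sd / sqrt(2 * block size)`, which places every
#' pair of class mean vectors at Euclidean distance
#' `class_separation * noise_sd` over the informative subspace (an
#' equilateral layout).  All columns carry i.i.d. Gaussian noise of SD
#' `noise_sd`.
#'
#' The indices of the informative columns are recorded in the
#' `"informative"` attribute (and retrievable with [informative_indices()])
#' so that feature-selection recovery can be scored.  Generation is bitwise
#' reproducible for a fixed seed.
#'
#' @param n_compounds Number of rows; classes are assigned near-balanced.
#' @param n_descriptors Number of descriptor columns.
#' @param n_informative Number of signal-carrying columns,
#'   `0 < n_informative <= n_descriptors`.
#' @param n_classes 2 or 3 (2 uses the `short`/`long` pairing).
#' @param class_separation Distance between any two class mean vectors over
#'   the informative subspace, in units of `noise_sd`.
#' @param noise_sd Noise standard deviation, > 0.
#' @param seed Integer RNG seed.
#' @return A descriptor tibble with attributes `informative` (sorted column
#'   indices into the descriptor columns) and `synthetic_spec`.
#' @export
generate_synthetic <- function(n_compounds = 15, n_descriptors = 2005,
                               n_informative = 200, n_classes = 3,
                               class_separation = 3, noise_sd = 1, seed = 1) {
  if (n_informative <= 0 || n_informative > n_descriptors) {
    abort("`n_informative` must satisfy 0 < n_informative <= n_descriptors.")
  }
  if (!n_classes %in% c(2L, 3L)) abort("`n_classes` must be 2 or 3.")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (class_separation < 0) abort("`class_separation` must be >= 0.")
  if (n_compounds < n_classes) abort("Need at least one compound per class.")

  classes <- switch(as.character(n_classes),
                    "2" = c("short", "long"), "3" = QW_CLASSES)
  labels <- rep_len(classes, n_compounds)

  withr::with_seed(seed, {
    informative <- sort(sample.int(n_descriptors, n_informative))
    X <- matrix(rnorm(n_compounds * n_descriptors, sd = noise_sd),
                nrow = n_compounds)
    block <- rep_len(seq_len(n_classes), n_informative)
    for (j in seq_len(n_classes)) {
      cols <- informative[block == j]
      if (length(cols) > 0) {
        shift <- class_separation * noise_sd / sqrt(2 * length(cols))
        X[labels == classes[j], cols] <- X[labels == classes[j], cols] + shift
      }
    }
  })

  colnames(X) <- sprintf("D%04d", seq_len(n_descriptors))
  out <- dplyr::bind_cols(
    tibble(
      compound_id = sprintf("syn%04d", seq_len(n_compounds)),
      label = qw_class_factor(labels)
    ),
    as_tibble(X)
  )
  attr(out, "informative") <- informative
  attr(out, "synthetic_spec") <- list(
    n_compounds = n_compounds, n_descriptors = n_descriptors,
    n_informative = n_informative, n_classes = n_classes,
    class_separation = class_separation, noise_sd = noise_sd, seed = seed
  )
  out
}

#' Informative column indices of a synthetic table
#' @param data A table from [generate_synthetic()].
#' @return Sorted integer indices into the descriptor columns.
#' @export
informative_indices <- function(data) {
  idx <- attr(data, "informative")
  if (is.null(idx)) abort("`data` carries no informative-column metadata.")
  idx
}

#' Write the synthetic-generation metadata as a JSON sidecar
#' @param data A table from [generate_synthetic()].
#' @param path Output JSON path.
#' @export
write_synthetic_meta <- function(data, path) {
  meta <- list(
    spec = attr(data, "synthetic_spec"),
    informative = attr(data, "informative")
  )
  if (is.null(meta$spec)) abort("`data` carries no synthetic metadata.")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
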