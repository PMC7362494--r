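#' Affinity between two pattern vectors
#'
#' Affinity is one minus the Euclidean distance normalized by the unit-cube
#' diagonal: `1 - ||x - y|| / sqrt(k)` for vectors in \[0, 1\]^k.  Identical
#' vectors have affinity 1; opposite corners of the cube have affinity 0.
#'
#' @param x,y Numeric vectors of equal length, expected in \[0, 1\].
#' @return Affinity in \[0, 1\].
#' @export
affinity <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same dimension.")
  }
  1 - sqrt(sum((x - y)^2)) / sqrt(length(x))
}

# Vectorized affinity of one query against the rows of a matrix.
affinity_rows <- function(M, x) {
  1 - sqrt(rowSums((M - matrix(x, nrow(M), length(x), byrow = TRUE))^2)) /
    sqrt(length(x))
}
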