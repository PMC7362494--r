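#' Artificial immune recognition system (AIRS) classifier
#'
#' Resource-limited memory-cell learner in the Watkins formulation.  Training
#' presents each antigen (training row) in order: the best same-class memory
#' cell is matched (the antigen founds the pool if no cell of its class
#' exists); a population of mutated clones (ARBs, artificial recognition
#' balls) competes for a limited resource budget allocated in proportion to
#' stimulation (affinity to the antigen); refinement rounds continue until
#' the mean stimulation reaches `stimulation_threshold`; the fittest ARB
#' becomes a candidate memory cell and enters the pool when it out-stimulates
#' the matched cell, replacing it when the two lie closer than
#' `affinity_threshold_scalar` times the mean inter-antigen distance.
#' Classification is a majority vote among the `k_neighbors`
#' highest-affinity memory cells.
#'
#' Training expects min-max normalized data ([minmax_normalize()]); ARB
#' mutation redraws each coordinate uniformly in \[0, 1\] with probability
#' `1 / hypermutation_rate`.  Runs are bitwise reproducible for a fixed seed.
#'
#' @param data A normalized descriptor tibble.
#' @param affinity_threshold_scalar Memory-cell replacement cutoff as a
#'   fraction of the mean inter-antigen distance, in (0, 1].
#' @param clonal_rate Clone-count and resource multiplier (integer).
#' @param hypermutation_rate Reciprocal per-coordinate mutation probability.
#' @param total_resources Resource budget each ARB population competes for.
#' @param stimulation_threshold Mean-stimulation stopping level in (0, 1).
#' @param k_neighbors Vote size at classification time (odd by default).
#' @param max_refinements Safety cap on refinement rounds per antigen.
#' @param seed Integer RNG seed.
#' @return An object of class `qw_airs` with the memory-cell pool (`cells`
#'   matrix, `cell_labels`), the per-step resource trace
#'   (`resource_trace`, every recorded value is <= `total_resources`), and
#'   the configuration.
#' @export
airs <- function(data, affinity_threshold_scalar = 0.2, clonal_rate = 10,
                 hypermutation_rate = 2, total_resources = 100,
                 stimulation_threshold = 0.9, k_neighbors = 3,
                 max_refinements = 10, seed = 1) {
  data <- as_descriptor_table(data)
  m <- ds_matrix(data)
  n <- nrow(m$X)
  if (n < 1) abort("Empty training set.")
  k <- ncol(m$X)
  stopifnot(affinity_threshold_scalar > 0, affinity_threshold_scalar <= 1,
            clonal_rate >= 1, hypermutation_rate >= 1,
            total_resources > 0,
            stimulation_threshold > 0, stimulation_threshold < 1)

  # mean pairwise distance between antigens: the affinity threshold scale
  mean_dist <- if (n > 1) mean(stats::dist(m$X)) else 0

  cells <- matrix(numeric(0), ncol = k)
  cell_labels <- character(0)
  resource_trace <- numeric(0)

  mutate_arb <- function(v) {
    redraw <- runif(k) < 1 / hypermutation_rate
    v[redraw] <- runif(sum(redraw))
    v
  }
  clone_rows <- function(v, n_clones) {
    if (n_clones < 1) return(NULL)
    do.call(rbind, lapply(seq_len(n_clones), function(.) mutate_arb(v)))
  }

  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      ag <- m$X[i, ]
      lab <- as.character(m$y[i])
      same <- which(cell_labels == lab)
      if (length(same) == 0) {
        cells <- rbind(cells, ag)
        cell_labels <- c(cell_labels, lab)
        next
      }
      match_aff <- affinity_rows(cells[same, , drop = FALSE], ag)
      mc <- cells[same[which.max(match_aff)], ]
      mc_stim <- max(match_aff)

      # initial ARB population: the matched cell plus mutated clones
      n_clones <- ceiling(clonal_rate * mc_stim)
      arbs <- rbind(mc, clone_rows(mc, n_clones))
      for (round in seq_len(max_refinements)) {
        stim <- affinity_rows(arbs, ag)
        resources <- stim * clonal_rate
        ord <- order(resources)
        drop <- integer(0)
        j <- 1
        while (sum(resources) - sum(resources[drop]) > total_resources &&
               length(drop) < nrow(arbs) - 1) {
          drop <- c(drop, ord[j])
          j <- j + 1
        }
        if (length(drop) > 0) {
          arbs <- arbs[-drop, , drop = FALSE]
          stim <- stim[-drop]
          resources <- resources[-drop]
        }
        resource_trace <- c(resource_trace, sum(resources))
        if (mean(stim) >= stimulation_threshold) break
        # surviving ARBs proliferate in proportion to their stimulation
        children <- do.call(rbind, lapply(seq_len(nrow(arbs)), function(r) {
          clone_rows(arbs[r, ], ceiling(clonal_rate * stim[r] / nrow(arbs)))
        }))
        if (!is.null(children)) arbs <- rbind(arbs, children)
      }
      stim <- affinity_rows(arbs, ag)
      candidate <- arbs[which.max(stim), ]
      if (max(stim) > mc_stim) {
        cells <- rbind(cells, candidate)
        cell_labels <- c(cell_labels, lab)
        if (sqrt(sum((candidate - mc)^2)) <
            affinity_threshold_scalar * mean_dist) {
          # candidate supersedes the matched cell
          kill <- same[which.max(match_aff)]
          cells <- cells[-kill, , drop = FALSE]
          cell_labels <- cell_labels[-kill]
        }
      }
    }
  })
  rownames(cells) <- NULL

  structure(
    list(
      cells = cells,
      cell_labels = qw_class_factor(cell_labels),
      descriptors = m$descriptors,
      classes = levels(droplevels(m$y)),
      resource_trace = resource_trace,
      config = list(
        affinity_threshold_scalar = affinity_threshold_scalar,
        clonal_rate = clonal_rate, hypermutation_rate = hypermutation_rate,
        total_resources = total_resources,
        stimulation_threshold = stimulation_threshold,
        k_neighbors = k_neighbors, max_refinements = max_refinements,
        seed = seed
      )
    ),
    class = c("qw_airs", "qw_model")
  )
}

#' @describeIn airs Predict classes (or per-class vote fractions with
#'   `type = "score"`) for new rows.  The vote is taken among the
#'   `k_neighbors` highest-affinity memory cells; ties break to the class of
#'   the single nearest cell.
#' @param object A fitted `qw_airs` model.
#' @param newdata A descriptor tibble with the training descriptor columns.
#' @param type `"class"` for labels, `"score"` for the vote-fraction matrix.
#' @param ... Unused.
#' @export
predict.qw_airs <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- query_matrix(newdata, object$descriptors)
  kk <- min(object$config$k_neighbors, nrow(object$cells))
  labs <- as.character(object$cell_labels)
  votes <- matrix(0, nrow(X), length(QW_CLASSES),
                  dimnames = list(NULL, QW_CLASSES))
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    aff <- affinity_rows(object$cells, X[i, ])
    ord <- order(-aff, seq_along(aff))  # ties to the earlier cell
    top <- ord[seq_len(kk)]
    tab <- table(factor(labs[top], levels = QW_CLASSES))
    votes[i, ] <- tab / kk
    winners <- names(tab)[tab == max(tab)]
    pred[i] <- if (length(winners) == 1) winners else labs[ord[1]]
  }
  if (type == "score") return(votes)
  qw_class_factor(pred)
}

# Coerce prediction input to the descriptor-matrix the model was fitted on.
query_matrix <- function(newdata, descriptors) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1)
    colnames(newdata) <- descriptors
    return(newdata)
  }
  if (is.matrix(newdata)) {
    stopifnot(ncol(newdata) == length(descriptors))
    return(newdata)
  }
  stopifnot(is.data.frame(newdata))
  missing <- setdiff(descriptors, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("`newdata` lacks descriptor column(s): %s.",
                  paste(sQuote(head(missing, 3)), collapse = ", ")))
  }
  as.matrix(newdata[descriptors])
}

#' @export
print.qw_airs <- function(x, ...) {
  cat(sprintf("<qw_airs> %d memory cells over %d descriptors (%s)\n",
              nrow(x$cells), ncol(x$cells),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' @describeIn airs `tidy()` returns one row per memory cell.
#' @param x A fitted `qw_airs` model.
#' @export
tidy.qw_airs <- function(x, ...) {
  out <- as_tibble(x$cells, .name_repair = ~ x$descriptors)
  dplyr::bind_cols(tibble(cell = seq_len(nrow(x$cells)), label = x$cell_labels), out)
}

#' @describeIn airs `glance()` returns a one-row fit summary.
#' @export
glance.qw_airs <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    n_descriptors = ncol(x$cells),
    max_resources_recorded = if (length(x$resource_trace)) max(x$resource_trace) else NA_real_,
    total_resources = x$config$total_resources,
    seed = x$config$seed
  )
}
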