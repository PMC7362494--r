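#' Clone counts of the ranked antibodies
#'
#' The i-th ranked (by affinity) selected antibody produces
#' `round(beta * N / i)` clones, rounding halves up, so with `beta = 1`,
#' `N = 10` the ranks 1..4 clone 10, 5, 3 and 3 times.
#'
#' @param n_select Number of ranked antibodies.
#' @param N Pool size.
#' @param beta Clonal expansion factor.
#' @return Integer clone counts for ranks `1..n_select`.
#' @export
clonalg_clone_counts <- function(n_select, N, beta = 1) {
  as.integer(round_half_up(beta * N / seq_len(n_select)))
}

#' CLONALG clonal-selection classifier
#'
#' Trains one antibody repertoire per class by clonal selection: antibodies
#' start uniform in \[0, 1\]^k; each generation presents every training
#' antigen of the class, selects the `n_select` highest-affinity antibodies,
#' clones them with rank-dependent counts ([clonalg_clone_counts()]),
#' matures the clones by per-coordinate Gaussian hypermutation with standard
#' deviation `mutation_sd * (1 - affinity)` (high-affinity clones mutate
#' little), keeps the best clone versus its parent (elitist), and finally
#' replaces the `d_replace` lowest-affinity antibodies with fresh uniform
#' ones.  The per-class pool size stays exactly `N` throughout, and the best
#' affinity to any presented antigen never decreases across generations.
#'
#' Classification assigns the class owning the single highest-affinity
#' antibody; exact ties break to the lowest class index
#' (short < medium < long).
#'
#' @param data A normalized descriptor tibble.
#' @param N Antibodies per class.
#' @param n_select Antibodies selected per antigen presentation, `<= N`.
#' @param beta Clonal expansion factor.
#' @param d_replace Worst antibodies refreshed per presentation.
#' @param generations Training generations.
#' @param mutation_sd Base hypermutation standard deviation.
#' @param seed Integer RNG seed.
#' @return An object of class `qw_clonalg` with per-class repertoires, the
#'   per-generation pool-size trace and best-affinity trace (one row per
#'   generation, one column per training antigen), and the configuration.
#' @export
clonalg <- function(data, N = 30, n_select = 5, beta = 1, d_replace = 2,
                    generations = 20, mutation_sd = 0.2, seed = 1) {
  data <- as_descriptor_table(data)
  m <- ds_matrix(data)
  k <- ncol(m$X)
  if (n_select > N) abort("`n_select` must not exceed the pool size `N`.")
  stopifnot(N >= 1, beta > 0, d_replace >= 0, d_replace < N, generations >= 1)
  classes <- levels(droplevels(m$y))

  counts <- clonalg_clone_counts(n_select, N, beta)
  pool_trace <- list()
  best_aff <- matrix(NA_real_, generations, nrow(m$X))

  withr::with_seed(seed, {
    pools <- lapply(classes, function(cl) matrix(runif(N * k), nrow = N))
    names(pools) <- classes
    # affinity of every pool antibody to every same-class antigen, kept
    # incrementally so elitism can be enforced across antigens: a
    # replacement is rejected if it would lower the pool's best affinity to
    # any antigen of the class.
    ag_rows <- lapply(classes, function(cl) which(m$y == cl))
    names(ag_rows) <- classes
    aff_mat <- lapply(classes, function(cl) {
      ags <- m$X[ag_rows[[cl]], , drop = FALSE]
      A <- matrix(0, N, nrow(ags))
      for (r in seq_len(N)) A[r, ] <- affinity_rows(ags, pools[[cl]][r, ])
      A
    })
    names(aff_mat) <- classes

    try_replace <- function(cl, row, candidate) {
      cand_aff <- affinity_rows(m$X[ag_rows[[cl]], , drop = FALSE], candidate)
      A <- aff_mat[[cl]]
      old_max <- apply(A, 2, max)
      A[row, ] <- cand_aff
      new_max <- apply(A, 2, max)
      if (any(new_max < old_max - 1e-12)) return(FALSE)
      pools[[cl]][row, ] <<- candidate
      aff_mat[[cl]] <<- A
      TRUE
    }

    for (g in seq_len(generations)) {
      for (i in seq_len(nrow(m$X))) {
        cl <- as.character(m$y[i])
        ag <- m$X[i, ]
        ag_pos <- match(i, ag_rows[[cl]])
        aff <- aff_mat[[cl]][, ag_pos]
        sel <- order(-aff, seq_len(N))[seq_len(n_select)]
        for (r in seq_len(n_select)) {
          parent <- pools[[cl]][sel[r], ]
          pa <- aff_mat[[cl]][sel[r], ag_pos]
          sdr <- mutation_sd * (1 - pa)
          clones <- matrix(
            pmin(1, pmax(0, rep(parent, each = counts[r]) +
                           rnorm(counts[r] * k, sd = sdr))),
            nrow = counts[r]
          )
          ca <- affinity_rows(clones, ag)
          if (max(ca) > pa) {
            try_replace(cl, sel[r], clones[which.max(ca), ])
          }
        }
        if (d_replace > 0) {
          # refresh the worst antibodies that are not the elite of any antigen
          A <- aff_mat[[cl]]
          elites <- unique(apply(A, 2, which.max))
          eligible <- setdiff(order(A[, ag_pos], seq_len(N)), elites)
          for (row in head(eligible, d_replace)) {
            fresh <- runif(k)
            pools[[cl]][row, ] <- fresh
            aff_mat[[cl]][row, ] <-
              affinity_rows(m$X[ag_rows[[cl]], , drop = FALSE], fresh)
          }
        }
        best_aff[g, i] <- max(aff_mat[[cl]][, ag_pos])
      }
      pool_trace[[g]] <- vapply(pools, nrow, integer(1))
    }
  })

  structure(
    list(
      pools = pools,
      classes = classes,
      descriptors = m$descriptors,
      pool_size_trace = do.call(rbind, pool_trace),
      best_affinity_trace = best_aff,
      config = list(
        N = N, n_select = n_select, beta = beta, d_replace = d_replace,
        generations = generations, mutation_sd = mutation_sd, seed = seed
      )
    ),
    class = c("qw_clonalg", "qw_model")
  )
}

#' @describeIn clonalg Predict classes (or the per-class maximal-affinity
#'   matrix with `type = "score"`).
#' @param object A fitted `qw_clonalg` model.
#' @param newdata A descriptor tibble, matrix, or single vector.
#' @param type `"class"` or `"score"`.
#' @param ... Unused.
#' @export
predict.qw_clonalg <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- query_matrix(newdata, object$descriptors)
  classes <- object$classes
  scores <- matrix(NA_real_, nrow(X), length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(nrow(X))) {
    scores[i, ] <- vapply(classes, function(cl) {
      max(affinity_rows(object$pools[[cl]], X[i, ]))
    }, numeric(1))
  }
  if (type == "score") return(scores)
  # ties break to the lowest class index in short < medium < long order
  ord <- match(classes, QW_CLASSES)
  pred <- apply(scores[, order(ord), drop = FALSE], 1, function(s) {
    classes[order(ord)][which.max(s)]
  })
  qw_class_factor(pred)
}

#' @export
print.qw_clonalg <- function(x, ...) {
  cat(sprintf("<qw_clonalg> %d antibodies x %d classes over %d descriptors\n",
              x$config$N, length(x$classes), length(x$descriptors)))
  invisible(x)
}

#' @describeIn clonalg `tidy()` returns one row per antibody.
#' @param x A fitted `qw_clonalg` model.
#' @export
tidy.qw_clonalg <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    out <- as_tibble(x$pools[[cl]], .name_repair = ~ x$descriptors)
    dplyr::bind_cols(tibble(label = cl, antibody = seq_len(nrow(out))), out)
  })
}

#' @describeIn clonalg `glance()` returns a one-row fit summary.
#' @export
glance.qw_clonalg <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    pool_size = x$config$N,
    generations = x$config$generations,
    final_mean_best_affinity = mean(x$best_affinity_trace[x$config$generations, ]),
    seed = x$config$seed
  )
}
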