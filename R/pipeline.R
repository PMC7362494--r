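#' Default pipeline run configuration
#'
#' Builds (and validates against the component registry) the configuration
#' for an end-to-end [run_pipeline()] run.  Either `input` (a descriptor CSV
#' path) or `synthetic` (arguments for [generate_synthetic()]) must be
#' given.
#'
#' @param input Path to a labeled descriptor CSV, or `NULL`.
#' @param synthetic Named list of [generate_synthetic()] arguments, or
#'   `NULL`.
#' @param selector Selector registry name.
#' @param classifiers Character vector of classifier registry names.
#' @param k Descriptors kept by the selector.
#' @param cv_folds Folds for the comparison table.
#' @param test_fraction Hold-out fraction for the candidate ranking.
#' @param seed Integer master seed.
#' @param output_dir Directory the artifacts are written to.
#' @param selector_args,classifier_args Extra component arguments.
#' @return A validated `qw_run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       selector = "gwo",
                       classifiers = c("nb", "lr", "dt", "rf", "svm",
                                       "airs", "clonalg", "ins"),
                       k = 200, cv_folds = 3, test_fraction = 1 / 3,
                       seed = 1, output_dir = tempfile("qw_run_"),
                       selector_args = list(), classifier_args = list()) {
  if (is.null(input) && is.null(synthetic)) {
    abort("One of `input` or `synthetic` is required.")
  }
  registry_check("selector", selector)
  for (cl in classifiers) registry_check("classifier", cl)
  structure(
    list(
      input = input, synthetic = synthetic, selector = selector,
      classifiers = classifiers, k = k, cv_folds = cv_folds,
      test_fraction = test_fraction, seed = as.integer(seed),
      output_dir = output_dir,
      selector_args = selector_args, classifier_args = classifier_args
    ),
    class = "qw_run_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A validated `qw_run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the descriptor-selection / immune-classification pipeline end to end
#'
#' Executes the full modelling workflow: load (or synthesize) the labeled
#' descriptor table, min-max normalize it, hold out a stratified test set,
#' fit the descriptor selector on the training set, train every configured
#' classifier on the reduced training set, evaluate each on the reduced test
#' set, build the cross-validated comparison table, and rank the test
#' compounds as candidates by predicted-class confidence (for the
#' immune-network model, by the binding-energy margin between the two lowest
#' class energies).  All artifacts are CSV/JSON files under
#' `config$output_dir`; `manifest.json` records the configuration, package
#' version, seed, per-stage timings and the MD5 hash of every artifact, so a
#' run can be re-executed bit-identically from its manifest alone.
#'
#' Any stage failure aborts with the stage name and removes partial outputs.
#'
#' @param config A `qw_run_config` from [run_config()] or
#'   [read_run_config()].
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qw_run_config"))
  out_dir <- config$output_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  artifacts <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      if (created) unlink(out_dir, recursive = TRUE)
      abort(sprintf("Pipeline stage %s failed: %s",
                    sQuote(name), conditionMessage(e)),
            class = "qw_pipeline_error")
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(data, file) {
    path <- file.path(out_dir, file)
    readr::write_csv(data, path, progress = FALSE)
    artifacts <<- c(artifacts, file)
    path
  }

  data <- stage("load", {
    if (!is.null(config$input)) {
      read_descriptor_csv(config$input)
    } else {
      do.call(generate_synthetic,
              modifyList(config$synthetic, list(seed = config$seed)))
    }
  })
  norm <- stage("normalize", minmax_normalize(data))
  split <- stage("split", split_stratified(norm, config$test_fraction,
                                           seed = config$seed))
  d <- length(descriptor_cols(norm))

  sel_idx <- stage("select", fit_selector(
    config$selector, split$train, k = min(config$k, d),
    seed = qw_subseed(config$seed, 1L), args = config$selector_args
  ))
  stage("write_reduced", {
    emit(apply_selection(norm, sel_idx), "reduced.csv")
    emit(tibble(descriptor = descriptor_cols(norm)[sel_idx]), "selected_descriptors.csv")
  })

  evals <- stage("train_evaluate", {
    purrr::map(setNames(config$classifiers, config$classifiers), function(cl) {
      fit <- train_classifier(
        cl, apply_selection(split$train, sel_idx),
        seed = qw_subseed(config$seed, 10L + match(cl, config$classifiers)),
        args = config$classifier_args[[cl]] %||% list()
      )
      list(fit = fit,
           panel = evaluate_classifier(fit, apply_selection(split$test, sel_idx)))
    })
  })
  stage("write_holdout", {
    panel <- purrr::map_dfr(names(evals), function(cl) {
      dplyr::bind_cols(tibble(classifier = cl), evals[[cl]]$panel)
    })
    emit(panel, "holdout_metrics.csv")
  })

  comparison <- stage("compare", compare_algorithms(
    norm, selectors = unique(c("none", config$selector)),
    classifiers = config$classifiers, cv_folds = config$cv_folds,
    k = min(config$k, d), seed = config$seed,
    selector_args = setNames(list(config$selector_args), config$selector),
    classifier_args = config$classifier_args
  ))
  stage("write_comparison", emit(comparison, "comparison.csv"))

  candidates <- stage("rank_candidates", {
    test_red <- apply_selection(split$test, sel_idx)
    ranked <- purrr::map_dfr(names(evals), function(cl) {
      fit <- evals[[cl]]$fit
      pred <- predict(fit, test_red)
      conf <- if (inherits(fit, "qw_ins")) {
        energy_margin(fit, test_red)
      } else {
        scores <- tryCatch(predict(fit, test_red, type = "score"),
                           error = function(e) NULL)
        if (is.null(scores)) rep(NA_real_, nrow(test_red)) else
          apply(scores, 1, max)
      }
      tibble(
        classifier = cl,
        compound_id = test_red$compound_id,
        label = as.character(test_red$label),
        predicted = as.character(pred),
        confidence = conf
      )
    })
    dplyr::arrange(ranked, .data$classifier, dplyr::desc(.data$confidence))
  })
  stage("write_candidates", emit(candidates, "candidates.csv"))

  manifest <- list(
    package = "qsarwolf",
    version = as.character(utils::packageVersion("qsarwolf")),
    config = unclass(config),
    seed = config$seed,
    timings = timings,
    artifacts = as.list(tools::md5sum(file.path(out_dir, unique(artifacts)))) |>
      setNames(unique(artifacts))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
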