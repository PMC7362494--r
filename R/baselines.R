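# Adapters giving the delegated baseline classifiers (naive Bayes, logistic
# regression, decision tree, random forest, SVM) the same train/predict/score
# contract as the immune models.  The statistical engines are established
# implementations; only the Bayes posterior formula itself is in-package
# (bayes_posterior()).

#' Train a classifier by registry name
#'
#' Uniform entry point over all classifiers in the component registry:
#' the immune models (`airs`, `clonalg`, `ins`) and the delegated baselines
#' (`nb` naive Bayes, `lr` ridge-regularized multinomial logistic
#' regression, `dt` decision tree, `rf` random forest, `svm` support vector
#' machine).  Every fitted object supports `predict(fit, newdata)` for
#' labels and `predict(fit, newdata, type = "score")` for a per-class score
#' matrix.
#'
#' @param name Registry name of the classifier.
#' @param data A normalized descriptor tibble.
#' @param seed Integer RNG seed (used by the stochastic trainers).
#' @param args Named list of extra arguments for the underlying trainer.
#' @return A fitted model.
#' @export
train_classifier <- function(name, data, seed = 1, args = list()) {
  registry_check("classifier", name)
  data <- as_descriptor_table(data)
  switch(name,
    airs = do.call(airs, c(list(data = data, seed = seed), args)),
    clonalg = do.call(clonalg, c(list(data = data, seed = seed), args)),
    ins = do.call(ins, c(list(data = data), args)),
    fit_baseline(name, data, seed = seed, args = args)
  )
}

# Build and evaluate fn(<data args as symbols>, <extra args>) so that
# engines which deparse(substitute(...)) their arguments (naiveBayes, svm,
# randomForest) see short symbols, not a giant embedded matrix.
call_with_symbols <- function(fn, data_args, extra = list()) {
  e <- list2env(data_args, parent = parent.frame())
  syms <- setNames(lapply(names(data_args), as.symbol), names(data_args))
  eval(as.call(c(list(fn), syms, extra)), e)
}

fit_baseline <- function(name, data, seed = 1, args = list()) {
  m <- ds_matrix(data)
  y <- droplevels(m$y)
  model <- withr::with_seed(seed, switch(name,
    nb = call_with_symbols(e1071::naiveBayes, list(x = m$X, y = y), args),
    lr = {
      fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
      do.call(glmnet::glmnet,
              c(list(x = m$X, y = y, family = fam, alpha = 0), args))
    },
    dt = {
      df <- as.data.frame(m$X)
      df$.label <- y
      do.call(rpart::rpart,
              c(list(formula = .label ~ ., data = df, method = "class",
                     control = rpart::rpart.control(minsplit = 4)), args))
    },
    rf = call_with_symbols(randomForest::randomForest, list(x = m$X, y = y),
                           c(list(ntree = 200), args)),
    svm = call_with_symbols(e1071::svm, list(x = m$X, y = y),
                            c(list(probability = TRUE), args))
  ))
  structure(
    list(name = name, model = model, descriptors = m$descriptors,
         classes = levels(y), seed = seed),
    class = c("qw_baseline", "qw_model")
  )
}

# fixed ridge penalty at which the logistic baseline predicts
QW_LR_LAMBDA <- 0.05

#' @export
predict.qw_baseline <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- query_matrix(newdata, object$descriptors)
  model <- object$model
  scores <- switch(object$name,
    nb = predict(model, X, type = "raw"),
    lr = {
      p <- predict(model, X, s = QW_LR_LAMBDA, type = "response")
      if (length(dim(p)) == 3) {
        p[, , 1]
      } else {
        # binomial: column is P(second level)
        cbind(1 - p[, 1], p[, 1]) |>
          `colnames<-`(object$classes)
      }
    },
    dt = predict(model, as.data.frame(X), type = "prob"),
    rf = predict(model, X, type = "prob"),
    svm = {
      pr <- predict(model, X, probability = TRUE)
      attr(pr, "probabilities")
    }
  )
  scores <- matrix(as.numeric(scores), nrow = nrow(X),
                   dimnames = list(NULL, colnames(scores)))
  scores <- scores[, intersect(QW_CLASSES, colnames(scores)), drop = FALSE]
  if (type == "score") return(scores)
  qw_class_factor(colnames(scores)[max.col(scores, ties.method = "first")])
}

#' @export
print.qw_baseline <- function(x, ...) {
  cat(sprintf("<qw_baseline> %s over %d descriptors\n",
              x$name, length(x$descriptors)))
  invisible(x)
}
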