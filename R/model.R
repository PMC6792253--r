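#' Split cases into train and test sets, balancing reported positives
#'
#' Cases are walked in chronological order of analysis and assigned greedily
#' to whichever side currently holds fewer reported (positive) variants;
#' exact ties alternate sides. This yields near-equal positive totals per
#' side and near-equal proportions of early and late cases, so chronological
#' drift in annotation knowledge does not concentrate in one split.
#'
#' @param cases data.frame with columns `case_id`, `n_positives`, and
#'   `chron_order` (the analysis-order key).
#' @return Object of class `split_assignment`: `train_cases`, `test_cases`,
#'   `train_positives`, `test_positives`.
#' @export
split_cases <- function(cases) {
  if (!nrow(cases)) stop("empty cohort: no cases to split")
  cases <- cases[order(cases$chron_order), , drop = FALSE]
  train <- character(0); test <- character(0)
  pos_train <- 0L; pos_test <- 0L
  tie_to_train <- TRUE
  for (i in seq_len(nrow(cases))) {
    side_train <- if (pos_train < pos_test) TRUE
    else if (pos_train > pos_test) FALSE
    else { s <- tie_to_train; tie_to_train <- !tie_to_train; s }
    if (side_train) {
      train <- c(train, cases$case_id[i]); pos_train <- pos_train + cases$n_positives[i]
    } else {
      test <- c(test, cases$case_id[i]); pos_test <- pos_test + cases$n_positives[i]
    }
  }
  structure(list(train_cases = train, test_cases = test,
                 train_positives = pos_train, test_positives = pos_test),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split: %d train cases (%d positives) / %d test cases (%d positives)\n",
              length(x$train_cases), x$train_positives,
              length(x$test_cases), x$test_positives))
  invisible(x)
}

#' Classifier configuration
#'
#' Four imbalance-aware binary classifier families are supported:
#' \describe{
#'   \item{weighted_forest}{random forest with training rows weighted
#'     inversely to class frequency. Hyperparameters: `num_trees`,
#'     `max_depth` (0 = unlimited; the default caps depth at 4 — under
#'     severe class imbalance, fully grown trees memorize the re-sampled
#'     minority rows and the class weighting never reaches held-out
#'     predictions).}
#'   \item{weighted_logistic}{L2-penalized logistic regression with
#'     class-frequency weights. Hyperparameter: `reg_strength` (inverse
#'     regularization, larger = weaker penalty).}
#'   \item{balanced_forest}{random forest where each tree trains on a
#'     class-balanced bootstrap obtained by under-sampling the majority
#'     class. Hyperparameters: `num_trees`, `max_depth`.}
#'   \item{undersampled_boost_ensemble}{an ensemble of AdaBoost learners,
#'     each trained on a random under-sample that balances the classes.
#'     Hyperparameters: `n_members`, `n_rounds`, `max_depth`.}
#' }
#'
#' @param family One of the four family names.
#' @param hyperparameters Named list; unknown names are rejected.
#' @param seed Integer seed controlling all stochastic parts of the fit.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(family = c("weighted_forest", "weighted_logistic",
                                         "balanced_forest",
                                         "undersampled_boost_ensemble"),
                              hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  schema <- .grid_schema()[[family]]
  unknown <- setdiff(names(hyperparameters), names(schema))
  if (length(unknown)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", family,
                 paste(unknown, collapse = ", ")))
  }
  hp <- utils::modifyList(schema, hyperparameters)
  structure(list(family = family, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_config")
}

# per-family hyperparameter schema with defaults
.grid_schema <- function() {
  list(
    weighted_forest = list(num_trees = 200L, max_depth = 4L),
    weighted_logistic = list(reg_strength = 1),
    balanced_forest = list(num_trees = 200L, max_depth = 8L),
    undersampled_boost_ensemble = list(n_members = 10L, n_rounds = 20L,
                                       max_depth = 1L)
  )
}

#' Default hyperparameter grids
#'
#' The shipped lattice per family (also available as an editable YAML via
#' [read_grids()] on `system.file("extdata", "grids.yaml", package =
#' "varprior")`). `small = TRUE` collapses each grid to its single default
#' point, for quick end-to-end runs.
#'
#' @param small Return one-point grids.
#' @return Named list: family -> named list of hyperparameter value vectors.
#' @export
default_grids <- function(small = FALSE) {
  if (small) {
    return(list(
      weighted_forest = list(num_trees = 200L, max_depth = 4L),
      weighted_logistic = list(reg_strength = 1),
      balanced_forest = list(num_trees = 200L, max_depth = 8L),
      undersampled_boost_ensemble = list(n_members = 10L, n_rounds = 20L,
                                         max_depth = 1L)
    ))
  }
  list(
    weighted_forest = list(num_trees = c(100L, 200L, 500L),
                           max_depth = c(4L, 8L, 0L)),
    weighted_logistic = list(reg_strength = c(0.01, 0.1, 1, 10)),
    balanced_forest = list(num_trees = c(100L, 200L, 500L),
                           max_depth = c(4L, 8L, 0L)),
    undersampled_boost_ensemble = list(n_members = c(10L, 50L),
                                       n_rounds = c(20L, 50L),
                                       max_depth = c(1L, 2L))
  )
}

#' Read hyperparameter grids from YAML
#' @param path YAML file mapping family -> hyperparameter -> values.
#' @return Named list of grids.
#' @export
read_grids <- function(path) {
  g <- yaml::read_yaml(path)
  int_params <- c("num_trees", "max_depth", "n_members", "n_rounds")
  lapply(g, function(fam) {
    stats::setNames(lapply(names(fam), function(p) {
      v <- unlist(fam[[p]])
      if (p %in% int_params) as.integer(v) else as.numeric(v)
    }), names(fam))
  })
}

# ---- family fitting ---------------------------------------------------------

.class_weights <- function(y) {
  # inverse class frequency, normalized so weights average 1
  tab <- table(factor(y, levels = c(0, 1)))
  w <- length(y) / (2 * as.numeric(tab[as.character(y)]))
  w
}

.fit_family <- function(config, x, y) {
  hp <- config$hyperparameters
  seed <- config$seed
  df <- as.data.frame(x)
  colnames(df) <- .safe_names(colnames(x))
  switch(config$family,
    weighted_forest = ranger::ranger(
      x = df, y = factor(y, levels = c(0, 1)),
      probability = TRUE, num.trees = hp$num_trees,
      max.depth = hp$max_depth, case.weights = .class_weights(y),
      importance = "impurity",
      num.threads = 1L, seed = seed, respect.unordered.factors = TRUE),
    balanced_forest = {
      n1 <- sum(y == 1); n0 <- sum(y == 0)
      frac <- min(n1, n0) / length(y)
      ranger::ranger(
        x = df, y = factor(y, levels = c(0, 1)),
        probability = TRUE, num.trees = hp$num_trees,
        max.depth = hp$max_depth, replace = TRUE,
        sample.fraction = c(frac, frac), importance = "impurity",
        num.threads = 1L, seed = seed, respect.unordered.factors = TRUE)
    },
    weighted_logistic = {
      n <- length(y)
      lambda <- 1 / (hp$reg_strength * n)
      if (ncol(x) < 2L) {   # glmnet needs >= 2 columns; pad with a null one
        x <- cbind(x, `.null_pad` = 0)
      }
      glmnet::glmnet(x = x, y = factor(y, levels = c(0, 1)),
                     family = "binomial", alpha = 0,
                     weights = .class_weights(y),
                     lambda = lambda * c(64, 16, 4, 1),
                     standardize = TRUE)
    },
    undersampled_boost_ensemble =
      .fit_easy_ensemble(x, y, n_members = hp$n_members,
                         n_rounds = hp$n_rounds, max_depth = hp$max_depth,
                         seed = seed)
  )
}

.predict_family <- function(fit, config, x) {
  switch(config$family,
    weighted_forest = ,
    balanced_forest = {
      df <- as.data.frame(x)
      colnames(df) <- .safe_names(colnames(x))
      stats::predict(fit, data = df, num.threads = 1L)$predictions[, "1"]
    },
    weighted_logistic = {
      if (ncol(x) < nrow(fit$beta)) {
        pad <- matrix(0, nrow(x), nrow(fit$beta) - ncol(x))
        colnames(pad) <- setdiff(rownames(fit$beta), colnames(x))
        x <- cbind(x, pad)
      }
      lambda <- min(fit$lambda)
      as.numeric(stats::predict(fit, newx = x, s = lambda, type = "response"))
    },
    undersampled_boost_ensemble = .predict_easy_ensemble(fit, x)
  )
}

# ranger requires syntactic column names
.safe_names <- function(nm) make.names(nm, unique = TRUE)

# ---- cross-validation and tuning -------------------------------------------

# label-stratified k-fold assignment; returns integer fold per row
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  rng <- .substream_seed(seed, "cvfolds")
  old <- .set_local_seed(rng)
  on.exit(.restore_seed(old))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.balanced_accuracy <- function(y, pred) {
  sens <- mean(pred[y == 1] == 1)
  spec <- mean(pred[y == 0] == 0)
  (sens + spec) / 2
}

.f1_score <- function(y, pred) {
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# one CV evaluation of a config: per-fold balanced accuracy and F1 (positive
# class, 0.5 threshold)
.cv_evaluate <- function(config, x, y, k_folds, seed) {
  fold <- .stratified_folds(y, k_folds, seed)
  if (min(table(y[fold != 0], fold[fold != 0])["1", ]) < 1) {
    stop("a CV fold has no positives; need >= k positives for stratification")
  }
  ba <- numeric(k_folds); f1 <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    fit <- .fit_family(config, x[tr, , drop = FALSE], y[tr])
    p <- .predict_family(fit, config, x[!tr, , drop = FALSE])
    pred <- as.integer(p >= 0.5)
    ba[f] <- .balanced_accuracy(y[!tr], pred)
    f1[f] <- .f1_score(y[!tr], pred)
  }
  list(balanced_accuracy = ba, f1 = f1)
}

#' Tune one classifier family by stratified 10-fold cross-validation
#'
#' Evaluates every point of the hyperparameter lattice with label-stratified
#' k-fold CV on the training matrix, recording per-fold balanced accuracy
#' (inverse-class-frequency weighted accuracy) and F1 of the positive class
#' at the 0.5 probability threshold. The configuration with the best mean F1
#' wins — the appropriate tuning criterion under heavy class imbalance; ties
#' go to the earlier lattice point.
#'
#' @param family Classifier family name (see [classifier_config()]).
#' @param grid Named list: hyperparameter -> vector of candidate values.
#' @param fm Training `feature_matrix` (binary labels, >= 10 positives).
#' @param selection Optional `selection_result`; when given, only its
#'   selected columns are used.
#' @param k_folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment and the fits.
#' @return List with `best` (a `classifier_config`) and `records`, a
#'   data.frame of one tuning record per lattice point (mean and sd of both
#'   CV metrics, plus per-fold values in list columns).
#' @export
grid_search <- function(family, grid, fm, selection = NULL, k_folds = 10L,
                        seed = 1L) {
  if (!length(grid)) stop("empty hyperparameter grid")
  x <- fm$x
  if (!is.null(selection)) x <- x[, selection$selected, drop = FALSE]
  y <- fm$labels
  if (sum(y == 1) < k_folds) {
    stop(sprintf("need >= %d positives for stratified %d-fold CV", k_folds, k_folds))
  }
  lattice <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  records <- vector("list", nrow(lattice))
  for (i in seq_len(nrow(lattice))) {
    hp <- as.list(lattice[i, , drop = FALSE])
    cfg <- classifier_config(family, hyperparameters = hp, seed = seed)
    cv <- .cv_evaluate(cfg, x, y, k_folds, seed)
    records[[i]] <- data.frame(
      config_id = i,
      cv_balanced_accuracy_mean = mean(cv$balanced_accuracy),
      cv_balanced_accuracy_sd = stats::sd(cv$balanced_accuracy),
      cv_f1_mean = mean(cv$f1),
      cv_f1_sd = stats::sd(cv$f1)
    )
    records[[i]]$folds_balanced_accuracy <- list(cv$balanced_accuracy)
    records[[i]]$folds_f1 <- list(cv$f1)
    records[[i]]$hyperparameters <- list(hp)
  }
  records <- do.call(rbind, records)
  best_i <- which.max(records$cv_f1_mean)  # ties: first lattice point
  best <- classifier_config(family,
                            hyperparameters = records$hyperparameters[[best_i]],
                            seed = seed)
  list(best = best, records = records)
}

#' Fit the final model on the full training set
#'
#' Trains the configured family on the selected feature columns of every
#' training row, honoring the family's imbalance contract (class weighting
#' or balanced under-sampling). The returned model carries its selection and
#' a fingerprint of the training inputs, so reproducibility under the stored
#' seed can be audited.
#'
#' @param config A `classifier_config`.
#' @param selection A `selection_result` fitted on this training matrix.
#' @param fm The training `feature_matrix`.
#' @return Object of class `trained_model`.
#' @export
train_final <- function(config, selection, fm) {
  missing_cols <- setdiff(selection$selected, colnames(fm$x))
  if (length(missing_cols)) {
    stop(sprintf("training matrix lacks selected column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- fm$x[, selection$selected, drop = FALSE]
  y <- fm$labels
  fit <- .fit_family(config, x, y)
  structure(list(config = config, selection = selection, fit = fit,
                 fingerprint = .fingerprint(list(config, selection$selected,
                                                 dim(x), sum(x), sum(y)))),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %s on %d features (seed %d, fingerprint %s)\n",
              x$config$family, length(x$selection$selected), x$config$seed,
              x$fingerprint))
  invisible(x)
}

#' Predict per-variant reported-class probability
#'
#' @param model A `trained_model`.
#' @param fm A `feature_matrix` whose columns include the model's selected
#'   features.
#' @return Numeric vector in `[0, 1]`, one per row, input order preserved.
#' @export
predict_proba <- function(model, fm) {
  missing_cols <- setdiff(model$selection$selected, colnames(fm$x))
  if (length(missing_cols)) {
    stop(sprintf("matrix lacks selected column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- fm$x[, model$selection$selected, drop = FALSE]
  p <- .predict_family(model$fit, model$config, x)
  pmin(pmax(p, 0), 1)
}

# cheap deterministic fingerprint of structured inputs
.fingerprint <- function(obj) {
  raw <- serialize(obj, NULL, version = 2)
  sprintf("%08x-%06d", sum(as.numeric(raw) * seq_along(raw)) %% .Machine$integer.max,
          length(raw) %% 1000000L)
}
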