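# Discrete AdaBoost over shallow rpart trees, and the balanced
# under-sampling ensemble built from it. Each ensemble member trains one
# AdaBoost learner on a random under-sample in which the majority class is
# reduced to the minority count; member probabilities are averaged.

# fit one discrete AdaBoost learner (labels 0/1, depth-limited rpart stumps)
.fit_adaboost <- function(x, y, n_rounds, max_depth) {
  n <- length(y)
  ysign <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  colnames(df) <- .safe_names(colnames(x))
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2,
                               xval = 0, maxsurrogate = 0, maxcompete = 0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(stats::predict(fit, df, type = "class")))
    hsign <- ifelse(pred == 1, 1, -1)
    err <- sum(w[hsign != ysign])
    if (err >= 0.5) break                       # no better than chance: stop
    err <- max(err, 1e-10)                      # cap alpha for perfect fits
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ysign * hsign)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (!length(stumps)) {
    # degenerate training set: fall back to the base rate
    return(list(stumps = list(), alphas = numeric(0), base_rate = mean(y),
                cols = colnames(x)))
  }
  list(stumps = stumps, alphas = alphas, base_rate = mean(y), cols = colnames(x))
}

.predict_adaboost <- function(model, x) {
  if (!length(model$stumps)) return(rep(model$base_rate, nrow(x)))
  df <- as.data.frame(x)
  colnames(df) <- .safe_names(colnames(x))
  score <- numeric(nrow(x))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(
      stats::predict(model$stumps[[m]], df, type = "class")))
    score <- score + model$alphas[m] * ifelse(pred == 1, 1, -1)
  }
  1 / (1 + exp(-2 * score))   # logistic link on the additive margin
}

.fit_easy_ensemble <- function(x, y, n_members, n_rounds, max_depth, seed) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) stop("both classes required")
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  members <- .with_substream(seed, "easyensemble", {
    lapply(seq_len(n_members), function(m) {
      keep <- c(minority, sample(majority, length(minority)))
      .fit_adaboost(x[keep, , drop = FALSE], y[keep],
                    n_rounds = n_rounds, max_depth = max_depth)
    })
  })
  list(members = members)
}

.predict_easy_ensemble <- function(fit, x) {
  probs <- vapply(fit$members, .predict_adaboost, numeric(nrow(x)), x = x)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(x))
  rowMeans(probs)
}
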