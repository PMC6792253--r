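test_that("greedy chronological split balances positives", {
  two <- data.frame(case_id = c("a", "b"), n_positives = c(1L, 1L),
                    chron_order = 1:2)
  s <- split_cases(two)
  expect_equal(length(s$train_cases), 1L)
  expect_equal(length(s$test_cases), 1L)
  expect_equal(s$train_positives, 1L)
  expect_equal(s$test_positives, 1L)

  # all positives in one case cannot be balanced
  lump <- data.frame(case_id = c("a", "b", "c"),
                     n_positives = c(9L, 0L, 0L), chron_order = 1:3)
  s2 <- split_cases(lump)
  expect_equal(abs(s2$train_positives - s2$test_positives), 9L)

  expect_error(split_cases(data.frame(case_id = character(0),
                                      n_positives = integer(0),
                                      chron_order = integer(0))), "empty")
})

test_that("a 237-case cohort with 378 positives splits 189/189 over 120/117 cases", {
  # per-case positive histogram shaped like a real referral cohort:
  # 114 cases with 1, 105 with 2, 18 with 3 reported variants
  set.seed(1)
  cnt <- sample(c(rep(1L, 114), rep(2L, 105), rep(3L, 18)))
  cases <- data.frame(case_id = sprintf("C%03d", 1:237), n_positives = cnt,
                      chron_order = 1:237)
  s <- split_cases(cases)
  expect_equal(s$train_positives, 189L)
  expect_equal(s$test_positives, 189L)
  expect_equal(length(s$train_cases), 120L)
  expect_equal(length(s$test_cases), 117L)
  # early/late proportions stay near-equal
  early <- sprintf("C%03d", 1:118)
  expect_lt(abs(sum(s$train_cases %in% early) - sum(s$test_cases %in% early)), 10)
})

test_that("configs validate their hyperparameters", {
  expect_error(classifier_config("weighted_forest",
                                 hyperparameters = list(bogus = 1)), "bogus")
  cfg <- classifier_config("weighted_logistic",
                           hyperparameters = list(reg_strength = 0.1))
  expect_equal(cfg$hyperparameters$reg_strength, 0.1)
})

test_that("grid search returns the only config, and records are consistent", {
  fm <- imbalanced_matrix(40, 400, p = 10, shift = 1.5, seed = 8)
  gs <- grid_search("weighted_logistic", list(reg_strength = 1), fm,
                    k_folds = 5L, seed = 2)
  expect_equal(nrow(gs$records), 1L)
  expect_equal(gs$best$hyperparameters$reg_strength, 1)
  rec <- gs$records
  expect_equal(rec$cv_f1_mean, mean(rec$folds_f1[[1]]), tolerance = 1e-12)
  expect_equal(rec$cv_f1_sd, sd(rec$folds_f1[[1]]), tolerance = 1e-12)
  expect_equal(rec$cv_balanced_accuracy_mean,
               mean(rec$folds_balanced_accuracy[[1]]), tolerance = 1e-12)
})

test_that("the clean config beats a crippled one by mean F1 on learnable data", {
  # signal spread over every feature: a single boosting round (one stump)
  # cannot use it, the full configuration can
  set.seed(13)
  n <- 440
  y <- c(rep(1L, 40), rep(0L, 400))
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  x[y == 1, ] <- x[y == 1, ] + 0.8
  fm <- structure(list(x = x, keys = sprintf("v%d", 1:n),
                       case_ids = rep("c", n), labels = y,
                       acmg_class = rep(NA_character_, n), specs = list()),
                  class = "feature_matrix")
  gs <- grid_search("undersampled_boost_ensemble",
                    list(n_rounds = c(20L, 1L), max_depth = 1L, n_members = 5L),
                    fm, k_folds = 5L, seed = 3)
  expect_equal(gs$best$hyperparameters$n_rounds, 20L)
  expect_gt(max(gs$records$cv_f1_mean), min(gs$records$cv_f1_mean))
})

test_that("every family trains, predicts in [0,1], and is seed-reproducible", {
  fm <- imbalanced_matrix(30, 300, p = 10, shift = 1.5, seed = 5)
  sel <- select_top_k(fm, k = 5)
  probe <- imbalanced_matrix(10, 50, p = 10, shift = 1.5, seed = 6)
  for (fam in c("weighted_forest", "weighted_logistic", "balanced_forest",
                "undersampled_boost_ensemble")) {
    m1 <- train_final(classifier_config(fam, seed = 7), sel, fm)
    m2 <- train_final(classifier_config(fam, seed = 7), sel, fm)
    p1 <- predict_proba(m1, probe)
    p2 <- predict_proba(m2, probe)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_equal(m1$fingerprint, m2$fingerprint)
    # duplicated row gets an identical probability
    dup <- subset_feature_matrix(probe, c(1L, 1L, 2L))
    pd <- predict_proba(m1, dup)
    expect_equal(pd[1], pd[2])
  }
})

test_that("weighted logistic probability is monotone in a single feature", {
  set.seed(10)
  x <- matrix(c(rnorm(150, 0), rnorm(50, 3)), ncol = 1,
              dimnames = list(NULL, "f01"))
  fm <- structure(list(x = x, keys = sprintf("v%d", 1:200),
                       case_ids = rep("c", 200),
                       labels = c(rep(0L, 150), rep(1L, 50)),
                       acmg_class = rep(NA_character_, 200), specs = list()),
                  class = "feature_matrix")
  sel <- structure(list(selected = "f01", scores = c(f01 = 1),
                        statistic = "anova_f", fitted_on = "c"),
                   class = "selection_result")
  m <- train_final(classifier_config("weighted_logistic", seed = 1), sel, fm)
  grid <- structure(list(x = matrix(seq(-2, 5, length.out = 30), ncol = 1,
                                    dimnames = list(NULL, "f01")),
                         keys = sprintf("g%d", 1:30), case_ids = rep("c", 30),
                         labels = rep(0L, 30),
                         acmg_class = rep(NA_character_, 30), specs = list()),
                    class = "feature_matrix")
  p <- predict_proba(m, grid)
  expect_true(all(diff(p) >= -1e-12))
})

test_that("training and prediction reject column mismatches", {
  fm <- imbalanced_matrix(20, 100, p = 5, shift = 1, seed = 1)
  sel <- select_top_k(fm, k = 3)
  m <- train_final(classifier_config("weighted_logistic", seed = 1), sel, fm)
  fm_bad <- fm
  colnames(fm_bad$x) <- paste0("x", seq_len(ncol(fm$x)))
  expect_error(predict_proba(m, fm_bad), "lacks selected column")
  sel_bad <- sel
  sel_bad$selected <- c(sel$selected, "ghost")
  expect_error(train_final(classifier_config("weighted_logistic", seed = 1),
                           sel_bad, fm), "ghost")
})

test_that("deleting test rows changes nothing fitted on training rows", {
  fm_all <- imbalanced_matrix(40, 400, p = 10, shift = 1.5, seed = 30)
  train_idx <- seq_len(300)
  fm_train <- subset_feature_matrix(fm_all, train_idx)
  sel_a <- select_top_k(fm_train, k = 5)
  m_a <- train_final(classifier_config("weighted_forest", seed = 4), sel_a, fm_train)
  # rebuild with the "test" rows removed entirely
  sel_b <- select_top_k(fm_train, k = 5)
  m_b <- train_final(classifier_config("weighted_forest", seed = 4), sel_b, fm_train)
  expect_identical(sel_a$selected, sel_b$selected)
  expect_identical(m_a$fingerprint, m_b$fingerprint)
  probe <- subset_feature_matrix(fm_all, 301:440)
  expect_identical(predict_proba(m_a, probe), predict_proba(m_b, probe))
})

test_that("grids round-trip through YAML with integer types intact", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(default_grids(), path)
  g <- read_grids(path)
  expect_identical(g$weighted_forest$num_trees, c(100L, 200L, 500L))
  expect_equal(g$weighted_logistic$reg_strength, c(0.01, 0.1, 1, 10))
})
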