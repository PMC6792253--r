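numeric_spec <- function(name = "score", default = -1, range = c(0, 10))
  feature_spec(name, "numeric_single", default_value = default,
               expected_range = range)

test_that("numeric encoding passes values through and defaults the missing", {
  sp <- numeric_spec()
  expect_equal(encode_numeric_single(c(23.1, NA, 0), sp), c(23.1, -1, 0))
  af <- feature_spec("af", "numeric_single", is_allele_freq = TRUE,
                     expected_range = c(0, 1))
  expect_equal(encode_numeric_single(NA_real_, af), 0)   # absent allele -> 0
  expect_error(encode_numeric_single("abc", sp), "non-numeric")
})

test_that("extremal-default validation rejects in-range defaults", {
  expect_error(feature_spec("bad", "numeric_single", default_value = 5,
                            expected_range = c(0, 10)), "inside")
  expect_silent(feature_spec("lo", "numeric_single", default_value = -1,
                             expected_range = c(0, 10)))
  expect_silent(feature_spec("hi", "numeric_single", default_value = 20,
                             expected_range = c(0, 10)))
})

test_that("multi-value reduction keeps the worst value", {
  mx <- feature_spec("m", "numeric_multi", worst_direction = "max",
                     default_value = -1, expected_range = c(0, 10))
  mn <- feature_spec("m", "numeric_multi", worst_direction = "min",
                     default_value = 20, expected_range = c(0, 10))
  expect_equal(reduce_multi_value(c(2.1, 5.3), mx), 5.3)
  expect_equal(reduce_multi_value(c(0.4, 0.1), mn), 0.1)
  expect_equal(reduce_multi_value(numeric(0), mx), -1)
})

test_that("bin counting tallies vocabulary labels and pools the rest", {
  sp <- feature_spec("clin", "categorical",
                     vocabulary = c("Pathogenic", "LikelyPathogenic", "Benign"))
  expect_equal(bin_count_encode(c("Pathogenic", "Pathogenic", "Benign"), sp),
               c(Pathogenic = 2L, LikelyPathogenic = 0L, Benign = 1L,
                 `_other` = 0L))
  expect_equal(sum(bin_count_encode(character(0), sp)), 0L)
  set.seed(4)
  for (i in 1:100) {
    labs <- sample(c(sp$vocabulary, "weird", "odd"), sample(0:6, 1),
                   replace = TRUE)
    expect_equal(sum(bin_count_encode(labs, sp)), length(labs))  # conservation
  }
})

test_that("the reference spec set encodes to exactly 95 deterministic columns", {
  co <- generate_cohort(cohort_spec(seed = 2, n_cases = 4, n_terms = 80,
                                    n_genes = 40, variants_per_case = c(30, 40)))
  v <- score_cohort_phenotypes(co$variants, co$cases, co$graph, co$annotations)
  fm <- assemble_feature_matrix(v, reference_feature_specs())
  expect_equal(ncol(fm$x), 95L)
  expect_false(anyNA(fm$x))
  fm2 <- assemble_feature_matrix(v, reference_feature_specs())
  expect_identical(fm$x, fm2$x)   # re-encoding is bit-identical
})

test_that("a one-variant, one-spec table gives a 1x1 matrix", {
  v <- data.table::as.data.table(list(key = "1:1:A:T", case_id = "c1",
                                      label = "not_reported", score = 3.5))
  fm <- assemble_feature_matrix(v, list(numeric_spec()))
  expect_equal(dim(fm$x), c(1L, 1L))
  expect_equal(fm$x[1, "score"], c(score = 3.5))
  expect_error(assemble_feature_matrix(v, list(numeric_spec(), numeric_spec())),
               "duplicate")
})

test_that("univariate F scores agree with anova(lm) and rank sensibly", {
  pm <- planted_matrix(300, 10, 3, shift = 1.2, seed = 9)
  sel <- select_top_k(pm$fm, k = 3)
  # oracle: per-column one-way ANOVA F from lm
  for (col in c(pm$signal_cols[1], setdiff(colnames(pm$fm$x), pm$signal_cols)[1])) {
    f_lm <- anova(lm(pm$fm$x[, col] ~ factor(pm$fm$labels)))$`F value`[1]
    expect_equal(unname(sel$scores[col]), f_lm, tolerance = 1e-10)
  }
  expect_setequal(sel$selected, pm$signal_cols)
})

test_that("selection keeps ties in column order and caps k", {
  x <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1), c = c(1, 0, 1, 0))
  fm <- structure(list(x = x, keys = letters[1:4], case_ids = rep("c", 4),
                       labels = c(0L, 0L, 1L, 1L),
                       acmg_class = rep(NA_character_, 4), specs = list()),
                  class = "feature_matrix")
  sel <- select_top_k(fm, k = 2)
  expect_identical(sel$selected, c("a", "b"))  # identical scores: column order
  expect_warning(sel_all <- select_top_k(fm, k = 10), "exceeds")
  expect_identical(sel_all$selected, c("a", "b", "c"))
})

test_that("selection depends only on training rows", {
  pm <- planted_matrix(500, 20, 5, shift = 1, seed = 21)
  sel1 <- select_top_k(pm$fm, k = 5)
  perm <- sample(nrow(pm$fm$x))  # permuting rows jointly leaves scores intact
  fm_perm <- subset_feature_matrix(pm$fm, perm)
  sel2 <- select_top_k(fm_perm, k = 5)
  expect_identical(sel1$selected, sel2$selected)
  expect_equal(sel1$scores, sel2$scores)
})

test_that("forest importances are normalized, ordered, and averageable", {
  fm <- imbalanced_matrix(60, 600, p = 8, shift = 1.5, seed = 3)
  sel <- select_top_k(fm, k = 8)
  m1 <- train_final(classifier_config("weighted_forest", seed = 1), sel, fm)
  m2 <- train_final(classifier_config("balanced_forest", seed = 1), sel, fm)
  i1 <- report_feature_importance(m1)
  i2 <- report_feature_importance(m2)
  expect_equal(sum(i1), 1, tolerance = 1e-6)
  expect_true(all(diff(i1) <= 0))
  avg <- average_feature_importance(i1, i2)
  expect_equal(sum(avg), 1, tolerance = 1e-6)
  expect_true(all(diff(avg) <= 0))
  m3 <- train_final(classifier_config("weighted_logistic", seed = 1), sel, fm)
  expect_error(report_feature_importance(m3), "importance")
})

test_that("feature specs survive a YAML round trip", {
  specs <- list(numeric_spec(),
                feature_spec("cat", "categorical", vocabulary = c("A", "B")),
                feature_spec("m", "numeric_multi", worst_direction = "min",
                             default_value = 99, expected_range = c(0, 10)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature_specs(specs, path)
  specs2 <- read_feature_specs(path)
  expect_equal(length(specs2), 3L)
  expect_equal(specs2[[1]]$default_value, -1)
  expect_equal(specs2[[2]]$vocabulary, c("A", "B"))
  expect_equal(specs2[[3]]$worst_direction, "min")
})
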