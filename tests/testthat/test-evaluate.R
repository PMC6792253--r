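test_that("case ranking sorts by probability with deterministic tie-breaks", {
  p <- c(a = 0.9, b = 0.5, c = 0.1)
  r <- rank_case(p)
  expect_identical(r$keys, c("a", "b", "c"))
  expect_equal(unname(r$ranks), 1:3)

  tied <- c(z = 0.5, a = 0.5, m = 0.5)
  rt <- rank_case(tied)
  expect_identical(rt$keys, c("a", "m", "z"))   # key order under ties

  perm <- rank_case(p[c(3, 1, 2)])
  expect_identical(perm$ranks, r$ranks)          # input order is irrelevant

  rp <- rank_case(tied, ties = "pessimistic")
  expect_equal(unname(rp$ranks), c(3L, 3L, 3L))
})

test_that("rank summaries match direct arithmetic", {
  mk_ranking <- function(case, n, rep_key, rep_rank, cls) {
    p <- stats::setNames(seq(1, 0.01, length.out = n), sprintf("%s_v%02d", case, 1:n))
    names(p)[rep_rank] <- rep_key
    rank_case(p, reported = rep_key,
              acmg = stats::setNames(cls, rep_key), case_id = case)
  }
  rks <- list(mk_ranking("c1", 30, "r1", 1, "Path"),
              mk_ranking("c2", 30, "r2", 10, "LP"),
              mk_ranking("c3", 30, "r3", 25, "VUS"))
  m <- rank_metrics(rks)
  all_row <- m[m$stratum == "All", ]
  expect_equal(all_row$n, 3L)
  expect_equal(all_row$median_rank, 10)
  expect_equal(all_row$mean_rank, 12)
  expect_equal(all_row$top1, 100 / 3, tolerance = 1e-10)
  expect_equal(all_row$top10, 200 / 3, tolerance = 1e-10)
  expect_equal(all_row$top20, 200 / 3, tolerance = 1e-10)
  # strata partition the reported set
  expect_equal(sum(m$n[m$stratum != "All"]), all_row$n)
  # all-at-rank-1 degenerate case
  ones <- lapply(1:3, function(i) mk_ranking(sprintf("d%d", i), 10, "r", 1, "Path"))
  m1 <- rank_metrics(ones)
  expect_equal(m1[m1$stratum == "All", c("median_rank", "mean_rank",
                                         "top1", "top10", "top20")],
               data.frame(median_rank = 1, mean_rank = 1, top1 = 100,
                          top10 = 100, top20 = 100),
               ignore_attr = TRUE)
})

test_that("top-X percentages are monotone in X", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    p <- stats::setNames(runif(n), sprintf("v%02d", 1:n))
    rep_keys <- sample(names(p), sample(1:3, 1))
    r <- rank_case(p, reported = rep_keys,
                   acmg = stats::setNames(sample(c("VUS", "LP", "Path"),
                                                 length(rep_keys), TRUE),
                                          rep_keys))
    m <- rank_metrics(list(r))
    a <- m[m$stratum == "All", ]
    expect_lte(a$top1, a$top10)
    expect_lte(a$top10, a$top20)
  }
})

test_that("curves hit exact values on canonical inputs", {
  perfect <- curves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$auprc, 1)
  inverted <- curves(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(inverted$auroc, 0)
  mixed <- curves(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(mixed$auroc, 0.75)   # 3 of 4 positive-negative pairs concordant
  expect_error(curves(c(0.1, 0.2), c(1, 1)), "both classes")
  # ROC endpoints
  expect_equal(mixed$roc$fpr[1], 0)
  expect_equal(mixed$roc$tpr[1], 0)
  expect_equal(mixed$roc$fpr[nrow(mixed$roc)], 1)
  expect_equal(mixed$roc$tpr[nrow(mixed$roc)], 1)
})

test_that("AUROC equals pairwise concordance on random small inputs", {
  concordance <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(17)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2)   # rounding forces ties
    expect_equal(curves(s, y)$auroc, concordance(s, y), tolerance = 1e-12)
  }
})

test_that("curve areas agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- rbinom(300, 1, 0.2)
  y[1:2] <- c(0, 1)
  s <- rnorm(300) + y
  cs <- curves(s, y)
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
  expect_equal(cs$auroc, auc_ref, tolerance = 1e-10)
})

test_that("baseline rankers are definitionally single-column rankings", {
  fm <- imbalanced_matrix(6, 60, p = 4, shift = 1, seed = 41)
  fm$case_ids <- rep(sprintf("case%d", 1:6), length.out = 66)
  fm$acmg_class[fm$labels == 1] <- "VUS"
  rks <- baseline_rankers(fm, "f01")
  by_hand <- rank_cases_by_score(fm, fm$x[, "f01"])
  expect_equal(rks, by_hand)
  expect_error(baseline_rankers(fm, "nope"), "absent")
  # constant column: pure key-order tie-break, ranks still 1..n
  fm$x[, "f02"] <- 1
  rc <- baseline_rankers(fm, "f02")[[1]]
  expect_equal(unname(rc$ranks), seq_along(rc$keys))
  expect_identical(rc$keys, sort(rc$keys))
})

test_that("raising a reported variant's score never worsens summaries", {
  set.seed(31)
  p <- stats::setNames(runif(20), sprintf("v%02d", 1:20))
  rep_key <- "v07"
  acmg <- stats::setNames("LP", rep_key)
  before <- rank_metrics(list(rank_case(p, rep_key, acmg)))
  p2 <- p
  p2[rep_key] <- p2[rep_key] + 0.5
  after <- rank_metrics(list(rank_case(p2, rep_key, acmg)))
  a <- before[before$stratum == "All", ]; b <- after[after$stratum == "All", ]
  expect_lte(b$median_rank, a$median_rank)
  expect_lte(b$mean_rank, a$mean_rank)
  expect_gte(b$top1, a$top1)
  expect_gte(b$top10, a$top10)
  expect_gte(b$top20, a$top20)
})

test_that("unscored variants fill in conservatively after the scored ones", {
  keys <- sprintf("v%d", 1:5)
  expect_equal(conservative_unranked_fill(c("v3", "v1", "v5"), keys),
               c("v3", "v1", "v5", "v2", "v4"))
  expect_equal(conservative_unranked_fill(keys, keys), keys)
  expect_equal(conservative_unranked_fill(character(0), keys), sort(keys))
})
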