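test_that("term vectors set exactly the closed bits", {
  g <- parse_obo(chain_obo())
  v <- build_term_vector(g, "C")
  expect_identical(v$dims, c("B", "C"))
  expect_equal(v$bits, c(1, 1))
  expect_equal(build_term_vector(g, character(0))$bits, c(0, 0))

  d <- parse_obo(diamond_obo())
  vd <- build_term_vector(d, "D")
  expect_equal(stats::setNames(vd$bits, vd$dims),
               c(B = 1, C = 1, D = 1))

  # all non-root terms -> all-ones
  va <- build_term_vector(g, setdiff(g$terms, g$roots))
  expect_true(all(va$bits == 1))
})

test_that("cosine has the right identities and matches direct evaluation", {
  g <- parse_obo(random_obo(12, 7, p_second_parent = 0))
  dims <- setdiff(g$terms, g$roots)
  mk <- function(bits) structure(list(dims = dims, bits = bits),
                                 class = "phenotype_vector")
  u <- mk(as.numeric(seq_along(dims) <= 3))
  expect_equal(cosine_score(u, u), 1, tolerance = 1e-12)
  v_disjoint <- mk(as.numeric(seq_along(dims) > 3))
  expect_equal(cosine_score(u, v_disjoint), 0)
  # |u|^2 = 3, |v|^2 = 2, overlap 2 -> 2/sqrt(6)
  v <- mk(as.numeric(seq_along(dims) %in% c(2, 3)))
  expect_equal(cosine_score(u, v), 2 / sqrt(6), tolerance = 1e-12)
  expect_equal(cosine_score(u, v), cosine_score(v, u))
  expect_equal(cosine_score(mk(rep(0, length(dims))), u), 0)
  expect_error(cosine_score(u, build_term_vector(parse_obo(chain_obo()), "C")),
               "dimension")
})

test_that("shared terms never decrease cosine on enumerated small vectors", {
  dims <- sprintf("d%d", 1:6)
  mk <- function(bits) structure(list(dims = dims, bits = bits),
                                 class = "phenotype_vector")
  set.seed(2)
  for (i in 1:50) {
    u <- rbinom(6, 1, 0.5); v <- rbinom(6, 1, 0.5)
    free <- which(u == 0 & v == 0)
    if (!length(free)) next
    j <- free[1]
    u2 <- u; v2 <- v; u2[j] <- 1; v2[j] <- 1
    expect_gte(cosine_score(mk(u2), mk(v2)) + 1e-12,
               cosine_score(mk(u), mk(v)))
  }
})

test_that("gene cosine scores match a brute-force closure + dot-product oracle", {
  obo <- random_obo(40, 11)
  g <- parse_obo(obo)
  non_root <- setdiff(g$terms, g$roots)
  set.seed(11)
  ann <- structure(lapply(1:10, function(i) sample(non_root, sample(2:5, 1))),
                   class = "gene_annotation_map")
  names(ann) <- sprintf("G%02d", 1:10)
  patient <- sample(non_root, 4)
  tab <- score_genes_cosine(g, ann, patient)

  pc <- oracle_closure(obo, patient)
  for (gene in names(ann)) {
    gc <- oracle_closure(obo, ann[[gene]])
    expected <- length(intersect(pc, gc)) / sqrt(length(pc) * length(gc))
    expect_equal(unname(tab$scores[gene]), expected, tolerance = 1e-12)
  }

  # a gene annotated with exactly the patient's terms is the argmax at 1
  ann$Gexact <- patient
  tab2 <- score_genes_cosine(g, ann, patient)
  expect_equal(unname(tab2$scores["Gexact"]), 1, tolerance = 1e-12)
  expect_equal(names(which.max(tab2$scores)), "Gexact")
})

test_that("the walk transition matrix is column-stochastic", {
  g <- parse_obo(random_obo(50, 3))
  non_root <- setdiff(g$terms, g$roots)
  set.seed(3)
  ann <- structure(lapply(1:15, function(i) sample(non_root, 3)),
                   class = "gene_annotation_map")
  names(ann) <- sprintf("G%02d", 1:15)
  rwr <- build_rwr_graph(g, ann)
  expect_equal(max(abs(Matrix::colSums(rwr$W) - 1)), 0, tolerance = 1e-12)

  # 1 term + 1 gene: two nodes, columns sum to 1
  g1 <- parse_obo(c("[Term]", "id: A", ""))
  rwr1 <- build_rwr_graph(g1, structure(list(G1 = "A"),
                                        class = "gene_annotation_map"))
  expect_equal(dim(rwr1$W), c(2L, 2L))
  expect_equal(as.numeric(Matrix::colSums(rwr1$W)), c(1, 1))

  # unit-weight node of degree 3 spreads mass 1/3 each
  gd <- parse_obo(c("[Term]", "id: R", "",
                    "[Term]", "id: X", "is_a: R", "",
                    "[Term]", "id: Y", "is_a: R", ""))
  rwrd <- build_rwr_graph(gd, structure(list(G1 = "R"),
                                        class = "gene_annotation_map"))
  expect_equal(as.numeric(rwrd$W[, "R"]),
               c(0, 1/3, 1/3, 1/3))
})

test_that("walk scores: degenerate restart, symmetry, and conservation", {
  # r = 1 returns the restart vector: all gene mass 0
  g <- parse_obo(diamond_obo())
  ann <- structure(list(G1 = "B", G2 = "C"), class = "gene_annotation_map")
  cfg1 <- rwr_config(restart_prob = 1)
  tab <- rwr_scores(build_rwr_graph(g, ann, cfg1), "D", cfg1)
  expect_equal(unname(tab$scores), c(0, 0))

  # mirror-image genes under a symmetric ontology get equal scores
  cfg <- rwr_config()
  tab2 <- rwr_scores(build_rwr_graph(g, ann, cfg), "A", cfg)
  expect_equal(unname(tab2$scores["G1"]), unname(tab2$scores["G2"]),
               tolerance = 1e-10)
  expect_equal(sum(tab2$stationary), 1, tolerance = 1e-10)
})

test_that("iterative walk matches the closed-form linear solve", {
  cfg <- rwr_config(restart_prob = 0.25, tol = 1e-14, max_iter = 5000)
  for (seed in 1:10) {
    g <- parse_obo(random_obo(sample(10:30, 1), seed))
    non_root <- setdiff(g$terms, g$roots)
    set.seed(seed)
    ann <- structure(lapply(1:5, function(i)
      sample(non_root, min(3, length(non_root)))),
      class = "gene_annotation_map")
    names(ann) <- sprintf("G%d", 1:5)
    rwr <- build_rwr_graph(g, ann, cfg)
    patient <- sample(non_root, 2)
    tab <- rwr_scores(rwr, patient, cfg)

    restart <- intersect(ancestor_closure(g, patient), rwr$nodes)
    p0 <- numeric(length(rwr$nodes))
    p0[match(restart, rwr$nodes)] <- 1 / length(restart)
    W <- as.matrix(rwr$W)
    closed <- cfg$restart_prob *
      solve(diag(length(p0)) - (1 - cfg$restart_prob) * W, p0)
    expect_equal(tab$stationary, unname(closed), tolerance = 1e-8)
    expect_equal(sum(tab$stationary), 1, tolerance = 1e-10)
  }
})

test_that("variants inherit the best score of their genes", {
  tab <- structure(list(method = "cosine",
                        scores = c(G1 = 0.3, G2 = 0.7)),
                   class = "gene_score_table")
  expect_equal(best_gene_score_per_variant(c("G1", "G2"), tab), 0.7)
  expect_equal(best_gene_score_per_variant("G1", tab), 0.3)
  expect_equal(best_gene_score_per_variant(c("GX", "GY"), tab), 0)
  expect_equal(best_gene_score_per_variant(character(0), tab), 0)
})
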