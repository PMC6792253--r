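#' Build a binary phenotype vector over the ontology dimensions
#'
#' A patient (or gene) is represented as a binary vector with one dimension
#' per non-root ontology term; the bits set are exactly the ancestor closure
#' of the given term set. Patient and gene vectors built over the same graph
#' share the same dimension ordering and are therefore directly comparable.
#'
#' @param graph An `ontology_graph`.
#' @param terms Character vector of term IDs (may be empty: all-zero vector).
#' @return Object of class `phenotype_vector`: list with `dims` (ordered
#'   non-root term IDs, length P) and `bits` (0/1 numeric vector).
#' @export
build_term_vector <- function(graph, terms) {
  dims <- setdiff(graph$terms, graph$roots)
  closed <- if (length(terms)) ancestor_closure(graph, terms) else character(0)
  structure(list(dims = dims, bits = as.numeric(dims %in% closed)),
            class = "phenotype_vector")
}

#' Cosine similarity between two binary phenotype vectors
#'
#' Returns the cosine of the angle between the vectors, in `[0, 1]` for
#' binary vectors. An all-zero vector (no phenotype information) has, by
#' convention, similarity 0 with anything.
#'
#' @param u,v `phenotype_vector`s built over the same ontology.
#' @return Numeric scalar in `[0, 1]`.
#' @export
cosine_score <- function(u, v) {
  if (length(u$bits) != length(v$bits) || !identical(u$dims, v$dims)) {
    stop("phenotype vectors built over different ontologies (dimension mismatch)")
  }
  nu <- sqrt(sum(u$bits^2))
  nv <- sqrt(sum(v$bits^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u$bits * v$bits) / (nu * nv)
}

# sparse P x G matrix of closed gene vectors, plus column norms
.gene_vector_matrix <- function(graph, annotations) {
  dims <- setdiff(graph$terms, graph$roots)
  genes <- names(annotations)
  closed <- lapply(annotations, function(tt) ancestor_closure(graph, tt))
  i <- match(unlist(closed, use.names = FALSE), dims)
  j <- rep(seq_along(genes), lengths(closed))
  keep <- !is.na(i)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(length(dims), length(genes)),
                            dimnames = list(dims, genes))
  m
}

#' Score every annotated gene against a patient's phenotypes by cosine
#'
#' Builds the patient's closed binary vector and each gene's closed binary
#' vector over the same ontology, and returns the cosine similarity per gene.
#' Genes with no annotations do not appear.
#'
#' @param graph An `ontology_graph`.
#' @param annotations A `gene_annotation_map`.
#' @param patient_terms Character vector of the patient's term IDs.
#' @return Object of class `gene_score_table`: list with `method = "cosine"`
#'   and `scores`, a named numeric vector (gene -> score in `[0, 1]`).
#' @export
score_genes_cosine <- function(graph, annotations, patient_terms) {
  gm <- .gene_vector_matrix(graph, annotations)
  pv <- build_term_vector(graph, patient_terms)
  p_norm <- sqrt(sum(pv$bits^2))
  g_norm <- sqrt(Matrix::colSums(gm^2))
  dots <- as.numeric(Matrix::crossprod(gm, pv$bits))
  denom <- p_norm * g_norm
  scores <- ifelse(denom > 0, dots / denom, 0)
  names(scores) <- colnames(gm)
  structure(list(method = "cosine", scores = scores), class = "gene_score_table")
}

#' Configuration for random walk with restart
#'
#' @param restart_prob Restart probability r in (0, 1]. Default 0.1.
#' @param tol Convergence tolerance on the L1 change per iteration.
#' @param max_iter Iteration cap.
#' @param gene_edge_weight Relative weight of gene-term annotation edges
#'   versus ontology is_a edges.
#' @param restart_on_closure If `TRUE` (default), restart mass is spread
#'   uniformly over the patient's ancestor-closed term set; if `FALSE`, only
#'   over the directly given terms.
#' @return A list of class `rwr_config`.
#' @export
rwr_config <- function(restart_prob = 0.1, tol = 1e-10, max_iter = 1000L,
                       gene_edge_weight = 1.0, restart_on_closure = TRUE) {
  stopifnot(restart_prob > 0, restart_prob <= 1, tol > 0, max_iter >= 1)
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_iter = as.integer(max_iter),
                 gene_edge_weight = gene_edge_weight,
                 restart_on_closure = restart_on_closure),
            class = "rwr_config")
}

#' Build the column-stochastic transition structure for the random walk
#'
#' Nodes are all ontology terms plus all annotated genes. Edges are
#' undirected: term-parent (weight 1) and gene-term (weight
#' `cfg$gene_edge_weight`). Each column of the returned transition matrix
#' sums to 1; an isolated node gets a self-loop.
#'
#' @param graph An `ontology_graph`.
#' @param annotations A `gene_annotation_map` (non-empty).
#' @param cfg An `rwr_config`.
#' @return Object of class `rwr_graph`: list with `W` (sparse
#'   column-stochastic matrix), `nodes`, `term_nodes`, `gene_nodes`.
#' @export
build_rwr_graph <- function(graph, annotations, cfg = rwr_config()) {
  if (!length(annotations)) stop("empty gene annotation map")
  terms <- graph$terms
  genes <- names(annotations)
  nodes <- c(terms, genes)
  n <- length(nodes)

  child <- rep(terms, lengths(graph$parents[terms]))
  parent <- unlist(graph$parents[terms], use.names = FALSE)
  g_from <- rep(genes, lengths(annotations))
  g_to <- unlist(annotations, use.names = FALSE)

  i <- c(match(child, nodes), match(parent, nodes),
         match(g_from, nodes), match(g_to, nodes))
  j <- c(match(parent, nodes), match(child, nodes),
         match(g_to, nodes), match(g_from, nodes))
  w <- c(rep(1, 2 * length(child)),
         rep(cfg$gene_edge_weight, 2 * length(g_from)))
  A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n),
                            dimnames = list(nodes, nodes))
  deg <- Matrix::colSums(A)
  iso <- which(deg == 0)
  if (length(iso)) {
    A <- A + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = c(n, n))
    deg <- Matrix::colSums(A)
  }
  W <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(W) <- list(nodes, nodes)
  structure(list(W = W, nodes = nodes, term_nodes = terms, gene_nodes = genes,
                 graph = graph),
            class = "rwr_graph")
}

#' Gene scores by random walk with restart from the patient's terms
#'
#' Iterates `p <- (1 - r) W p + r p0` until the L1 change drops below
#' `cfg$tol` or `cfg$max_iter` is reached, with restart vector `p0` uniform
#' over the patient's (closed) term nodes. The stationary mass restricted to
#' gene nodes is the score table; over all nodes the stationary vector sums
#' to 1.
#'
#' @param rwr An `rwr_graph` from [build_rwr_graph()].
#' @param patient_terms Non-empty character vector of patient term IDs.
#' @param cfg An `rwr_config`.
#' @return A `gene_score_table` with `method = "rwr"`; attribute
#'   `stationary` holds the full stationary vector over all nodes.
#' @export
rwr_scores <- function(rwr, patient_terms, cfg = rwr_config()) {
  if (!length(patient_terms)) stop("patient term set is empty")
  restart_terms <- if (cfg$restart_on_closure) {
    union(ancestor_closure(rwr$graph, patient_terms),
          intersect(patient_terms, rwr$graph$roots))
  } else {
    patient_terms
  }
  restart_terms <- intersect(restart_terms, rwr$term_nodes)
  if (!length(restart_terms)) stop("no patient terms present in the walk graph")
  n <- length(rwr$nodes)
  p0 <- numeric(n)
  p0[match(restart_terms, rwr$nodes)] <- 1 / length(restart_terms)
  r <- cfg$restart_prob
  p <- p0
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    p_new <- as.numeric((1 - r) * (rwr$W %*% p)) + r * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("random walk did not converge in %d iterations (L1 change %.3g); returning best iterate",
                    cfg$max_iter, delta))
  }
  scores <- p[match(rwr$gene_nodes, rwr$nodes)]
  names(scores) <- rwr$gene_nodes
  structure(list(method = "rwr", scores = scores, stationary = p),
            class = "gene_score_table")
}

#' Best gene score for a variant
#'
#' A variant overlapping several genes inherits the best (maximum) score
#' among them; genes absent from the score table contribute the method's
#' floor of 0, as does a variant with no gene links.
#'
#' @param variant_genes Character vector of gene symbols (possibly empty).
#' @param table A `gene_score_table`.
#' @return Numeric scalar.
#' @export
best_gene_score_per_variant <- function(variant_genes, table) {
  if (!length(variant_genes)) return(0)
  s <- table$scores[variant_genes]
  s[is.na(s)] <- 0
  max(s, 0)
}
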