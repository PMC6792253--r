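#' Parse an OBO-format ontology into a phenotype term graph
#'
#' Reads the flat-file OBO 1.2 dialect used by the Human Phenotype Ontology.
#' Only `[Term]` stanzas and their `id:`, `is_a:` and `is_obsolete:` lines are
#' interpreted; obsolete terms are dropped and `replaced_by` is not followed.
#' The result is a directed acyclic graph of terms linked by is_a edges, the
#' coordinate system for every phenotype vector in the package.
#'
#' @param path Path to an OBO file, or a character vector of its lines.
#' @return An object of class `ontology_graph` with elements
#'   \describe{
#'     \item{terms}{character vector of term IDs (non-obsolete).}
#'     \item{parents}{named list mapping each term to its direct is_a parents.}
#'     \item{roots}{term IDs with no parents (usually one).}
#'     \item{n_dims}{number of non-root terms: the dimensionality P of
#'       phenotype vectors built over this graph.}
#'   }
#' @details Multiple roots are permitted (P then excludes all of them). A
#'   cycle among is_a edges is a structural error; one offending cycle is
#'   reported.
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- trimws(lines)

  # stanza boundaries: lines like [Term], [Typedef], ...
  stanza_starts <- grep("^\\[.*\\]$", lines)
  if (length(stanza_starts) == 0L) {
    stop("no stanzas found: not an OBO file?")
  }
  stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))

  ids <- character(0)
  parent_list <- list()
  for (k in seq_along(stanza_starts)) {
    if (lines[stanza_starts[k]] != "[Term]") next
    body <- lines[seq(stanza_starts[k] + 1L, stanza_ends[k])]
    body <- body[nzchar(body)]
    id_lines <- grep("^id:", body, value = TRUE)
    if (length(id_lines) != 1L) {
      stop(sprintf("malformed [Term] stanza starting at line %d: expected exactly one id:, found %d",
                   stanza_starts[k], length(id_lines)))
    }
    id <- trimws(sub("^id:", "", id_lines))
    if (any(grepl("^is_obsolete:\\s*true", body))) next
    isa <- grep("^is_a:", body, value = TRUE)
    # strip trailing "! name" comments and optional qualifiers
    parents <- trimws(sub("!.*$", "", sub("^is_a:", "", isa)))
    parents <- sub("\\s.*$", "", parents)  # keep only the ID token
    ids <- c(ids, id)
    parent_list[[id]] <- unique(parents[nzchar(parents)])
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate term id: %s", ids[duplicated(ids)][1L]))
  }
  # drop parent links to terms not in the graph (e.g. obsolete targets)
  parent_list <- lapply(parent_list, function(p) p[p %in% ids])
  g <- structure(
    list(terms = ids, parents = parent_list,
         roots = ids[vapply(parent_list[ids], length, 1L) == 0L]),
    class = "ontology_graph"
  )
  g$n_dims <- length(g$terms) - length(g$roots)
  cyc <- .find_cycle(g)
  if (!is.null(cyc)) {
    stop(sprintf("is_a cycle detected: %s", paste(cyc, collapse = " -> ")))
  }
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d root(s), P = %d vector dims\n",
              length(x$terms), length(x$roots), x$n_dims))
  invisible(x)
}

# iterative DFS cycle check over parent edges; returns one cycle or NULL
.find_cycle <- function(graph) {
  color <- stats::setNames(rep(0L, length(graph$terms)), graph$terms)  # 0 white 1 grey 2 black
  for (start in graph$terms) {
    if (color[start] != 0L) next
    stack <- list(list(node = start, i = 0L))
    path <- character(0)
    while (length(stack)) {
      top <- stack[[length(stack)]]
      node <- top$node
      if (top$i == 0L) {
        color[node] <- 1L
        path <- c(path, node)
      }
      kids <- graph$parents[[node]]
      if (top$i < length(kids)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- kids[top$i + 1L]
        if (color[nxt] == 1L) {
          cycle <- c(path[which(path == nxt):length(path)], nxt)
          return(cycle)
        }
        if (color[nxt] == 0L) stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
      } else {
        color[node] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' Ancestor closure of a term set
#'
#' Unions a set of terms with all their transitive is_a ancestors. Root terms
#' are excluded from the result: every closed set would otherwise share them,
#' adding a constant, uninformative dimension to all phenotype vectors.
#'
#' @param graph An `ontology_graph`.
#' @param terms Character vector of term IDs present in the graph.
#' @return Character vector: the closure, root(s) removed, in graph term order.
#' @export
ancestor_closure <- function(graph, terms) {
  terms <- unique(terms)
  unknown <- setdiff(terms, graph$terms)
  if (length(unknown)) {
    stop(sprintf("unknown term(s): %s", paste(unknown, collapse = ", ")))
  }
  seen <- terms
  frontier <- terms
  while (length(frontier)) {
    up <- unique(unlist(graph$parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, seen)
    seen <- c(seen, frontier)
  }
  intersect(graph$terms, setdiff(seen, graph$roots))
}

#' Load gene-to-phenotype annotations
#'
#' Reads a TSV in the shape of HPO's `genes_to_phenotype.txt`: one row per
#' (gene, term) pair. Comment lines start with `#`. Duplicate rows collapse to
#' set semantics.
#'
#' @param path Path to the TSV file, or a character vector of its lines.
#' @param graph An `ontology_graph` used to validate term IDs.
#' @param gene_col,term_col 1-based column indices of the gene symbol and the
#'   HPO term ID (HPO releases move these around).
#' @param strict If `TRUE`, a row citing a term absent from the ontology is an
#'   error; by default such rows are skipped with a warning.
#' @return A named list (class `gene_annotation_map`): gene symbol -> character
#'   vector of directly annotated term IDs.
#' @export
load_gene_annotations <- function(path, graph, gene_col = 1L, term_col = 2L,
                                  strict = FALSE) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(structure(list(), class = "gene_annotation_map"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- max(gene_col, term_col)
  short <- vapply(parts, length, 1L) < ncol_min
  if (any(short)) {
    stop(sprintf("annotation row with fewer than %d columns: %s",
                 ncol_min, lines[short][1L]))
  }
  genes <- vapply(parts, `[[`, "", gene_col)
  terms <- vapply(parts, `[[`, "", term_col)
  bad <- !(terms %in% graph$terms)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("annotation references unknown term(s): %s",
                   paste(unique(terms[bad]), collapse = ", ")))
    }
    warning(sprintf("skipping %d annotation row(s) with unknown terms (e.g. %s)",
                    sum(bad), terms[bad][1L]))
    genes <- genes[!bad]
    terms <- terms[!bad]
  }
  ann <- lapply(split(terms, genes), unique)
  structure(ann[order(names(ann))], class = "gene_annotation_map")
}

#' @export
print.gene_annotation_map <- function(x, ...) {
  cat(sprintf("gene_annotation_map: %d genes, %d gene-term pairs\n",
              length(x), sum(lengths(x))))
  invisible(x)
}
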