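# plain-text serialization of the pipeline's inputs and outputs: OBO for the
# ontology, TSV for gene-phenotype annotations and truth tables, JSON-lines
# for variant cohorts

#' Write an ontology graph as an OBO 1.2 flat file
#' @param graph An `ontology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in graph$terms) {
    writeLines(c("[Term]", sprintf("id: %s", t),
                 sprintf("is_a: %s", graph$parents[[t]]), ""), con)
  }
  invisible(path)
}

#' Write gene-to-phenotype annotations as TSV
#' @param annotations A `gene_annotation_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(annotations, path) {
  lines <- c("#gene\thpo_term",
             unlist(lapply(names(annotations), function(g)
               sprintf("%s\t%s", g, annotations[[g]])), use.names = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Write a variant table as JSON-lines
#'
#' One JSON object per variant; list columns (genes, multi-value and
#' categorical annotations) become JSON arrays.
#'
#' @param variants Variant data.table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_jsonl <- function(variants, path) {
  v <- data.table::as.data.table(variants)
  con <- file(path, "w")
  on.exit(close(con))
  list_cols <- names(v)[vapply(v, is.list, TRUE)]
  for (i in seq_len(nrow(v))) {
    rec <- as.list(v[i])
    for (lc in list_cols) rec[[lc]] <- rec[[lc]][[1L]]
    rec <- rec[!vapply(rec, function(x) length(x) == 1L && is.na(x), TRUE)]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON-lines variant table
#' @param path JSON-lines file.
#' @return A variant data.table with the package's standard column layout.
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  all_names <- unique(unlist(lapply(recs, names)))
  list_like <- c("genes", "transcript_effects", "gene_disease_assocs")
  scalar_cols <- c("key", "case_id", "total_depth", "alt_depth", "pop_freq",
                   "label", "acmg_class", "chron_order")
  v <- data.table::data.table(row = seq_along(recs))
  for (nm in all_names) {
    vals <- lapply(recs, `[[`, nm)
    if (nm %in% scalar_cols) {
      v[[nm]] <- unlist(lapply(vals, function(x) if (is.null(x)) NA else x),
                        use.names = FALSE)
    } else {
      v[[nm]] <- lapply(vals, function(x) {
        if (is.null(x)) {
          if (nm %in% list_like) character(0) else numeric(0)
        } else x
      })
      # single-value numeric annotations round-trip as plain columns
      if (!nm %in% list_like &&
          all(vapply(v[[nm]], length, 1L) <= 1L) &&
          all(vapply(v[[nm]], function(x) length(x) == 0L || is.numeric(x), TRUE))) {
        single <- vapply(v[[nm]], function(x) if (length(x)) x[[1L]] else NA_real_, 0.0)
        v[[nm]] <- single
      }
    }
  }
  v$row <- NULL
  v
}

#' Write / read the planted-positive truth table as TSV
#' @param truth data.table of planted positives.
#' @param path TSV path.
#' @rdname truth_io
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_io
#' @export
read_truth_tsv <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Write a synthetic cohort bundle to a directory
#'
#' Emits the full self-contained input set: `ontology.obo`,
#' `gene2pheno.tsv`, `cohort.jsonl`, `truth.tsv`, `cases.tsv`,
#' `blacklist.txt` and `spec-echo.yaml`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_obo(cohort$graph, file.path(dir, "ontology.obo"))
  write_gene_annotations(cohort$annotations, file.path(dir, "gene2pheno.tsv"))
  write_cohort_jsonl(cohort$variants, file.path(dir, "cohort.jsonl"))
  write_truth_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  cases <- data.table::copy(cohort$cases)
  cases$patient_terms <- vapply(cases$patient_terms, paste, "", collapse = ",")
  utils::write.table(cases, file.path(dir, "cases.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$blacklist, file.path(dir, "blacklist.txt"))
  yaml::write_yaml(unclass(cohort$spec), file.path(dir, "spec-echo.yaml"))
  invisible(dir)
}
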