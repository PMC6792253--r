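#' Declare one annotation-to-feature conversion
#'
#' A feature spec says how one raw annotation becomes numeric feature
#' column(s): single numeric values pass through, multi-valued numeric
#' annotations are reduced to their "worst" value (most deleterious / most
#' conserved), and multi-label categorical annotations are bin-count encoded
#' (one column per vocabulary label plus an `_other` bucket).
#'
#' Missing numeric annotations take `default_value`, which must lie outside
#' `expected_range` on the less-impactful side — e.g. a missing conservation
#' score defaults below the observable range, erring on the side of "not
#' conserved". The one exception is allele-frequency-like features
#' (`is_allele_freq = TRUE`), where absence from the population database
#' means a frequency of 0.
#'
#' @param name Feature name; also the annotation column it reads.
#' @param kind One of `"numeric_single"`, `"numeric_multi"`, `"categorical"`.
#' @param worst_direction `"min"` or `"max"`: which end is most impactful,
#'   for `numeric_multi` reduction.
#' @param default_value Value substituted for missing numeric annotations.
#' @param vocabulary Ordered category labels (categorical kind).
#' @param is_allele_freq Marks population-frequency features (default 0).
#' @param expected_range Length-2 numeric: the plausible value range, used to
#'   validate that `default_value` is extremal.
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("numeric_single", "numeric_multi", "categorical"),
                         worst_direction = NULL, default_value = NULL,
                         vocabulary = NULL, is_allele_freq = FALSE,
                         expected_range = NULL) {
  kind <- match.arg(kind)
  if (kind == "numeric_multi") {
    if (is.null(worst_direction) || !worst_direction %in% c("min", "max")) {
      stop(sprintf("feature '%s': numeric_multi needs worst_direction 'min' or 'max'", name))
    }
  }
  if (kind == "categorical") {
    if (!length(vocabulary)) stop(sprintf("feature '%s': categorical needs a non-empty vocabulary", name))
  } else {
    if (is.null(default_value)) {
      default_value <- if (is_allele_freq) 0 else stop(sprintf("feature '%s': numeric kinds need default_value", name))
    }
    if (!is_allele_freq && !is.null(expected_range)) {
      if (default_value > min(expected_range) && default_value < max(expected_range)) {
        stop(sprintf("feature '%s': default %g lies inside the expected range [%g, %g]",
                     name, default_value, min(expected_range), max(expected_range)))
      }
    }
  }
  structure(list(name = name, kind = kind, worst_direction = worst_direction,
                 default_value = default_value, vocabulary = vocabulary,
                 is_allele_freq = isTRUE(is_allele_freq),
                 expected_range = expected_range),
            class = "feature_spec")
}

#' Column names a spec expands to in the feature matrix
#' @param spec A `feature_spec`.
#' @return Character vector of matrix column names.
#' @export
feature_columns <- function(spec) {
  if (spec$kind == "categorical") {
    paste(spec$name, c(spec$vocabulary, "_other"), sep = "_")
  } else {
    spec$name
  }
}

#' Encode a single-valued numeric annotation
#'
#' Values pass through unchanged; missing values take the spec default
#' (0 for allele-frequency features).
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @param spec A `feature_spec` of kind `numeric_single`.
#' @return Numeric vector with no `NA`s.
#' @export
encode_numeric_single <- function(values, spec) {
  stopifnot(spec$kind == "numeric_single")
  if (!is.numeric(values)) {
    bad <- which(is.na(suppressWarnings(as.numeric(values))) & !is.na(values))
    if (length(bad)) {
      stop(sprintf("feature '%s': non-numeric value '%s' at row %d",
                   spec$name, as.character(values[bad[1L]]), bad[1L]))
    }
    values <- suppressWarnings(as.numeric(values))
  }
  values[is.na(values)] <- spec$default_value
  values
}

#' Reduce a multi-valued numeric annotation to its worst value
#'
#' @param values Numeric vector (one variant's values); empty means missing.
#' @param spec A `feature_spec` of kind `numeric_multi`.
#' @return Numeric scalar: max or min of the values per `worst_direction`,
#'   or `default_value` when empty.
#' @export
reduce_multi_value <- function(values, spec) {
  stopifnot(spec$kind == "numeric_multi")
  values <- values[!is.na(values)]
  if (!length(values)) return(spec$default_value)
  if (spec$worst_direction == "max") max(values) else min(values)
}

#' Bin-count encode a multi-label categorical annotation
#'
#' Counts how often each vocabulary label occurs; labels outside the
#' vocabulary are pooled into the `_other` bucket. Labels are matched
#' case-sensitively after whitespace trimming.
#'
#' @param labels Character vector of category labels for one variant.
#' @param spec A `feature_spec` of kind `categorical`.
#' @return Named integer vector over `c(vocabulary, "_other")`.
#' @export
bin_count_encode <- function(labels, spec) {
  stopifnot(spec$kind == "categorical")
  labels <- trimws(labels[!is.na(labels)])
  labels <- labels[nzchar(labels)]
  hit <- factor(ifelse(labels %in% spec$vocabulary, labels, "_other"),
                levels = c(spec$vocabulary, "_other"))
  stats::setNames(as.integer(table(hit)), c(spec$vocabulary, "_other"))
}

#' Assemble the numeric feature matrix for a variant table
#'
#' Applies every feature spec to the cohort, producing a dense numeric
#' matrix with one row per variant and a deterministic column order (specs
#' in order, categorical vocabularies in order). Encoding is total: no
#' missing cells survive, by construction of the default rules. Annotation
#' columns not covered by any spec are reported and dropped.
#'
#' @param variants Variant table (data.frame / data.table): reserved columns
#'   `key`, `case_id`, `genes`, `total_depth`, `alt_depth`, `pop_freq`,
#'   `transcript_effects`, `gene_disease_assocs`, `label`, `acmg_class`,
#'   `chron_order` plus one column per annotation (numeric, or a list column
#'   for multi-valued and categorical annotations).
#' @param specs List of [feature_spec()]s; names must be unique.
#' @return Object of class `feature_matrix`: list with `x` (numeric matrix),
#'   `keys`, `case_ids`, `labels` (1 = reported), `acmg_class`, `specs`.
#' @export
assemble_feature_matrix <- function(variants, specs) {
  v <- data.table::as.data.table(variants)
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate feature spec name: %s", nm[duplicated(nm)][1L]))
  }
  reserved <- c("key", "case_id", "genes", "total_depth", "alt_depth",
                "pop_freq", "transcript_effects", "gene_disease_assocs",
                "label", "acmg_class", "chron_order")
  uncovered <- setdiff(names(v), c(reserved, nm))
  if (length(uncovered)) {
    message(sprintf("dropping %d annotation column(s) not covered by a spec: %s",
                    length(uncovered), paste(uncovered, collapse = ", ")))
  }
  n <- nrow(v)
  cols <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    raw <- if (spec$name %in% names(v)) v[[spec$name]] else NULL
    if (spec$kind == "numeric_single") {
      vals <- if (is.null(raw)) rep(NA_real_, n) else raw
      m <- matrix(encode_numeric_single(vals, spec), ncol = 1,
                  dimnames = list(NULL, spec$name))
    } else if (spec$kind == "numeric_multi") {
      vals <- if (is.null(raw)) rep(list(numeric(0)), n) else raw
      m <- matrix(vapply(vals, reduce_multi_value, 0.0, spec = spec), ncol = 1,
                  dimnames = list(NULL, spec$name))
    } else {
      lv <- c(spec$vocabulary, "_other")
      m <- matrix(0L, nrow = n, ncol = length(lv),
                  dimnames = list(NULL, feature_columns(spec)))
      if (!is.null(raw) && n > 0) {
        lens <- lengths(raw)
        if (any(lens > 0)) {
          row_id <- rep(seq_len(n), lens)
          lab <- trimws(unlist(raw, use.names = FALSE))
          keep <- !is.na(lab) & nzchar(lab)
          lab <- ifelse(lab[keep] %in% spec$vocabulary, lab[keep], "_other")
          tab <- table(factor(row_id[keep], levels = seq_len(n)),
                       factor(lab, levels = lv))
          m <- matrix(as.integer(tab), nrow = n,
                      dimnames = list(NULL, feature_columns(spec)))
        }
      }
    }
    cols[[s]] <- m
  }
  x <- do.call(cbind, cols)
  if (anyNA(x)) stop("internal error: NA survived feature encoding")
  structure(list(
    x = x,
    keys = v$key,
    case_ids = v$case_id,
    labels = if ("label" %in% names(v)) as.integer(v$label == "reported") else rep(NA_integer_, n),
    acmg_class = if ("acmg_class" %in% names(v)) v$acmg_class else rep(NA_character_, n),
    specs = specs
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d variants x %d features (%d reported, %d cases)\n",
              nrow(x$x), ncol(x$x), sum(x$labels, na.rm = TRUE),
              length(unique(x$case_ids))))
  invisible(x)
}

#' Subset a feature matrix by row
#' @param fm A `feature_matrix`.
#' @param idx Integer or logical row index.
#' @return A `feature_matrix` with the selected rows.
#' @export
subset_feature_matrix <- function(fm, idx) {
  structure(list(x = fm$x[idx, , drop = FALSE], keys = fm$keys[idx],
                 case_ids = fm$case_ids[idx], labels = fm$labels[idx],
                 acmg_class = fm$acmg_class[idx], specs = fm$specs),
            class = "feature_matrix")
}

# vectorized one-way (two-group) ANOVA F statistic per column
.anova_f <- function(x, y) {
  y <- as.integer(y)
  n <- nrow(x)
  n1 <- sum(y == 1L); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present for univariate screening")
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ss_tot <- colSums(x^2) - n * m^2
  ssw <- ss_tot - ssb
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw <= .Machine$double.eps * ss_tot] <- ifelse(
    ssb[ssw <= .Machine$double.eps * ss_tot] > 0, Inf, 0)
  f[is.na(f)] <- 0
  f
}

# chi-square score per column against the binary label (for count columns):
# sum over classes of (observed column total - expected)^2 / expected,
# the univariate screening statistic used for non-negative count features
.chisq_score <- function(x, y) {
  if (any(x < 0)) stop("chi-square screening requires non-negative features")
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- length(y) - n1
  tot <- colSums(x)
  obs1 <- colSums(x[y == 1L, , drop = FALSE])
  obs0 <- tot - obs1
  exp1 <- tot * n1 / length(y)
  exp0 <- tot * n0 / length(y)
  chi <- ifelse(tot > 0, (obs1 - exp1)^2 / exp1 + (obs0 - exp0)^2 / exp0, 0)
  chi
}

#' Select the top k features by univariate screening
#'
#' Scores every column independently against the binary reported label and
#' keeps the k best. The default statistic is the one-way ANOVA F of the
#' column split by label (a chi-square alternative is available for
#' non-negative count columns). Selection must be fitted on training rows
#' only; the returned object records which cases it saw.
#'
#' @param fm A `feature_matrix` of training rows with binary labels.
#' @param k Number of features to keep.
#' @param statistic `"anova_f"` (default) or `"chisq"`.
#' @return Object of class `selection_result`: `selected` (column names,
#'   best first, ties broken by column order), `scores` (all columns),
#'   `fitted_on` (training case IDs).
#' @export
select_top_k <- function(fm, k = 20L, statistic = c("anova_f", "chisq")) {
  statistic <- match.arg(statistic)
  stopifnot(k >= 1)
  scores <- if (statistic == "anova_f") .anova_f(fm$x, fm$labels) else .chisq_score(fm$x, fm$labels)
  names(scores) <- colnames(fm$x)
  if (k > length(scores)) {
    warning(sprintf("k = %d exceeds the %d available columns; keeping all", k, length(scores)))
    k <- length(scores)
  }
  ord <- order(-scores, seq_along(scores))  # ties broken by column order
  structure(list(selected = names(scores)[ord[seq_len(k)]],
                 scores = scores,
                 statistic = statistic,
                 fitted_on = sort(unique(fm$case_ids))),
            class = "selection_result")
}

#' Per-feature importance of a fitted forest model
#'
#' Forest families report impurity-based importances over the selected
#' features, normalized to sum to 1 and sorted descending. Model families
#' without importances (penalized logistic, the boosted ensemble) are
#' rejected.
#'
#' @param model A `trained_model` whose family is a forest.
#' @return Named numeric vector summing to 1, descending.
#' @export
report_feature_importance <- function(model) {
  if (!model$config$family %in% c("weighted_forest", "balanced_forest")) {
    stop(sprintf("family '%s' does not expose feature importances", model$config$family))
  }
  imp <- model$fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  sort(imp, decreasing = TRUE)
}

#' Average importance maps across models
#'
#' Averages per-feature importances from several forest models (e.g. the
#' class-weighted and balanced-bootstrap forests) and orders the result from
#' most to least important.
#'
#' @param ... Named numeric importance vectors over the same feature set.
#' @return Named numeric vector of mean importances, descending.
#' @export
average_feature_importance <- function(...) {
  maps <- list(...)
  feats <- names(maps[[1L]])
  stopifnot(all(vapply(maps, function(m) setequal(names(m), feats), TRUE)))
  mean_imp <- Reduce(`+`, lapply(maps, function(m) m[feats])) / length(maps)
  sort(mean_imp, decreasing = TRUE)
}

#' Read / write feature specs as YAML
#' @param path YAML file: a list of feature_spec fields.
#' @rdname feature_spec_io
#' @export
read_feature_specs <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(e) do.call(feature_spec, e))
}

#' @param specs List of `feature_spec`s.
#' @rdname feature_spec_io
#' @export
write_feature_specs <- function(specs, path) {
  yaml::write_yaml(lapply(specs, function(s) Filter(Negate(is.null), unclass(s))), path)
  invisible(path)
}
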