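#' Clinical filter configuration
#'
#' The six-criterion screen a clinical analyst applies before review:
#' sufficient total read depth, sufficient alternate read depth, low
#' population frequency, at least one predicted transcript effect, at least
#' one gene-disease association, and absence from a blacklist of known
#' sequencing false positives.
#'
#' Default thresholds are placeholders chosen for a typical short-read
#' clinical pipeline; every one is configurable and nothing downstream
#' depends on the defaults.
#'
#' @param min_total_depth Minimum total read depth (reads).
#' @param min_alt_depth Minimum alternate-allele read depth (reads).
#' @param max_pop_freq Maximum population allele frequency in `[0, 1]`.
#'   A missing frequency means the variant is absent from the population
#'   database and is treated as frequency 0.
#' @param require_transcript_effect Require >= 1 predicted transcript effect.
#' @param require_gene_disease_assoc Require >= 1 gene-disease association.
#'   Variants with no gene links fail this criterion.
#' @param blacklist Character vector of variant keys (chrom:pos:ref:alt)
#'   known to be common sequencing false positives; matched exactly.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_total_depth = 8L, min_alt_depth = 4L,
                          max_pop_freq = 0.01,
                          require_transcript_effect = TRUE,
                          require_gene_disease_assoc = TRUE,
                          blacklist = character(0)) {
  stopifnot(min_alt_depth <= min_total_depth,
            max_pop_freq >= 0, max_pop_freq <= 1)
  structure(list(min_total_depth = min_total_depth,
                 min_alt_depth = min_alt_depth,
                 max_pop_freq = max_pop_freq,
                 require_transcript_effect = isTRUE(require_transcript_effect),
                 require_gene_disease_assoc = isTRUE(require_gene_disease_assoc),
                 blacklist = as.character(blacklist)),
            class = "filter_config")
}

#' Read / write a filter configuration as YAML
#' @param path YAML file path.
#' @rdname filter_config_io
#' @export
read_filter_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(filter_config, y[intersect(names(y), names(formals(filter_config)))])
}

#' @param cfg A `filter_config`.
#' @rdname filter_config_io
#' @export
write_filter_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Apply the six-criterion clinical filter to a variant table
#'
#' Reduces a cohort's called variants to the set an analyst would review.
#' Missing depth fields fail the depth criteria (conservative); a missing
#' population frequency means "absent from the database" and passes the
#' frequency criterion as frequency 0. Input row order is preserved and the
#' per-criterion rejection tally is attached as attribute `"rejections"`
#' (a variant failing several criteria is tallied once, under the first in
#' the order depth, alt_depth, freq, effect, assoc, blacklist).
#'
#' @param variants A data.frame / data.table of annotated variants with
#'   columns `key`, `genes` (list column), `total_depth`, `alt_depth`,
#'   `pop_freq`, `transcript_effects` (list column), `gene_disease_assocs`
#'   (list column); extra columns pass through untouched.
#' @param cfg A [filter_config()].
#' @param verbose Log the per-criterion rejection counts.
#' @return The passing subset of `variants`, same column layout, with the
#'   `"rejections"` attribute.
#' @export
apply_clinical_filter <- function(variants, cfg = filter_config(),
                                  verbose = FALSE) {
  v <- data.table::as.data.table(variants)
  n <- nrow(v)
  td <- v$total_depth; td[is.na(td)] <- -Inf
  ad <- v$alt_depth;   ad[is.na(ad)] <- -Inf
  pf <- v$pop_freq;    pf[is.na(pf)] <- 0

  ok_depth <- td >= cfg$min_total_depth
  ok_alt   <- ad >= cfg$min_alt_depth
  ok_freq  <- pf <= cfg$max_pop_freq
  ok_eff   <- if (cfg$require_transcript_effect) {
    vapply(v$transcript_effects, function(x) length(x[nzchar(x)]) > 0, TRUE)
  } else rep(TRUE, n)
  ok_assoc <- if (cfg$require_gene_disease_assoc) {
    vapply(v$genes, length, 1L) > 0 &
      vapply(v$gene_disease_assocs, function(x) length(x[nzchar(x)]) > 0, TRUE)
  } else rep(TRUE, n)
  ok_black <- !(v$key %in% cfg$blacklist)

  crit <- cbind(depth = ok_depth, alt_depth = ok_alt, freq = ok_freq,
                effect = ok_eff, assoc = ok_assoc, blacklist = ok_black)
  pass <- rowSums(crit) == ncol(crit)
  first_fail <- apply(!crit, 1L, function(row) which(row)[1L])
  tally <- table(factor(colnames(crit)[unlist(first_fail[!pass])],
                        levels = colnames(crit)))
  rejections <- stats::setNames(as.integer(tally), names(tally))
  if (verbose) {
    message(sprintf("clinical filter: %d/%d pass; rejected by {%s}",
                    sum(pass), n,
                    paste(sprintf("%s:%d", names(rejections), rejections),
                          collapse = ", ")))
  }
  out <- v[pass]
  data.table::setattr(out, "rejections", rejections)
  out
}
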