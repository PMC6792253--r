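# shared fixtures: toy ontologies, random DAG builders, the hand-designed
# clinical-filter cohort, and small random variant tables

chain_obo <- function() {
  c("[Term]", "id: A", "",
    "[Term]", "id: B", "is_a: A", "",
    "[Term]", "id: C", "is_a: B", "")
}

diamond_obo <- function() {
  c("[Term]", "id: A", "",
    "[Term]", "id: B", "is_a: A", "",
    "[Term]", "id: C", "is_a: A", "",
    "[Term]", "id: D", "is_a: B", "is_a: C", "")
}

# random rooted DAG as an ontology_graph-compatible OBO text; term i attaches
# below 1-2 earlier terms, so acyclicity and rootedness hold by construction
random_obo <- function(n_terms, seed, p_second_parent = 0.3) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  lines <- character(0)
  for (i in seq_len(n_terms)) {
    stanza <- c("[Term]", sprintf("id: %s", ids[i]))
    if (i > 1L) {
      parents <- ids[sample.int(i - 1L, 1L)]
      if (i > 2L && runif(1) < p_second_parent) {
        parents <- unique(c(parents, ids[sample.int(i - 1L, 1L)]))
      }
      stanza <- c(stanza, sprintf("is_a: %s", parents))
    }
    lines <- c(lines, stanza, "")
  }
  lines
}

# independent closure oracle: DFS reachability over the parent relation,
# done with plain recursion on the raw is_a lines (no package code)
oracle_closure <- function(obo_lines, terms) {
  ids <- sub("^id: ", "", grep("^id: ", obo_lines, value = TRUE))
  parent_of <- list()
  cur <- NULL
  for (ln in obo_lines) {
    if (startsWith(ln, "id: ")) cur <- sub("^id: ", "", ln)
    if (startsWith(ln, "is_a: ")) {
      parent_of[[cur]] <- c(parent_of[[cur]], sub("^is_a: ", "", ln))
    }
  }
  roots <- setdiff(ids, names(parent_of))
  reach <- function(t) {
    ps <- parent_of[[t]]
    if (is.null(ps)) return(t)
    unique(c(t, unlist(lapply(ps, reach))))
  }
  out <- unique(unlist(lapply(terms, reach)))
  intersect(ids, setdiff(out, roots))
}

# 20-variant filter fixture: 14 passers plus one variant failing each of the
# six criteria, under thresholds min_total_depth=10, min_alt_depth=5,
# max_pop_freq=0.05, both flags on, blacklist containing "bad:1:A:T"
filter_fixture <- function() {
  mk <- function(key, td = 30L, ad = 15L, pf = 0.001,
                 eff = "Missense", assoc = "OMIM:1", genes = "G1") {
    list(key = key, genes = list(genes), total_depth = td, alt_depth = ad,
         pop_freq = pf, transcript_effects = list(eff),
         gene_disease_assocs = list(assoc))
  }
  rows <- c(
    lapply(1:14, function(i) mk(sprintf("pass:%d:A:T", i))),
    list(
      mk("faildepth:1:A:T", td = 5L, ad = 3L),
      mk("failalt:1:A:T", ad = 2L),
      mk("failfreq:1:A:T", pf = 0.2),
      mk("faileffect:1:A:T", eff = character(0)),
      mk("failassoc:1:A:T", assoc = character(0)),
      mk("bad:1:A:T")
    )
  )
  dt <- data.table::rbindlist(lapply(rows, function(r) {
    data.table::as.data.table(list(key = r$key, genes = list(r$genes[[1]]),
                                   total_depth = r$total_depth,
                                   alt_depth = r$alt_depth, pop_freq = r$pop_freq,
                                   transcript_effects = list(r$transcript_effects[[1]]),
                                   gene_disease_assocs = list(r$gene_disease_assocs[[1]])))
  }))
  dt
}

fixture_filter_config <- function() {
  filter_config(min_total_depth = 10L, min_alt_depth = 5L, max_pop_freq = 0.05,
                blacklist = "bad:1:A:T")
}

# random structurally-valid variants for filter property tests
random_variants <- function(n, seed) {
  set.seed(seed)
  td <- sample(0:60, n, replace = TRUE)
  data.table::as.data.table(list(
    key = sprintf("%d:%d:A:T", sample(1:22, n, TRUE), sample.int(1e6, n)),
    genes = lapply(seq_len(n), function(i)
      if (runif(1) < 0.1) character(0) else sprintf("G%d", sample.int(50, 1))),
    total_depth = td,
    alt_depth = pmin(td, sample(0:30, n, replace = TRUE)),
    pop_freq = ifelse(runif(n) < 0.3, NA_real_, runif(n, 0, 0.3)),
    transcript_effects = lapply(seq_len(n), function(i)
      if (runif(1) < 0.15) character(0) else "Missense"),
    gene_disease_assocs = lapply(seq_len(n), function(i)
      if (runif(1) < 0.15) character(0) else "OMIM:1")
  ))
}

# labelled random feature matrix with planted signal columns
planted_matrix <- function(n, p, n_signal, shift, seed, pos_frac = 0.5) {
  set.seed(seed)
  y <- rbinom(n, 1, pos_frac)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  sig <- sample(p, n_signal)
  x[y == 1, sig] <- x[y == 1, sig] + shift
  fm <- structure(list(x = x, keys = sprintf("v%d", seq_len(n)),
                       case_ids = rep("case1", n), labels = y,
                       acmg_class = rep(NA_character_, n), specs = list()),
                  class = "feature_matrix")
  list(fm = fm, signal_cols = colnames(x)[sig])
}

# small imbalanced training matrix with informative features
imbalanced_matrix <- function(n_pos, n_neg, p = 20, shift = 1, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  x[y == 1, seq_len(p %/% 2)] <- x[y == 1, seq_len(p %/% 2)] + shift
  structure(list(x = x, keys = sprintf("v%d", seq_len(n)),
                 case_ids = sprintf("case%d", rep_len(1:20, n)), labels = y,
                 acmg_class = rep(NA_character_, n), specs = list()),
            class = "feature_matrix")
}
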