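#' Specification of a synthetic rare-disease cohort
#'
#' Defines the shape of a fully self-contained simulated cohort: a random
#' phenotype ontology with gene annotations, probands with noisy phenotype
#' term lists drawn from a causal gene, and per-proband variant tables in
#' which 1-3 planted reported variants hide among a few hundred
#' filter-passing negatives. The defaults mirror a realistic clinical
#' exome/genome cohort after primary filtering: 237 cases, 200-400 filtered
#' variants each, positives at roughly 1:230 to negatives, and a VUS-heavy
#' pathogenicity mix.
#'
#' Positive variants receive a mean shift on the 20 designated
#' signal-bearing features only (the other 75 encoded columns are pure
#' noise), scaled upward with the ACMG class so pathogenic variants are the
#' most separable — the gradient a trained ranker should recover.
#'
#' @param seed Master seed; every stage draws from named substreams of it.
#' @param n_terms Ontology size (terms including the root).
#' @param extra_parent_prob Probability a term gets a second is_a parent.
#' @param n_genes Number of annotated genes.
#' @param annotations_per_gene Mean directly annotated terms per gene.
#' @param n_cases Number of probands.
#' @param variants_per_case Length-2 range of filter-passing variants per
#'   case.
#' @param positives_per_case Length-2 range of planted reported variants.
#' @param class_mix Named probabilities over `VUS`, `LP`, `Path` (sums to 1).
#' @param signal_strength Base mean shift for positives, in units of each
#'   feature's background standard deviation; 0 disables the signal.
#' @param class_weights Named multipliers of `signal_strength` per ACMG
#'   class (Path > LP > VUS).
#' @param spurious_terms Range of spurious phenotype terms added per case
#'   (non-genetic or unrelated phenotypes).
#' @param dropped_term_frac Probability each causal-gene term is absent from
#'   the patient's list (incomplete penetrance / collection variability).
#' @param missing_rate Per-feature probability an annotation is missing.
#' @param fail_fraction Extra variants generated to fail the clinical
#'   filter, as a fraction of the passing count.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 1L, n_terms = 400L, extra_parent_prob = 0.3,
                        n_genes = 300L, annotations_per_gene = 8,
                        n_cases = 237L, variants_per_case = c(200L, 400L),
                        positives_per_case = c(1L, 3L),
                        class_mix = c(VUS = 0.59, LP = 0.22, Path = 0.19),
                        signal_strength = 0.4,
                        class_weights = c(VUS = 0.45, LP = 1.0, Path = 1.8),
                        spurious_terms = c(2L, 10L),
                        dropped_term_frac = 0.5,
                        missing_rate = 0.1,
                        fail_fraction = 0.15) {
  stopifnot(n_terms > 2, n_genes > 1, n_cases >= 1,
            abs(sum(class_mix) - 1) < 1e-9,
            all(names(class_mix) == c("VUS", "LP", "Path")),
            signal_strength >= 0, dropped_term_frac >= 0, dropped_term_frac < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a random rooted phenotype ontology with gene annotations
#'
#' Terms are created in order; each non-root term attaches below one
#' uniformly chosen earlier term (plus, with some probability, a second
#' parent), so every term reaches the single root and the graph is acyclic
#' by construction. Each gene is annotated with a coherent neighborhood of
#' the ontology: an anchor term plus terms sampled from the anchor's
#' ancestors and descendants, topped up at random to hit the target
#' annotation count.
#'
#' @param spec A [cohort_spec()].
#' @return List with `graph` (an `ontology_graph`) and `annotations`
#'   (a `gene_annotation_map`). Deterministic given `spec$seed`.
#' @export
generate_ontology <- function(spec) {
  .with_substream(spec$seed, "ontology", {
    n <- spec$n_terms
    ids <- sprintf("ST:%06d", seq_len(n))
    parents <- vector("list", n)
    names(parents) <- ids
    parents[[1L]] <- character(0)
    for (i in 2:n) {
      p <- ids[sample.int(i - 1L, 1L)]
      if (i > 2L && stats::runif(1) < spec$extra_parent_prob) {
        p <- unique(c(p, ids[sample.int(i - 1L, 1L)]))
      }
      parents[[i]] <- p
    }
    graph <- structure(list(terms = ids, parents = parents, roots = ids[1L],
                            n_dims = n - 1L),
                       class = "ontology_graph")

    # children index for descendant sampling
    kids <- split(rep(ids, lengths(parents)), unlist(parents, use.names = FALSE))
    descendants <- function(t) {
      out <- character(0); frontier <- t
      while (length(frontier)) {
        nxt <- unique(unlist(kids[frontier], use.names = FALSE))
        nxt <- setdiff(nxt, out)
        out <- c(out, nxt); frontier <- nxt
      }
      out
    }
    genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
    non_root <- ids[-1L]
    ann <- lapply(genes, function(g) {
      anchor <- sample(non_root, 1L)
      target <- 1L + stats::rpois(1L, spec$annotations_per_gene - 1)
      pool <- unique(c(setdiff(ancestor_closure(graph, anchor), anchor),
                       descendants(anchor)))
      take <- sample(pool, min(length(pool), target - 1L))
      terms <- unique(c(anchor, take))
      if (length(terms) < target) {
        terms <- unique(c(terms, sample(setdiff(non_root, terms),
                                        target - length(terms))))
      }
      terms
    })
    names(ann) <- genes
    list(graph = graph,
         annotations = structure(ann, class = "gene_annotation_map"))
  })
}

# categorical background samplers for the reference annotation set
.cat_background <- function() {
  list(
    HGMD_assessment = list(labels = c("DM", "DM?", "DP", "DFP", "FP", "R"),
                           prob = c(.15, .1, .2, .15, .3, .1), max_n = 2L, p_any = 0.3),
    HGMD_confidence = list(labels = c("High", "Medium", "Low"),
                           prob = c(.3, .4, .3), max_n = 1L, p_any = 0.3),
    ClinVar_classification = list(
      labels = c("Pathogenic", "Likely Pathogenic", "Uncertain Significance",
                 "Likely Benign", "Benign", "drug response"),
      prob = c(.08, .1, .4, .2, .2, .02), max_n = 3L, p_any = 0.4),
    MetaSVM_prediction = list(labels = c("D", "T"), prob = c(.3, .7),
                              max_n = 1L, p_any = 0.6),
    PolyPhen_HV_prediction = list(labels = c("D", "P", "B"),
                                  prob = c(.25, .25, .5), max_n = 2L, p_any = 0.6),
    PolyPhen_HD_prediction = list(labels = c("D", "P", "B"),
                                  prob = c(.25, .25, .5), max_n = 2L, p_any = 0.6),
    SIFT_prediction = list(labels = c("D", "T"), prob = c(.3, .7),
                           max_n = 1L, p_any = 0.6),
    Effects = list(labels = c("Premature stop", "Missense",
                              "Possible splicing modifier", "Synonymous",
                              "Intronic", "Frameshift", "In-frame indel"),
                   prob = c(.03, .45, .07, .2, .15, .05, .05), max_n = 2L,
                   p_any = 1.0)  # every variant has >= 1 predicted effect
  )
}

# numeric background distributions (mean, sd) for the reference annotation
# set; signal features get class-scaled mean shifts for positives
.num_background <- function() {
  specs <- reference_feature_specs()
  out <- list()
  for (s in specs) {
    if (s$kind == "categorical") next
    if (s$name %in% c("HPO_cosine", "PyxisMap")) next  # computed, not drawn
    rng <- s$expected_range
    mu <- mean(rng); sd_ <- diff(rng) / 8
    if (s$name == "CADD_scaled") { mu <- 12; sd_ <- 7 }
    if (s$name %in% c("gnomad_genome_af", "gnomad_exome_af")) { mu <- 0.003; sd_ <- 0.002 }
    if (s$name == "gnomad_genome_total_ac") { mu <- 400; sd_ <- 300 }
    out[[s$name]] <- list(kind = s$kind, mean = mu, sd = sd_,
                          range = rng, multi = s$kind == "numeric_multi")
  }
  out
}

#' Generate a synthetic proband cohort with planted reported variants
#'
#' Each case receives a causal gene, a noisy phenotype term list drawn from
#' that gene's annotations (terms dropped and spurious terms added, as in
#' real phenotype collection), a few hundred filter-passing background
#' variants, a tranche of variants designed to fail the clinical filter,
#' and 1-3 planted positives in the causal gene whose signal features are
#' mean-shifted according to their ACMG class. Missing annotations are
#' injected per feature. A truth table records every planted positive.
#'
#' @param spec A [cohort_spec()].
#' @param ontology Result of [generate_ontology()] (regenerated from the
#'   spec when omitted).
#' @return List of class `synthetic_cohort`:
#'   `variants` (data.table, one row per variant, pre-filter),
#'   `cases` (data.table: case_id, chron_order, causal_gene, patient_terms),
#'   `truth` (data.table of planted positives), `blacklist`, `graph`,
#'   `annotations`, `spec`.
#' @export
generate_cohort <- function(spec, ontology = NULL) {
  if (is.null(ontology)) ontology <- generate_ontology(spec)
  graph <- ontology$graph
  ann <- ontology$annotations
  genes <- names(ann)
  .with_substream(spec$seed, "cohort", {
    n_cases <- spec$n_cases
    case_ids <- sprintf("CASE%04d", seq_len(n_cases))
    eligible <- genes[lengths(ann) >= 3L]
    causal <- sample(eligible, n_cases, replace = TRUE)

    patient_terms <- lapply(seq_len(n_cases), function(i) {
      src <- ann[[causal[i]]]
      keep <- src[stats::runif(length(src)) > spec$dropped_term_frac]
      if (!length(keep)) keep <- sample(src, 1L)
      n_spur <- sample(seq(spec$spurious_terms[1], spec$spurious_terms[2]), 1L)
      spur <- if (n_spur > 0) sample(setdiff(graph$terms[-1L], keep), n_spur) else character(0)
      c(keep, spur)
    })

    n_pass <- sample(seq(spec$variants_per_case[1], spec$variants_per_case[2]),
                     n_cases, replace = TRUE)
    n_pos <- sample(seq(spec$positives_per_case[1], spec$positives_per_case[2]),
                    n_cases, replace = TRUE)
    n_fail <- pmax(1L, round(spec$fail_fraction * n_pass))

    # one row per variant; positives first within each case
    case_rep <- rep(seq_len(n_cases), n_pass + n_fail)
    N <- length(case_rep)
    is_pos <- unlist(lapply(seq_len(n_cases), function(i)
      c(rep(TRUE, n_pos[i]), rep(FALSE, n_pass[i] + n_fail[i] - n_pos[i]))))
    fails <- unlist(lapply(seq_len(n_cases), function(i)
      c(rep(FALSE, n_pass[i]), rep(TRUE, n_fail[i]))))

    chrom <- sample(c(1:22, "X"), N, replace = TRUE)
    pos <- sample.int(2.5e8, N, replace = TRUE)
    ref <- sample(c("A", "C", "G", "T"), N, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    key <- sprintf("%s:%d:%s:%s", chrom, pos, ref, alt)
    # regenerate any colliding keys until unique (collisions are ~0 anyway)
    while (anyDuplicated(key)) {
      d <- which(duplicated(key))
      pos[d] <- sample.int(2.5e8, length(d), replace = TRUE)
      key[d] <- sprintf("%s:%d:%s:%s", chrom[d], pos[d], ref[d], alt[d])
    }

    # gene links: positives sit in the causal gene; ~5% of variants overlap
    # a second gene
    gene1 <- ifelse(is_pos, causal[case_rep], sample(genes, N, replace = TRUE))
    second <- stats::runif(N) < 0.05
    gene2 <- sample(genes, N, replace = TRUE)
    gene_list <- lapply(seq_len(N), function(i) {
      if (second[i]) unique(c(gene1[i], gene2[i])) else gene1[i]
    })

    # filter fields: passing variants comfortably satisfy any sane
    # threshold set; failing variants break exactly one criterion each
    total_depth <- sample(20:80, N, replace = TRUE)
    alt_depth <- pmax(8L, as.integer(round(total_depth *
                                             stats::runif(N, 0.35, 0.65))))
    pop_freq <- ifelse(stats::runif(N) < 0.4, NA_real_,
                       stats::runif(N, 0, 0.008))
    cb <- .cat_background()
    eff <- cb$Effects
    effects_len <- 1L + (stats::runif(N) < 0.3)
    effects_all <- sample(eff$labels, sum(effects_len), replace = TRUE,
                          prob = eff$prob)
    transcript_effects <- split(effects_all,
                                factor(rep(seq_len(N), effects_len),
                                       levels = seq_len(N)))
    names(transcript_effects) <- NULL
    assoc_len <- 1L + (stats::runif(N) < 0.2)
    assoc_all <- sprintf("OMIM:%06d", sample.int(999999L, sum(assoc_len),
                                                 replace = TRUE))
    gene_disease_assocs <- split(assoc_all,
                                 factor(rep(seq_len(N), assoc_len),
                                        levels = seq_len(N)))
    names(gene_disease_assocs) <- NULL

    blacklist <- character(0)
    fail_idx <- which(fails)
    fail_mode <- sample(c("depth", "alt_depth", "freq", "effect", "assoc",
                          "blacklist"), length(fail_idx), replace = TRUE)
    total_depth[fail_idx[fail_mode == "depth"]] <-
      sample(0:7, sum(fail_mode == "depth"), replace = TRUE)
    alt_depth[fail_idx[fail_mode == "depth"]] <-
      pmin(alt_depth[fail_idx[fail_mode == "depth"]],
           total_depth[fail_idx[fail_mode == "depth"]])
    alt_depth[fail_idx[fail_mode == "alt_depth"]] <-
      sample(0:3, sum(fail_mode == "alt_depth"), replace = TRUE)
    pop_freq[fail_idx[fail_mode == "freq"]] <-
      stats::runif(sum(fail_mode == "freq"), 0.02, 0.5)
    for (i in fail_idx[fail_mode == "effect"]) transcript_effects[[i]] <- character(0)
    for (i in fail_idx[fail_mode == "assoc"]) gene_disease_assocs[[i]] <- character(0)
    blacklist <- key[fail_idx[fail_mode == "blacklist"]]

    # ACMG classes for positives
    acmg <- rep(NA_character_, N)
    acmg[is_pos] <- sample(names(spec$class_mix), sum(is_pos), replace = TRUE,
                           prob = spec$class_mix)
    shift_units <- ifelse(is_pos, spec$signal_strength *
                            unname(spec$class_weights[acmg]), 0)
    shift_units[is.na(shift_units)] <- 0

    v <- data.table::as.data.table(list(
      key = key, case_id = case_ids[case_rep],
      genes = gene_list,
      total_depth = total_depth, alt_depth = alt_depth, pop_freq = pop_freq,
      transcript_effects = transcript_effects,
      gene_disease_assocs = gene_disease_assocs,
      label = ifelse(is_pos, "reported", "not_reported"),
      acmg_class = acmg,
      chron_order = case_rep
    ))

    # numeric annotations
    signal <- .signal_feature_names()
    nb <- .num_background()
    for (nm in names(nb)) {
      bg <- nb[[nm]]
      shift <- if (nm %in% signal) shift_units * bg$sd else numeric(N)
      if (!bg$multi) {
        vals <- stats::rnorm(N, bg$mean, bg$sd) + shift
        miss <- stats::runif(N) < spec$missing_rate
        if (nm %in% c("gnomad_genome_af", "gnomad_exome_af")) {
          vals <- pmax(pmin(vals, 1), 0)
          # rare alleles are often absent from the database altogether:
          # ~40% of filtered negatives and ~80% of true positives; the
          # positive-specific rarity is part of the planted signal, so it is
          # switched off with it
          pos_sig <- is_pos & spec$signal_strength > 0
          miss <- stats::runif(N) < ifelse(pos_sig, 0.8, 0.4)
          vals[pos_sig & !miss] <- stats::runif(sum(pos_sig & !miss), 0, 1e-3)
        }
        if (nm == "gnomad_genome_total_ac") vals <- pmax(round(vals), 0)
        vals[miss] <- NA_real_
        v[[nm]] <- vals
      } else {
        lens <- sample(1:3, N, replace = TRUE)
        miss <- stats::runif(N) < spec$missing_rate
        lens[miss] <- 0L
        all_vals <- stats::rnorm(sum(lens), bg$mean, bg$sd) +
          rep(shift, lens)
        col <- split(all_vals, factor(rep(seq_len(N), lens), levels = seq_len(N)))
        names(col) <- NULL
        v[[nm]] <- col
      }
    }
    # categorical annotations (Effects reuses the transcript-effect labels)
    for (nm in names(cb)) {
      if (nm == "Effects") { v[[nm]] <- v$transcript_effects; next }
      b <- cb[[nm]]
      lens <- ifelse(stats::runif(N) < b$p_any,
                     1L + (stats::runif(N) < 0.25) * (b$max_n > 1L), 0L)
      labs <- sample(b$labels, sum(lens), replace = TRUE, prob = b$prob)
      col <- split(labs, factor(rep(seq_len(N), lens), levels = seq_len(N)))
      names(col) <- NULL
      v[[nm]] <- col
    }
    # prior-curation signal: reported variants have been seen before with a
    # probability that grows with their pathogenicity tier — an HGMD
    # disease-mutation entry (with high confidence) and ClinVar pathogenic
    # classifications; switched off with the rest of the planted signal
    if (spec$signal_strength > 0) {
      # per-row hit probability 0.33 x class weight: ~0.59 Path, 0.33 LP,
      # 0.15 VUS under the default weights
      q <- 0.33 * shift_units / spec$signal_strength
      hit_dm <- is_pos & stats::runif(N) < q
      hit_conf <- hit_dm & stats::runif(N) < 0.8
      hit_path <- is_pos & stats::runif(N) < q
      hit_lp <- is_pos & stats::runif(N) < 0.5 * q
      for (i in which(hit_dm)) v$HGMD_assessment[[i]] <- c(v$HGMD_assessment[[i]], "DM")
      for (i in which(hit_conf)) v$HGMD_confidence[[i]] <- c(v$HGMD_confidence[[i]], "High")
      for (i in which(hit_path)) {
        v$ClinVar_classification[[i]] <- c(v$ClinVar_classification[[i]], "Pathogenic")
      }
      for (i in which(hit_lp)) {
        v$ClinVar_classification[[i]] <- c(v$ClinVar_classification[[i]], "Likely Pathogenic")
      }
    }

    cases <- data.table::data.table(
      case_id = case_ids, chron_order = seq_len(n_cases),
      causal_gene = causal)
    cases$patient_terms <- patient_terms
    truth <- v[v$label == "reported",
               c("case_id", "key", "acmg_class", "chron_order")]
    structure(list(variants = v, cases = cases, truth = truth,
                   blacklist = blacklist, graph = graph, annotations = ann,
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d cases, %d variants (%d planted positives), %d-term ontology, %d genes\n",
              nrow(x$cases), nrow(x$variants), nrow(x$truth),
              length(x$graph$terms), length(x$annotations)))
  invisible(x)
}
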