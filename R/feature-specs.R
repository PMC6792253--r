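#' The reference 95-column feature specification set
#'
#' A clinical annotation pipeline exposes on the order of fifty raw
#' annotations per variant; encoded (with bin-count expansion of the
#' categorical ones) they become 95 numeric feature columns. This reference
#' set covers the named annotations a rare-disease analyst works from —
#' the two phenotype-match scores, scaled CADD, nucleotide conservation
#' (phyloP / phastCons / GERP), HGMD assessment and confidence bins, gnomAD
#' population counts, ClinVar classification bins, splice-impact predictors,
#' protein-effect predictor bins and transcript-effect categories — padded
#' with generic numeric annotation slots to the full 95-column shape, since
#' the complete inventory of a proprietary annotation stack is site-specific
#' and therefore configuration, not a constant.
#'
#' The two phenotype scores (`HPO_cosine`, `PyxisMap`) are ordinary
#' numeric-single features: they are computed per case by the phenoscore
#' functions and attached to the variant table before encoding.
#'
#' @return A list of [feature_spec()]s whose encoded column count is 95.
#' @export
reference_feature_specs <- function() {
  ns <- function(name, default, range, af = FALSE)
    feature_spec(name, "numeric_single", default_value = default,
                 expected_range = range, is_allele_freq = af)
  nm <- function(name, dir, default, range)
    feature_spec(name, "numeric_multi", worst_direction = dir,
                 default_value = default, expected_range = range)
  cat_ <- function(name, vocab) feature_spec(name, "categorical", vocabulary = vocab)

  specs <- list(
    # phenotype-match scores (computed, never missing in practice)
    ns("HPO_cosine", -1, c(0, 1)),
    ns("PyxisMap",   -1, c(0, 1)),
    # deleteriousness / conservation
    ns("CADD_scaled", -1, c(0, 99)),
    nm("phylop100_cons", "max", -30, c(-20, 10)),
    nm("phylop_cons",    "max", -30, c(-20, 10)),
    nm("phastcon100_cons", "max", -1, c(0, 1)),
    nm("phastcon_cons",    "max", -1, c(0, 1)),
    nm("GERP_rs", "max", -15, c(-12.3, 6.2)),
    # splice-impact predictors
    ns("splice_ADA", -1, c(0, 1)),
    ns("splice_RF",  -1, c(0, 1)),
    # population frequency / counts: absence from the database means 0
    ns("gnomad_genome_af", 0, c(0, 1), af = TRUE),
    ns("gnomad_exome_af",  0, c(0, 1), af = TRUE),
    ns("gnomad_genome_total_ac", 0, c(0, 300000), af = TRUE),
    # gene-level scores
    ns("haploinsufficiency", -1, c(0, 1)),
    ns("RVIS_intolerance", 20, c(-10, 10)),  # high = tolerant = less impactful
    nm("mappability", "min", 2, c(0, 1)),    # low = hard to map = impactful
    # curated-database and predictor categories (bin-count encoded)
    cat_("HGMD_assessment", c("DM", "DM?", "DP", "DFP", "FP")),
    cat_("HGMD_confidence", c("High", "Medium", "Low")),
    cat_("ClinVar_classification",
         c("Pathogenic", "Likely Pathogenic", "Uncertain Significance",
           "Likely Benign", "Benign")),
    cat_("MetaSVM_prediction", c("D", "T")),
    cat_("PolyPhen_HV_prediction", c("D", "P", "B")),
    cat_("PolyPhen_HD_prediction", c("D", "P", "B")),
    cat_("SIFT_prediction", c("D", "T")),
    cat_("Effects", c("Premature stop", "Missense", "Possible splicing modifier",
                      "Synonymous", "Intronic", "Frameshift", "In-frame indel"))
  )
  # generic numeric annotation slots: stand-ins for the remainder of a
  # site-specific annotation inventory
  for (i in 1:30) {
    specs[[length(specs) + 1L]] <-
      ns(sprintf("generic_score_%02d", i), -1, c(0, 10))
  }
  for (i in 1:11) {
    specs[[length(specs) + 1L]] <-
      nm(sprintf("generic_multi_%02d", i), if (i %% 2) "max" else "min",
         if (i %% 2) -1 else 20, c(0, 10))
  }
  specs
}

# encoded columns the synthetic generator treats as signal-bearing (20 of
# 95): the two phenotype scores carry signal implicitly via the causal gene;
# the numeric ones receive class-scaled mean shifts for positives; the four
# categorical bins (prior-curation labels) are drawn with class-scaled
# probabilities, the mechanism that actually separates pathogenicity tiers
# in clinical annotation data
.signal_feature_names <- function() {
  c("HPO_cosine", "PyxisMap", "CADD_scaled",
    "phylop100_cons", "phylop_cons", "phastcon100_cons", "phastcon_cons",
    "GERP_rs", "splice_ADA", "splice_RF", "haploinsufficiency",
    "RVIS_intolerance", sprintf("generic_score_%02d", 1:4),
    "HGMD_assessment_DM", "HGMD_confidence_High",
    "ClinVar_classification_Pathogenic",
    "ClinVar_classification_Likely Pathogenic")
}
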