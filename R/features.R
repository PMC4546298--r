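# Canonical feature vocabulary shared across the pipeline.

#' Feature names used by the binding-region models
#'
#' The classifier works on 23 named features in three families: two
#' sequence-motif (SM) features from PWM scanning, eleven chromatin-state
#' (CS) features (histone H3 occupancy, two acetyltransferases, and seven
#' histone modifications, all on the H3-normalized scale), and ten
#' DNA-structure (DS) features (the per-region means of the top five
#' dinucleotide-property principal components, `PC1`..`PC5`, and their
#' differences from the 30 bp flanking regions, `dPC1`..`dPC5`).
#'
#' @param family One of `"SM"`, `"CS"`, `"DS"`, or `"all"`.
#' @return Character vector of feature names in canonical order.
#' @examples
#' feature_names("SM")
#' length(feature_names())
#' @export
feature_names <- function(family = c("all", "SM", "CS", "DS")) {
  family <- match.arg(family)
  sm <- c("ScerTFhit", "ScerTFpvalue")
  cs <- c("H3", "ESA1", "GCN5", "H4ac", "H3K9ac", "H3K14ac",
          "H3K4me1", "H3K4me2", "H3K4me3", "H3K36me3", "H3K79me3")
  ds <- c(paste0("PC", 1:5), paste0("dPC", 1:5))
  switch(family, SM = sm, CS = cs, DS = ds, all = c(sm, cs, ds))
}

#' Feature subsets used by the evaluation models
#'
#' Returns the named feature subsets compared by [feature_set_models()]:
#' the three single-family sets, their pairwise and full combinations, the
#' three-feature `MAJOR` set (experimental H3 occupancy plus the two leading
#' structure components) and the `INTRINSIC` set, which replaces H3 with
#' in-silico predicted nucleosome occupancy so that every feature is
#' computable from genome sequence alone.
#'
#' @return Named list of character vectors.
#' @export
model_feature_sets <- function() {
  list(
    SM         = feature_names("SM"),
    CS         = feature_names("CS"),
    DS         = feature_names("DS"),
    `SM+CS`    = c(feature_names("SM"), feature_names("CS")),
    `SM+DS`    = c(feature_names("SM"), feature_names("DS")),
    `CS+DS`    = c(feature_names("CS"), feature_names("DS")),
    `SM+CS+DS` = feature_names("all"),
    MAJOR      = c("H3", "PC1", "PC2"),
    INTRINSIC  = c("occupancy", "PC1", "PC2")
  )
}

# The 16 dinucleotides in fixed row order used everywhere a 16-row
# property table or score matrix appears.
DINUCLEOTIDES <- c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0)))

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

#' @noRd
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# reverse complement of plain character sequences (vectorised)
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
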