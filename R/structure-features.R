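# DNA-structure (DS) features. The ~hundred physical dinucleotide
# properties (helix geometry, thermodynamics) are highly redundant, so
# they are consolidated by PCA over the 16 dinucleotides; a region is
# then described by the mean component score of its dinucleotide steps
# (PC1..PC5) and by the difference between that mean and the mean over
# its 30 bp flanks (dPC1..dPC5).

#' Fit a principal-component model of dinucleotide properties
#'
#' Property columns are standardized over the 16 dinucleotides (zero
#' mean, unit variance — correlation PCA, required because the properties
#' mix thermodynamic and geometric units) before eigendecomposition.
#' Constant columns are dropped with a warning. The sign of each retained
#' component is fixed so that its largest-magnitude loading is positive,
#' which makes loadings and scores stable across runs.
#'
#' @param table Dinucleotide property tibble: `dinucleotide` column plus
#'   numeric property columns (see [read_dinuc_table()]).
#' @param k Number of components to retain (default 5); reduced with a
#'   warning when fewer informative dimensions exist.
#' @return An object of class `pc_model` with elements `property_means`,
#'   `property_scales`, `loadings` (P x K), `explained_variance_ratio`
#'   (length K), `explained_variance_ratio_full` (all components), and
#'   `dinuc_scores` (16 x K component scores per dinucleotide).
#' @export
fit_pca <- function(table, k = 5L) {
  props <- setdiff(names(table), "dinucleotide")
  x <- as.matrix(table[props])
  rownames(x) <- table$dinucleotide
  x <- x[DINUCLEOTIDES, , drop = FALSE]
  sds <- apply(x, 2, sd)
  constant <- sds < 1e-12
  if (any(constant)) {
    warn(sprintf("dropping %d constant property column(s): %s",
                 sum(constant),
                 paste(head(props[constant], 5), collapse = ", ")))
    x <- x[, !constant, drop = FALSE]
  }
  if (ncol(x) < 2L) abort("need >= 2 properties with nonzero variance")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  evr_full <- pc$sdev^2 / sum(pc$sdev^2)
  informative <- sum(pc$sdev > 1e-8 * pc$sdev[1])
  k_eff <- min(k, informative)
  if (k_eff < k) {
    warn(sprintf("only %d informative dimensions; retaining %d components",
                 informative, k_eff))
  }
  load <- pc$rotation[, seq_len(k_eff), drop = FALSE]
  scores <- pc$x[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(k_eff))
  structure(
    list(
      property_means = pc$center,
      property_scales = pc$scale,
      loadings = load,
      explained_variance_ratio = evr_full[seq_len(k_eff)],
      explained_variance_ratio_full = evr_full,
      dinuc_scores = scores,
      k = k_eff
    ),
    class = "pc_model"
  )
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d properties, %d components (%.1f%% of variance)\n",
              nrow(x$loadings), x$k,
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' @describeIn fit_pca Loadings in tidy form: one row per
#'   (component, property) with the loading coefficient.
#' @param x,object A `pc_model`.
#' @param ... Unused.
#' @method tidy pc_model
#' @export
tidy.pc_model <- function(x, ...) {
  load <- x$loadings
  tibble(
    pc = rep(colnames(load), each = nrow(load)),
    property = rep(rownames(load), times = ncol(load)),
    loading = as.vector(load)
  )
}

#' @describeIn fit_pca One-row summary: components retained and variance
#'   explained.
#' @method glance pc_model
#' @export
glance.pc_model <- function(x, ...) {
  tibble(
    n_properties = nrow(x$loadings),
    n_components = x$k,
    variance_explained = sum(x$explained_variance_ratio)
  )
}

#' Annotate principal components by their top-loading properties
#'
#' For each retained component, lists the `k` property names with the
#' highest absolute loading (ties broken by property order in the
#' table). This is how a component acquires a physical interpretation,
#' e.g. a component whose top loadings are all major-groove geometry
#' properties reads as "major groove geometry".
#'
#' @param model A fitted [fit_pca()] model.
#' @param k Number of top properties per component (clamped to the number
#'   of properties).
#' @param pcs Component indices to annotate; default all retained.
#'   Requesting a component beyond the model errors.
#' @return Tibble with columns `pc`, `rank`, `property`, `loading`.
#' @export
annotate_pcs <- function(model, k = 10L, pcs = seq_len(model$k)) {
  if (any(pcs < 1L | pcs > model$k)) {
    abort(sprintf("requested component outside the %d-component model",
                  model$k))
  }
  k <- min(k, nrow(model$loadings))
  if (k < 1L) {
    return(tibble(pc = character(), rank = integer(),
                  property = character(), loading = numeric()))
  }
  purrr::map_dfr(pcs, function(j) {
    l <- model$loadings[, j]
    ord <- order(-abs(l), seq_along(l))[seq_len(k)]
    tibble(pc = paste0("PC", j), rank = seq_len(k),
           property = rownames(model$loadings)[ord], loading = l[ord])
  })
}

# dinucleotide step indices of a sequence (1..16, NA for steps touching
# non-ACGT); length len - 1
dinuc_steps <- function(sequence) {
  code <- encode_bases(sequence)
  n <- length(code)
  if (n < 2L) return(integer(0))
  (code[-n] - 1L) * 4L + code[-1L]
}

#' Mean principal-component scores of a region
#'
#' Each of the `len - 1` dinucleotide steps (step size one base pair)
#' gets the component score of its dinucleotide; the region value is the
#' mean over steps. Steps containing non-ACGT characters are skipped; a
#' region with no valid step yields missing values.
#'
#' @param sequence Region sequence (length >= 2 for any valid step).
#' @param model A fitted [fit_pca()] model.
#' @return One-row tibble with columns `PC1`..`PCk`.
#' @export
region_pc_scores <- function(sequence, model) {
  steps <- dinuc_steps(sequence)
  steps <- steps[!is.na(steps)]
  pcs <- paste0("PC", seq_len(model$k))
  if (!length(steps)) {
    return(as_tibble(setNames(as.list(rep(NA_real_, model$k)), pcs)))
  }
  m <- colMeans(model$dinuc_scores[steps, , drop = FALSE])
  as_tibble(as.list(setNames(m, pcs)))
}

#' Flank-contrast principal-component scores of a region
#'
#' `dPCx` is the mean component score over the region's steps minus the
#' mean over the steps of its 5' and 3' flanking sequences. With
#' `flank_mode = "pooled"` (default) the two flanks' steps are pooled
#' into one mean; `"mean_of_means"` averages the two per-flank means
#' instead. A missing (empty or < 2 bp) flank simply contributes no
#' steps; when both flanks are empty the result is missing.
#'
#' @param sequence Region sequence.
#' @param flank5,flank3 Flanking sequences (nominally 30 bp each,
#'   truncated at chromosome ends; `""` when absent).
#' @param model A fitted [fit_pca()] model.
#' @param flank_mode `"pooled"` or `"mean_of_means"`.
#' @return One-row tibble with columns `dPC1`..`dPCk`.
#' @export
delta_pc <- function(sequence, flank5 = "", flank3 = "", model,
                     flank_mode = c("pooled", "mean_of_means")) {
  flank_mode <- match.arg(flank_mode)
  dpcs <- paste0("dPC", seq_len(model$k))
  region_steps <- dinuc_steps(sequence)
  region_steps <- region_steps[!is.na(region_steps)]
  s5 <- dinuc_steps(flank5); s5 <- s5[!is.na(s5)]
  s3 <- dinuc_steps(flank3); s3 <- s3[!is.na(s3)]
  if (!length(region_steps) || (!length(s5) && !length(s3))) {
    return(as_tibble(setNames(as.list(rep(NA_real_, model$k)), dpcs)))
  }
  region_mean <- colMeans(model$dinuc_scores[region_steps, , drop = FALSE])
  flank_mean <- if (flank_mode == "pooled") {
    colMeans(model$dinuc_scores[c(s5, s3), , drop = FALSE])
  } else {
    means <- list()
    if (length(s5)) means <- c(means, list(colMeans(model$dinuc_scores[s5, , drop = FALSE])))
    if (length(s3)) means <- c(means, list(colMeans(model$dinuc_scores[s3, , drop = FALSE])))
    Reduce(`+`, means) / length(means)
  }
  as_tibble(as.list(setNames(region_mean - flank_mean, dpcs)))
}

#' DNA-structure features for a table of regions
#'
#' Convenience wrapper computing `PC1..PC5` and `dPC1..dPC5` for each
#' region against a genome, with 30 bp flanks truncated at chromosome
#' ends.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param genome Named character vector of chromosome sequences.
#' @param model A fitted [fit_pca()] model.
#' @param flank Flank width in bp, default 30.
#' @inheritParams delta_pc
#' @return `regions` with the 10 DS feature columns appended.
#' @export
ds_features <- function(regions, genome, model, flank = 30L,
                        flank_mode = c("pooled", "mean_of_means")) {
  flank_mode <- match.arg(flank_mode)
  rows <- purrr::pmap_dfr(
    regions[c("chrom", "start", "end")],
    function(chrom, start, end) {
      seqlen <- nchar(genome[[chrom]])
      reg <- substr(genome[[chrom]], start + 1L, end)
      f5 <- substr(genome[[chrom]], max(0L, start - flank) + 1L, start)
      f3 <- substr(genome[[chrom]], end + 1L, min(seqlen, end + flank))
      dplyr::bind_cols(
        region_pc_scores(reg, model),
        delta_pc(reg, f5, f3, model, flank_mode)
      )
    }
  )
  dplyr::bind_cols(regions, rows)
}
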