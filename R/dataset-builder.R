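# Balanced per-TF datasets: motif-centered 60 bp refinement of bound
# probes, lowest-signal negative selection, the missing-value drop rule,
# and the < 30-bound-probes filter.

#' Refine a probe to a motif-centered 60 bp region
#'
#' Scans from 240 bp upstream of the probe start to 240 bp downstream of
#' the probe end and returns the 60 bp region centered on the midpoint
#' of the best motif hit. "Best" is the maximum score, ties broken by
#' smaller p-value, then leftmost start, then `+` strand. When no window
#' is scannable (or `centering = "midpoint"`), the region is centered on
#' the probe midpoint instead. Regions are shifted to stay inside the
#' chromosome; chromosomes shorter than 60 bp yield a clipped region
#' flagged by the `clipped` column.
#'
#' @param probes Probe tibble (`chrom`, `start`, `end`, plus any other
#'   columns, which are carried through).
#' @param pwm A [pwm_record()].
#' @param genome Named character vector of chromosome sequences.
#' @param background Background base probabilities; default estimated
#'   from the genome.
#' @param dist Optional precomputed [score_pvalue_distribution()].
#' @param centering `"motif"` (default) or `"midpoint"`.
#' @param flank Scan extension on each side of the probe, default 240.
#' @return Tibble like `probes` with `start`, `end` replaced by the
#'   refined 60 bp region and a logical `clipped` column added.
#' @export
refine_regions <- function(probes, pwm, genome,
                           background = base_background(genome),
                           dist = NULL,
                           centering = c("motif", "midpoint"),
                           flank = 240L) {
  centering <- match.arg(centering)
  if (centering == "motif" && is.null(dist)) {
    dist <- score_pvalue_distribution(pwm, background)
  }
  k <- if (centering == "motif") {
    pwm_binned_scores(pwm, background, attr(dist, "bin_width"))
  }
  L <- nrow(pwm$matrix)
  centers <- purrr::pmap_int(
    probes[c("chrom", "start", "end")],
    function(chrom, start, end) {
      midpoint <- as.integer((start + end) %/% 2L)
      if (centering == "midpoint") return(midpoint)
      lo <- max(0L, start - flank)
      hi <- min(nchar(genome[[chrom]]), end + flank)
      window <- substr(genome[[chrom]], lo + 1L, hi)
      scans <- scan_both_strands(window, k, dist)
      ok <- !is.na(scans$k)
      if (!any(ok)) return(midpoint)
      s <- scans[ok, ]
      best <- s[order(-s$k, s$pvalue, s$start, s$strand != "+"), ][1, ]
      as.integer(lo + best$start + L %/% 2L)
    }
  )
  out <- probes
  chromlen <- nchar(genome)[probes$chrom]
  start <- pmax(0L, pmin(centers - 30L, as.integer(chromlen) - 60L))
  out$start <- as.integer(start)
  out$end <- as.integer(pmin(chromlen, start + 60L))
  out$clipped <- (out$end - out$start) != 60L
  out
}

#' Select the lowest-signal unbound probes as negatives
#'
#' The negative candidate set is the `n` unbound probes with the lowest
#' signal, ties broken by coordinate order.
#'
#' @param probes Probe tibble with `signal` (unbound probes only, or
#'   mixed — only rows labeled `"unbound"` are considered when a `label`
#'   column exists).
#' @param n Number of negatives required.
#' @return Tibble of `n` probes.
#' @export
select_negatives <- function(probes, n) {
  if ("label" %in% names(probes)) probes <- probes[probes$label == "unbound", ]
  if (nrow(probes) < n) {
    abort(sprintf("need %d unbound probes, have %d", n, nrow(probes)))
  }
  probes[order(probes$signal, probes$chrom, probes$start), ][seq_len(n), ]
}

#' Compute the full 23-feature matrix (plus occupancy) for regions
#'
#' Runs the three feature extractors over a region table: SM features by
#' PWM scanning, CS features from the tracks, DS features from the
#' dinucleotide-property PC model, plus the intrinsic occupancy score.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param pwm A [pwm_record()].
#' @param genome Named character vector of chromosome sequences.
#' @param tracks CS track tibble (see [extract_cs_features()]).
#' @param pc_model A fitted [fit_pca()] model.
#' @param background Background base probabilities; default from genome.
#' @param normalize CS normalization mode, see [extract_cs_features()].
#' @param occupancy_track Optional precomputed occupancy track.
#' @return `regions` with 24 feature columns appended.
#' @export
assemble_features <- function(regions, pwm, genome, tracks, pc_model,
                              background = base_background(genome),
                              normalize = c("h3_subtract", "none"),
                              occupancy_track = NULL) {
  normalize <- match.arg(normalize)
  dist <- score_pvalue_distribution(pwm, background)
  sm <- purrr::pmap_dfr(
    regions[c("chrom", "start", "end")],
    function(chrom, start, end) {
      sm_features(pwm, substr(genome[[chrom]], start + 1L, end),
                  background, dist = dist)
    }
  )
  out <- dplyr::bind_cols(regions, sm)
  out <- extract_cs_features(out, tracks, normalize)
  out <- ds_features(out, genome, pc_model)
  occupancy_feature(out, genome, occupancy_track)
}

#' Build the balanced bound/unbound dataset for one TF
#'
#' Implements the dataset-construction rules: bound probes are refined to
#' motif-centered 60 bp regions and form the positive set; the same
#' number of lowest-signal unbound probes form the negative set (refined
#' with the same centering rule by default, or probe-midpoint centering
#' via `negative_centering`); rows with a missing value in any of the 23
#' features are dropped; a TF ending up with fewer than `min_bound`
#' positives is skipped (returns `NULL` with a message). After
#' filtering, the larger class is truncated — negatives by keeping the
#' lowest signals, positives by keeping the highest — so the dataset is
#' exactly balanced.
#'
#' @param probes Probe tibble for one TF with `label` and `signal`.
#' @param pwm,genome,tracks,pc_model,background,normalize,occupancy_track
#'   Passed to [assemble_features()] / [refine_regions()].
#' @param tf TF identifier; defaults to `pwm$tf`.
#' @param negative_centering `"motif"` (default, symmetric with
#'   positives) or `"midpoint"`.
#' @param min_bound Minimum surviving positives, default 30.
#' @return A balanced dataset tibble (`tf`, region columns, `label`,
#'   23 + 1 feature columns), or `NULL` when the TF is skipped; the skip
#'   reason is attached as attribute `"skip_reason"` of the `NULL` is
#'   reported via `inform()`.
#' @export
build_tf_dataset <- function(probes, pwm, genome, tracks, pc_model,
                             tf = pwm$tf,
                             background = base_background(genome),
                             normalize = c("h3_subtract", "none"),
                             negative_centering = c("motif", "midpoint"),
                             occupancy_track = NULL,
                             min_bound = 30L) {
  normalize <- match.arg(normalize)
  negative_centering <- match.arg(negative_centering)
  bound <- probes[probes$label == "bound", ]
  if (nrow(bound) < min_bound) {
    inform(sprintf("skipping %s: %d bound probes (< %d)",
                   tf, nrow(bound), min_bound))
    return(NULL)
  }
  dist <- score_pvalue_distribution(pwm, background)
  pos <- refine_regions(bound, pwm, genome, background, dist, "motif")
  n_avail <- sum(probes$label == "unbound")
  neg <- select_negatives(probes, min(nrow(bound), n_avail))
  neg <- refine_regions(neg, pwm, genome, background, dist,
                        negative_centering)
  all_regions <- dplyr::bind_rows(pos, neg)
  all_regions$tf <- tf
  feats <- assemble_features(all_regions, pwm, genome, tracks, pc_model,
                             background, normalize, occupancy_track)
  complete <- complete.cases(feats[feature_names()])
  feats <- feats[complete, ]
  pos_f <- feats[feats$label == "bound", ]
  neg_f <- feats[feats$label == "unbound", ]
  if (nrow(pos_f) < min_bound) {
    inform(sprintf("skipping %s: %d bound probes after filtering (< %d)",
                   tf, nrow(pos_f), min_bound))
    return(NULL)
  }
  m <- min(nrow(pos_f), nrow(neg_f))
  if (m < min_bound) {
    inform(sprintf("skipping %s: only %d unbound probes after filtering",
                   tf, nrow(neg_f)))
    return(NULL)
  }
  pos_f <- pos_f[order(-pos_f$signal), ][seq_len(m), ]
  neg_f <- neg_f[order(neg_f$signal), ][seq_len(m), ]
  dplyr::bind_rows(pos_f, neg_f)
}

#' Pair a focal TF's bound regions against each other TF's
#'
#' For TF-specific binding prediction, the focal TF's bound regions are
#' contrasted with regions bound by each of the other TFs in turn: one
#' balanced dataset per other TF, the larger class downsampled (seeded)
#' to the smaller. Performance is typically summarized as the mean over
#' the pairs.
#'
#' @param datasets Combined dataset tibble for several TFs (rows carry
#'   `tf` and `label`; only `"bound"` rows are used).
#' @param focal TF identifier to contrast against the rest.
#' @param seed Seed for the downsampling.
#' @return Nested tibble: `focal`, `other`, `data` (list of balanced
#'   dataset tibbles in which the other TF's regions are labeled
#'   `"unbound"`).
#' @export
build_one_vs_rest <- function(datasets, focal, seed = 1L) {
  bound <- datasets[datasets$label == "bound", ]
  others <- setdiff(unique(bound$tf), focal)
  if (!length(others)) abort("need at least 2 TFs for one-vs-rest pairs")
  focal_rows <- bound[bound$tf == focal, ]
  set.seed(seed)
  pairs <- purrr::map(others, function(other) {
    neg <- bound[bound$tf == other, ]
    neg$label <- "unbound"
    m <- min(nrow(focal_rows), nrow(neg))
    pos <- focal_rows[sample(nrow(focal_rows), m), ]
    neg <- neg[sample(nrow(neg), m), ]
    dplyr::bind_rows(pos, neg)
  })
  tibble(focal = focal, other = others, data = pairs)
}
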