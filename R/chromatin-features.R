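# Chromatin-state (CS) features from ChIP-chip style probe tracks, plus
# the sequence-intrinsic nucleosome-occupancy score used by the intrinsic
# property model.

#' Average track signal over a region
#'
#' The region value of a probe track is the unweighted mean of the values
#' of probes covering more than half of the region (strictly more: a
#' probe overlapping exactly 30 of 60 bp does not qualify). When no probe
#' qualifies the value is missing — missingness propagates to the dataset
#' builder's row-drop rule rather than being imputed as zero.
#'
#' @param track Track tibble (`chrom`, `start`, `end`, `value`), one
#'   feature.
#' @param chrom,start,end Region coordinates (0-based half-open;
#'   nominally 60 bp).
#' @return Scalar value or `NA`.
#' @export
region_track_value <- function(track, chrom, start, end) {
  p <- track[track$chrom == chrom, ]
  if (!nrow(p)) return(NA_real_)
  overlap <- pmin(p$end, end) - pmax(p$start, start)
  qualifying <- overlap > (end - start) / 2
  if (!any(qualifying)) return(NA_real_)
  mean(p$value[qualifying])
}

# region values for many regions against one feature's probes, same
# qualification rule; vectorized over regions per chromosome
track_values <- function(track, regions) {
  out <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    p <- track[track$chrom == ch, ]
    idx <- which(regions$chrom == ch)
    if (!nrow(p)) next
    for (i in idx) {
      overlap <- pmin(p$end, regions$end[i]) - pmax(p$start, regions$start[i])
      q <- overlap > (regions$end[i] - regions$start[i]) / 2
      if (any(q)) out[i] <- mean(p$value[q])
    }
  }
  out
}

#' Extract the 11 chromatin-state features for regions
#'
#' Computes the per-region value of each CS track by the
#' more-than-half-coverage rule of [region_track_value()]. With
#' `normalize = "h3_subtract"` (the default) each modification feature is
#' reported relative to histone H3 occupancy — value minus the region's
#' H3 value on the log-ratio track scale — and H3 itself is reported raw;
#' regions with missing H3 then have all modification features missing.
#' Use `normalize = "none"` for tracks that are already H3-normalized
#' (the synthetic generator emits such tracks).
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param tracks Track tibble with a `feature` column covering (a subset
#'   of) the 11 CS feature names.
#' @param normalize `"h3_subtract"` or `"none"`.
#' @return `regions` with one numeric column per CS feature appended
#'   (missing tracks yield missing columns of `NA`).
#' @export
extract_cs_features <- function(regions, tracks,
                                normalize = c("h3_subtract", "none")) {
  normalize <- match.arg(normalize)
  cs <- feature_names("CS")
  unknown <- setdiff(unique(tracks$feature),
                     c(cs, "occupancy"))
  if (length(unknown)) {
    abort(sprintf("unknown chromatin feature(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  vals <- purrr::map(setNames(cs, cs), function(f) {
    tr <- tracks[tracks$feature == f, ]
    if (!nrow(tr)) return(rep(NA_real_, nrow(regions)))
    track_values(tr, regions)
  })
  if (normalize == "h3_subtract") {
    h3 <- vals$H3
    for (f in setdiff(cs, "H3")) vals[[f]] <- vals[[f]] - h3
  }
  dplyr::bind_cols(regions, as_tibble(vals))
}

# raw components of the default occupancy score for one sequence:
# GC fraction, 10 bp phase concentration of AA/TT/TA steps, and the
# fraction of bases inside poly(dA:dT) runs (>= 5 bp)
occupancy_components <- function(sequence) {
  code <- encode_bases(sequence)
  n <- sum(!is.na(code))
  if (n == 0L) return(c(gc = NA_real_, period = NA_real_, polyat = NA_real_))
  gc <- sum(code %in% c(2L, 3L)) / n
  # AA/TT/TA step starts and their phase modulo the helical repeat
  steps <- dinuc_steps(sequence)
  at_steps <- which(steps %in% c(1L, 16L, 13L))  # AA, TT, TA
  period <- if (length(at_steps)) {
    phase <- (at_steps - 1L) %% 10L
    max(tabulate(phase + 1L, 10L)) / length(at_steps) - 0.1
  } else 0
  runs <- rle(ifelse(is.na(code), 0L, code))
  polyat_bases <- sum(runs$lengths[runs$lengths >= 5L &
                                     runs$values %in% c(1L, 4L)])
  c(gc = gc, period = period, polyat = polyat_bases / length(code))
}

#' Sequence-intrinsic nucleosome occupancy score
#'
#' A simple, documented default predictor for the intrinsic property
#' model: occupancy rises with GC content and with 10 bp phasing of
#' AA/TT/TA dinucleotides (the helical-repeat periodicity of
#' nucleosome-favoring sequences) and falls with poly(dA:dT) content
#' (runs of >= 5 A or T, which exclude nucleosomes). The three components
#' are z-scored across the supplied cohort of sequences and combined as
#' `z(GC) + z(periodicity) - z(polyAT)`, so the score is a unitless
#' relative ranking within the cohort, higher = more occupied.
#' Alternatively, any precomputed per-probe occupancy track can be used
#' instead via [region_track_value()]; the model evaluation layer only
#' requires an `occupancy` column, not this default formula.
#'
#' @param sequences Character vector of region sequences (nominally
#'   60 bp).
#' @return Numeric vector of occupancy scores (`NA` for all-N input).
#' @export
predict_nucleosome_occupancy <- function(sequences) {
  comp <- t(vapply(sequences, occupancy_components, numeric(3),
                   USE.NAMES = FALSE))
  z <- apply(comp, 2, function(v) {
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s < 1e-12) return(ifelse(is.na(v), NA_real_, 0))
    (v - mean(v, na.rm = TRUE)) / s
  })
  z <- matrix(z, ncol = 3)
  z[, 1] + z[, 2] - z[, 3]
}

#' Occupancy feature for a table of regions
#'
#' Appends an `occupancy` column: from a precomputed occupancy `track`
#' when supplied (pass-through via the probe-coverage rule), otherwise
#' from the sequence-intrinsic default of
#' [predict_nucleosome_occupancy()].
#'
#' @param regions Region tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param track Optional occupancy track tibble.
#' @return `regions` with an `occupancy` column appended.
#' @export
occupancy_feature <- function(regions, genome = NULL, track = NULL) {
  if (!is.null(track)) {
    regions$occupancy <- track_values(track, regions)
    return(regions)
  }
  seqs <- purrr::pmap_chr(regions[c("chrom", "start", "end")],
                          function(chrom, start, end)
                            substr(genome[[chrom]], start + 1L, end))
  regions$occupancy <- predict_nucleosome_occupancy(seqs)
  regions
}
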