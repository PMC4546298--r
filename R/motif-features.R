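# Sequence-motif (SM) features: PWM scanning with log-odds scores and
# exact score p-values computed by dynamic programming over the 0-order
# background, following the log-likelihood-ratio convention of classical
# matrix scanners.

#' 0-order background base composition
#'
#' Estimates the background base probabilities from one or more sequences
#' (the scanned chromosome, typically). Non-ACGT characters are ignored. A
#' small floor keeps all four probabilities positive so log-odds scores
#' stay finite.
#'
#' @param sequences Character vector of sequences, or `NULL` for the
#'   uniform background.
#' @param floor Minimum probability per base before renormalization.
#' @return Named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
base_background <- function(sequences = NULL, floor = 1e-3) {
  if (is.null(sequences)) {
    return(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  }
  chars <- strsplit(paste(toupper(sequences), collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
  p <- pmax(as.numeric(counts) / max(sum(counts), 1), floor)
  setNames(p / sum(p), c("A", "C", "G", "T"))
}

# per-position log2 odds matrix (L x 4) with pseudocount regularization:
# probabilities get `pseudocount` added and are renormalized per position
# before the odds against the background are taken
pwm_log_odds <- function(pwm, background, pseudocount = 1e-3) {
  m <- pwm$matrix + pseudocount
  m <- m / rowSums(m)
  sweep(log2(m), 2, log2(background), `-`)
}

# integer-binned log-odds matrix used by both the DP and the scanner so
# that scan p-values are exactly the DP survival values
pwm_binned_scores <- function(pwm, background, bin_width, pseudocount = 1e-3) {
  s <- pwm_log_odds(pwm, background, pseudocount)
  k <- round(s / bin_width)
  storage.mode(k) <- "integer"
  dimnames(k) <- NULL
  k
}

#' Log-odds score of a single window
#'
#' `score = sum_i log2(pwm[i, base_i] / background[base_i])`, with a
#' pseudocount added to the matrix probabilities (and renormalized) so
#' zero entries score finitely.
#'
#' @param pwm A [pwm_record()].
#' @param window Character scalar of length equal to the motif width.
#' @param background Background base probabilities (default uniform); see
#'   [base_background()].
#' @param pseudocount Probability pseudocount, default `1e-3`.
#' @return Log-odds score in bits; `NA` if the window contains non-ACGT
#'   characters.
#' @export
score_window <- function(pwm, window, background = base_background(),
                         pseudocount = 1e-3) {
  L <- nrow(pwm$matrix)
  code <- encode_bases(window)
  if (length(code) != L) {
    abort(sprintf("window length %d does not match motif width %d",
                  length(code), L))
  }
  if (anyNA(code)) return(NA_real_)
  s <- pwm_log_odds(pwm, background, pseudocount)
  sum(s[cbind(seq_len(L), code)])
}

# A=1 C=2 G=3 T=4, anything else NA
encode_bases <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
}

#' Exact distribution of PWM window scores under the background
#'
#' Computes, by dynamic programming over motif positions, the exact
#' distribution of the (binned) log-odds score of a random window drawn
#' i.i.d. from the 0-order background. The survival function
#' `P(score >= s)` is the scan p-value: the probability that a background
#' window scores at least as high as the observed window.
#'
#' @inheritParams score_window
#' @param bin_width Score discretization in bits, default `1e-3`.
#' @return An object of class `score_distribution`: tibble columns
#'   `score` (bin midpoint, bits), `prob` and `survival`, with the
#'   binning metadata attached.
#' @export
score_pvalue_distribution <- function(pwm, background = base_background(),
                                      bin_width = 1e-3,
                                      pseudocount = 1e-3) {
  assert_scalar_number(bin_width, "bin_width")
  if (bin_width <= 0) abort("`bin_width` must be > 0")
  k <- pwm_binned_scores(pwm, background, bin_width, pseudocount)
  L <- nrow(k)
  # dist[j] = P(partial score == offset + j - 1), in bin units
  dist <- 1
  offset <- 0L
  for (i in seq_len(L)) {
    lo <- min(k[i, ]); hi <- max(k[i, ])
    new <- numeric(length(dist) + (hi - lo))
    for (b in 1:4) {
      shift <- k[i, b] - lo
      idx <- seq_along(dist) + shift
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
    offset <- offset + lo
  }
  keep <- dist > 0
  bins <- offset + which(keep) - 1L
  prob <- dist[keep]
  survival <- rev(cumsum(rev(prob)))
  structure(
    tibble(score = bins * bin_width, prob = prob, survival = survival),
    bins = bins, bin_width = bin_width, offset = offset,
    full_survival = rev(cumsum(rev(dist))),
    class = c("score_distribution", class(tibble()))
  )
}

# p-value of an integer-binned score against a score_distribution;
# scores above the support get p of the top bin's survival floor (0 is
# impossible for achievable scores), below the support get 1
lookup_pvalue <- function(dist, k_int) {
  offset <- attr(dist, "offset")
  sv <- attr(dist, "full_survival")
  idx <- k_int - offset + 1L
  p <- rep(1, length(k_int))
  inside <- !is.na(idx) & idx >= 1L & idx <= length(sv)
  p[inside] <- sv[idx[inside]]
  p[!is.na(idx) & idx > length(sv)] <- 0
  p[is.na(k_int)] <- NA_real_
  p
}

# integer window scores at every start for one strand.
# codes: integer-encoded sequence; k: L x 4 binned score matrix.
windowed_scores <- function(codes, k) {
  L <- nrow(k)
  n_win <- length(codes) - L + 1L
  if (n_win < 1L) return(integer(0))
  total <- rep(0L, n_win)
  na <- rep(FALSE, n_win)
  for (i in seq_len(L)) {
    ci <- codes[i:(i + n_win - 1L)]
    na <- na | is.na(ci)
    ci[is.na(ci)] <- 1L
    total <- total + k[i, ci]
  }
  total[na] <- NA_integer_
  total
}

#' Scan a sequence for motif hits on both strands
#'
#' Every window (forward and reverse strand) whose exact background
#' p-value is below `threshold` is reported as a hit; overlapping hits
#' are not merged. The reverse-strand score of a window equals the
#' forward score of its reverse complement. Windows containing non-ACGT
#' characters are skipped.
#'
#' @inheritParams score_window
#' @param sequence Region sequence to scan (length >= motif width, else
#'   no hits).
#' @param threshold Hit p-value threshold, default `0.001`.
#' @param dist Optional precomputed [score_pvalue_distribution()] for this
#'   PWM/background (computed on the fly otherwise).
#' @param offset Genomic coordinate of the first base of `sequence`
#'   (added to hit starts), default 0.
#' @return Tibble of hits: `start` (0-based), `strand`, `score` (bits),
#'   `pvalue`; zero rows when nothing passes.
#' @export
scan_region <- function(pwm, sequence, background = base_background(),
                        threshold = 0.001, dist = NULL, offset = 0L,
                        pseudocount = 1e-3) {
  if (is.null(dist)) {
    dist <- score_pvalue_distribution(pwm, background,
                                      pseudocount = pseudocount)
  }
  bw <- attr(dist, "bin_width")
  k <- pwm_binned_scores(pwm, background, bw, pseudocount)
  scans <- scan_both_strands(sequence, k, dist)
  hits <- scans[!is.na(scans$pvalue) & scans$pvalue < threshold, ]
  tibble(start = hits$start + as.integer(offset), strand = hits$strand,
         score = hits$k * bw, pvalue = hits$pvalue)
}

# shared scanning core: integer scores + p-values for all starts on both
# strands; reverse strand is scanned by reverse-complementing the score
# matrix, so starts refer to the forward coordinate of the window
scan_both_strands <- function(sequence, k, dist) {
  codes <- encode_bases(sequence)
  L <- nrow(k)
  k_rc <- k[rev(seq_len(L)), c(4L, 3L, 2L, 1L), drop = FALSE]
  fwd <- windowed_scores(codes, k)
  rev_ <- windowed_scores(codes, k_rc)
  n <- length(fwd)
  out <- tibble(
    start = rep(seq_len(n) - 1L, 2L),
    strand = rep(c("+", "-"), each = n),
    k = c(fwd, rev_)
  )
  out$pvalue <- lookup_pvalue(dist, out$k)
  out
}

#' Sequence-motif features of one region
#'
#' The two SM features: `ScerTFhit`, the number of motif occurrences at
#' p < 0.001 (windows passing on both strands at the same start are
#' counted once, keeping the better strand), and `ScerTFpvalue`, the
#' minimum window p-value over the whole region and both strands, whether
#' or not it passes the hit threshold. A region with no scannable window
#' (shorter than the motif, or all N) gets `ScerTFhit = 0`,
#' `ScerTFpvalue = 1`.
#'
#' @inheritParams scan_region
#' @return One-row tibble with `ScerTFhit` (integer) and `ScerTFpvalue`.
#' @export
sm_features <- function(pwm, sequence, background = base_background(),
                        threshold = 0.001, dist = NULL,
                        pseudocount = 1e-3) {
  if (is.null(dist)) {
    dist <- score_pvalue_distribution(pwm, background,
                                      pseudocount = pseudocount)
  }
  k <- pwm_binned_scores(pwm, background, attr(dist, "bin_width"),
                         pseudocount)
  scans <- scan_both_strands(sequence, k, dist)
  p <- scans$pvalue[!is.na(scans$pvalue)]
  if (!length(p)) {
    return(tibble(ScerTFhit = 0L, ScerTFpvalue = 1))
  }
  per_start <- tapply(scans$pvalue, scans$start,
                      function(v) suppressWarnings(min(v, na.rm = TRUE)))
  tibble(
    ScerTFhit = sum(is.finite(per_start) & per_start < threshold),
    ScerTFpvalue = min(p)
  )
}
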