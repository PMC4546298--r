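# Expression-coherence validation: genes whose promoter motif sites all
# fall inside predicted bound regions should be more tightly
# co-expressed than genes whose sites all fall outside.

#' Map promoter motif sites for every gene
#'
#' The promoter is the intergenic sequence immediately upstream of the
#' TSS on the gene's strand, capped at `max_promoter` (1000 bp) and
#' truncated at the neighbouring gene boundary. Each promoter is scanned
#' with the TF's PWM at the hit threshold (p < 0.001).
#'
#' @param annotation Gene annotation tibble (see [read_annotation()]).
#' @param pwm A [pwm_record()].
#' @param genome Named character vector of chromosome sequences.
#' @param background Background base probabilities; default from genome.
#' @param threshold Hit p-value threshold, default 0.001.
#' @param max_promoter Promoter cap in bp, default 1000.
#' @return Tibble of hits: `gene`, `chrom`, `start`, `end` (the motif
#'   window, 0-based half-open), `strand`, `pvalue`. Genes without hits
#'   contribute no rows.
#' @export
map_promoter_sites <- function(annotation, pwm, genome,
                               background = base_background(genome),
                               threshold = 0.001, max_promoter = 1000L) {
  dist <- score_pvalue_distribution(pwm, background)
  L <- nrow(pwm$matrix)
  ann <- dplyr::arrange(annotation, .data$chrom, .data$start)
  purrr::pmap_dfr(
    ann[c("gene", "chrom", "start", "end", "strand")],
    function(gene, chrom, start, end, strand) {
      same <- ann[ann$chrom == chrom & ann$gene != gene, ]
      seqlen <- nchar(genome[[chrom]])
      if (strand == "-") {
        next_start <- suppressWarnings(min(same$start[same$start >= end],
                                           seqlen))
        plo <- end
        phi <- min(end + max_promoter, next_start, seqlen)
      } else {
        prev_end <- suppressWarnings(max(same$end[same$end <= start], 0L))
        plo <- max(start - max_promoter, prev_end, 0L)
        phi <- start
      }
      if (phi - plo < L) return(NULL)
      hits <- scan_region(pwm, substr(genome[[chrom]], plo + 1L, phi),
                          background, threshold, dist, offset = plo)
      if (!nrow(hits)) return(NULL)
      tibble(gene = gene, chrom = chrom, start = hits$start,
             end = hits$start + L, strand = hits$strand,
             pvalue = hits$pvalue)
    }
  )
}

#' Classify genes by containment of their motif sites in bound regions
#'
#' A site counts as "within" a predicted bound region only when the full
#' motif window is contained in the region (a site straddling a boundary
#' is not within). Genes with all sites within are `"bound"`, with none
#' within `"unbound"`, and with a mixture `"ambiguous"` — the ambiguous
#' group is excluded from the coherence analysis. Genes without sites
#' are not classified.
#'
#' @param sites Site tibble from [map_promoter_sites()].
#' @param bound_regions Region tibble of predicted bound regions
#'   (`chrom`, `start`, `end`).
#' @return Tibble `gene`, `n_sites`, `n_within`, `class`.
#' @export
classify_genes <- function(sites, bound_regions) {
  if (!nrow(sites)) {
    return(tibble(gene = character(), n_sites = integer(),
                  n_within = integer(), class = character()))
  }
  within <- vapply(seq_len(nrow(sites)), function(i) {
    any(bound_regions$chrom == sites$chrom[i] &
          bound_regions$start <= sites$start[i] &
          bound_regions$end >= sites$end[i])
  }, logical(1))
  out <- dplyr::summarise(
    dplyr::group_by(tibble(gene = sites$gene, within = within),
                    .data$gene),
    n_sites = dplyr::n(), n_within = sum(.data$within), .groups = "drop"
  )
  out$class <- dplyr::case_when(
    out$n_within == out$n_sites ~ "bound",
    out$n_within == 0L ~ "unbound",
    .default = "ambiguous"
  )
  out
}

#' Maximal single-time-lag absolute Spearman correlation
#'
#' The co-expression statistic for a gene pair: the Spearman correlation
#' is evaluated with one profile shifted by -1, 0 and +1 time points
#' (edges truncated, so lagged overlaps have `n - 1` points), and the
#' maximum absolute value over the three lags is returned, so activation
#' and repression count equally. Lags on which either overlapping series
#' is constant are undefined and skipped; the value is missing when all
#' three lags are undefined.
#'
#' @param x,y Numeric expression time series of equal length (>= 4 so
#'   every lag keeps >= 3 points).
#' @return Value in `[0, 1]`, or `NA`.
#' @export
max_lag_spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("series must have equal length")
  if (n < 4L) abort("need >= 4 time points so every lag keeps >= 3")
  rho <- suppressWarnings(c(
    cor(x, y, method = "spearman"),
    cor(x[-n], y[-1L], method = "spearman"),
    cor(x[-1L], y[-n], method = "spearman")
  ))
  rho <- rho[!is.na(rho)]
  if (!length(rho)) return(NA_real_)
  max(abs(rho))
}

# all within-set pairwise max-lag |Spearman| values, vectorized via
# three rank-correlation matrices (lag 0, +1, -1)
pairwise_max_lag <- function(m) {
  n <- ncol(m)
  c0 <- suppressWarnings(cor(t(m), method = "spearman"))
  cp <- suppressWarnings(cor(t(m[, -n, drop = FALSE]),
                             t(m[, -1L, drop = FALSE]),
                             method = "spearman"))
  idx <- which(upper.tri(c0), arr.ind = TRUE)
  vals <- pmax(abs(c0[idx]), abs(cp[idx]), abs(cp[idx[, c(2, 1)]]),
               na.rm = TRUE)
  vals[is.infinite(vals)] <- NA_real_
  vals
}

#' Coherence test of bound versus unbound gene sets
#'
#' Computes all within-set pairwise [max_lag_spearman()] values for the
#' bound and unbound gene sets (pairs with undefined correlation are
#' dropped) and compares the two distributions with a one-sided
#' two-sample Kolmogorov-Smirnov test of the alternative that bound-set
#' correlations are stochastically larger. Both sets must have at least
#' `min_genes` (10) members.
#'
#' @param bound_genes,unbound_genes Character vectors of gene ids.
#' @param expression Expression tibble (see [read_expression()]).
#' @param min_genes Minimum set size, default 10.
#' @return A `coherence_result`: `within_bound`, `within_unbound`
#'   (pairwise correlation values), `ks_pvalue`, set sizes.
#' @export
coherence_test <- function(bound_genes, unbound_genes, expression,
                           min_genes = 10L) {
  if (length(bound_genes) < min_genes || length(unbound_genes) < min_genes) {
    abort(sprintf(
      "coherence test needs >= %d genes per set (have %d bound, %d unbound)",
      min_genes, length(bound_genes), length(unbound_genes)))
  }
  m <- expression_matrix(expression)
  missing_genes <- setdiff(c(bound_genes, unbound_genes), rownames(m))
  if (length(missing_genes)) {
    abort(sprintf("genes absent from expression matrix: %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  if (ncol(m) < 4L) abort("need >= 4 time points")
  wb <- pairwise_max_lag(m[bound_genes, , drop = FALSE])
  wu <- pairwise_max_lag(m[unbound_genes, , drop = FALSE])
  wb <- wb[!is.na(wb)]; wu <- wu[!is.na(wu)]
  # one-sided KS: alternative "bound stochastically larger", i.e. the
  # bound CDF lies below the unbound CDF. The exact conditional null
  # distribution of the one-sided Smirnov statistic is used where
  # feasible; the asymptotic formula is visibly anticonservative at
  # these sample sizes.
  ks <- suppressWarnings(ks.test(wb, wu, alternative = "less"))
  p <- if (length(wb) * length(wu) <= 4e6) {
    stats::psmirnov(unname(ks$statistic) - 1e-12,
                    sizes = c(length(wb), length(wu)),
                    two.sided = FALSE, exact = TRUE, lower.tail = FALSE)
  } else {
    ks$p.value
  }
  structure(
    list(within_bound = wb, within_unbound = wu,
         ks_pvalue = p,
         n_bound = length(bound_genes), n_unbound = length(unbound_genes)),
    class = "coherence_result"
  )
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf(
    "<coherence_result> %d bound / %d unbound genes; mean |rho| %.3f vs %.3f; one-sided KS p = %.3g\n",
    x$n_bound, x$n_unbound, mean(x$within_bound), mean(x$within_unbound),
    x$ks_pvalue))
  invisible(x)
}

#' @describeIn coherence_test One row per gene pair with its set and
#'   correlation value.
#' @param x,object A `coherence_result`.
#' @param ... Unused.
#' @method tidy coherence_result
#' @export
tidy.coherence_result <- function(x, ...) {
  tibble(
    set = rep(c("bound", "unbound"),
              c(length(x$within_bound), length(x$within_unbound))),
    correlation = c(x$within_bound, x$within_unbound)
  )
}

#' @describeIn coherence_test One-row summary with mean correlations and
#'   the KS p-value.
#' @method glance coherence_result
#' @export
glance.coherence_result <- function(x, ...) {
  tibble(
    n_bound = x$n_bound, n_unbound = x$n_unbound,
    mean_bound = mean(x$within_bound),
    mean_unbound = mean(x$within_unbound),
    ks_pvalue = x$ks_pvalue
  )
}

#' Promoter-to-coherence pipeline for one TF
#'
#' Composes [map_promoter_sites()], [classify_genes()] and
#' [coherence_test()]: maps promoter motif sites, classifies genes by
#' containment of their sites in the predicted bound regions, and tests
#' co-expression coherence of the resulting bound versus unbound gene
#' sets.
#'
#' @inheritParams map_promoter_sites
#' @param bound_regions Predicted bound-region tibble.
#' @param expression Expression tibble.
#' @param min_genes Minimum genes per set, default 10.
#' @return A `coherence_result` with the gene classification attached as
#'   attribute `"gene_sets"`.
#' @export
coherence_pipeline <- function(annotation, pwm, genome, bound_regions,
                               expression,
                               background = base_background(genome),
                               threshold = 0.001, min_genes = 10L) {
  sites <- map_promoter_sites(annotation, pwm, genome, background,
                              threshold)
  classes <- classify_genes(sites, bound_regions)
  res <- coherence_test(classes$gene[classes$class == "bound"],
                        classes$gene[classes$class == "unbound"],
                        expression, min_genes)
  attr(res, "gene_sets") <- classes
  res
}
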