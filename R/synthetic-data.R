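# Synthetic-data generators. Every input the pipeline consumes can be
# generated with the statistical structure the analysis assumes: a genome
# with planted motif instances, bound regions with depleted H3 and
# elevated modification signal, a block-correlated dinucleotide property
# table, and co-regulated expression modules. Effect sizes are
# standardized mean shifts between bound and unbound regions.

#' Configuration for the synthetic study
#'
#' Bundles every tunable of the generators. The defaults describe the
#' emulated study conditions: a yeast-like background (GC 0.38), 60 bp
#' analysis regions, probes of 75-300 bp, 100 bound and 100 unbound
#' regions per TF, bound regions depleted of histone H3 and enriched for
#' activating marks at standardized effect size 1.5, and co-expression
#' modules with within-module Spearman correlation 0.9 over 18 time
#' points.
#'
#' @param genome_length Genome length in bases.
#' @param gc_content Fraction of G+C in the background sequence.
#' @param n_tfs Number of TFs to simulate.
#' @param motif_length Planted motif width in bases.
#' @param n_bound_per_tf,n_unbound_per_tf Regions per class per TF.
#' @param effect_sizes Named numeric vector, feature name to standardized
#'   mean shift (bound minus unbound); names must be among the 23 model
#'   features or `"occupancy"`. Negative H3 encodes nucleosome depletion
#'   of bound regions.
#' @param tf_group_profiles Optional named list, TF to the feature
#'   families (`"SM"`, `"CS"`, `"DS"`) that carry signal for that TF;
#'   families not listed have their effects zeroed, emulating TF groups
#'   that are predictable from only some families.
#' @param n_genes Number of genes in the annotation / expression matrix.
#' @param n_timepoints Expression time points (>= 3).
#' @param module_rho Target within-module pairwise Spearman correlation.
#' @param lag_fraction Fraction of module genes whose profile is shifted
#'   by one time point.
#' @param seed Integer master seed; all generators derive their streams
#'   from it and are bit-reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = 200000L,
                             gc_content = 0.38,
                             n_tfs = 3L,
                             motif_length = 8L,
                             n_bound_per_tf = 100L,
                             n_unbound_per_tf = 100L,
                             effect_sizes = c(
                               H3 = -1.5, H3K4me1 = 1.5, H3K9ac = 1.5,
                               H4ac = 1.5, H3K14ac = 1.0, H3K4me3 = 1.0,
                               PC1 = 1.0, PC2 = 1.0, occupancy = -1.0
                             ),
                             tf_group_profiles = NULL,
                             n_genes = 60L,
                             n_timepoints = 18L,
                             module_rho = 0.9,
                             lag_fraction = 0.2,
                             seed = 1L) {
  genome_length <- assert_count(genome_length, "genome_length")
  n_tfs <- assert_count(n_tfs, "n_tfs")
  motif_length <- assert_count(motif_length, "motif_length")
  n_bound_per_tf <- assert_count(n_bound_per_tf, "n_bound_per_tf", min = 0L)
  n_unbound_per_tf <- assert_count(n_unbound_per_tf, "n_unbound_per_tf",
                                   min = 0L)
  n_genes <- assert_count(n_genes, "n_genes")
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 3L)
  assert_scalar_number(gc_content, "gc_content", 0, 1)
  assert_scalar_number(module_rho, "module_rho", 0, 1)
  assert_scalar_number(lag_fraction, "lag_fraction", 0, 1)
  seed <- assert_count(seed, "seed", min = 0L)
  bad <- setdiff(names(effect_sizes), c(feature_names(), "occupancy"))
  if (length(bad)) {
    abort(sprintf("effect_sizes names not among the model features: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(
    list(genome_length = genome_length, gc_content = gc_content,
         n_tfs = n_tfs, motif_length = motif_length,
         n_bound_per_tf = n_bound_per_tf,
         n_unbound_per_tf = n_unbound_per_tf,
         effect_sizes = effect_sizes,
         tf_group_profiles = tf_group_profiles,
         n_genes = n_genes, n_timepoints = n_timepoints,
         module_rho = module_rho, lag_fraction = lag_fraction,
         seed = seed),
    class = "synthetic_config"
  )
}

#' Generate a background genome with gene annotation
#'
#' Background sequence is i.i.d. with the configured GC content (the
#' simplest null consistent with the 0-order PWM background). Genes are
#' laid out on one chromosome with alternating strands and at least one
#' intergenic base between neighbours.
#'
#' @param config A [synthetic_config()].
#' @return List with `genome` (named character vector, one chromosome
#'   `"chrS"`) and `annotation` (tibble as from [read_annotation()]).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqc <- paste(sample(names(p), L, replace = TRUE, prob = p),
                collapse = "")
  n <- config$n_genes
  pitch <- L %/% n
  gene_len <- max(2L, as.integer(floor(pitch * 0.7)))
  if (pitch - gene_len < 1L || pitch < 3L) {
    abort(sprintf("genome of %d bases too short for %d genes", L, n))
  }
  start <- (seq_len(n) - 1L) * pitch + (pitch - gene_len) %/% 2L
  strand <- rep(c("+", "-"), length.out = n)
  tibble_ann <- tibble(
    gene = sprintf("gene%03d", seq_len(n)),
    chrom = "chrS",
    start = start, end = start + gene_len, strand = strand,
    tss = ifelse(strand == "-", start + gene_len - 1L, start)
  )
  list(genome = c(chrS = seqc), annotation = tibble_ann)
}

# consensus sequence (argmax base per position) of a PWM
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$matrix, 1, which.max)],
        collapse = "")
}

#' Plant TF binding regions and probe intervals into a genome
#'
#' Chooses non-overlapping 60 bp regions, writes the PWM consensus into
#' the center of each bound region (unbound regions keep background
#' sequence, so they carry hits only at the background rate), and emits
#' ChIP-chip style probe intervals of 75-300 bp fully covering each
#' region, with higher signal for bound probes.
#'
#' @param genome Named character vector (modified copy is returned).
#' @param pwm A [pwm_record()] for the TF.
#' @param config A [synthetic_config()].
#' @param tf TF identifier; defaults to `pwm$tf`.
#' @param slot Integer >= 0 selecting a disjoint placement stream so that
#'   several TFs can be planted into one genome without overlap.
#' @return List with `genome` (sequence with planted motifs), `regions`
#'   (60 bp truth tibble: `chrom`, `start`, `end`, `tf`, `label`,
#'   `signal`) and `probes` (probe tibble with the same columns).
#' @export
plant_binding_regions <- function(genome, pwm, config, tf = pwm$tf,
                                  slot = 0L) {
  set.seed(config$seed + 7L * (slot + 1L))
  n_b <- config$n_bound_per_tf
  n_u <- config$n_unbound_per_tf
  n <- n_b + n_u
  chrom <- names(genome)[1]
  L <- nchar(genome[[chrom]])
  pitch <- 400L
  slots <- seq(300L, L - 360L, by = pitch)
  n_slots_per_tf <- length(slots) %/% max(1L, config$n_tfs)
  mine <- slots[seq_len(n_slots_per_tf) + slot * n_slots_per_tf]
  if (n > length(mine)) {
    abort(sprintf("cannot place %d non-overlapping regions (have %d slots)",
                  n, length(mine)))
  }
  starts <- sort(sample(mine, n))
  label <- sample(rep(c("bound", "unbound"), c(n_b, n_u)))
  regions <- tibble(
    chrom = chrom, start = starts, end = starts + 60L,
    tf = tf, label = label,
    signal = rnorm(n, mean = ifelse(label == "bound", 5, 1), sd = 1)
  )
  consensus <- pwm_consensus(pwm)
  ml <- nchar(consensus)
  seqc <- genome[[chrom]]
  for (i in which(label == "bound")) {
    at <- starts[i] + (60L - ml) %/% 2L  # 0-based insert position
    substr(seqc, at + 1L, at + ml) <- consensus
  }
  genome[[chrom]] <- seqc
  if (n > 0L) {
    plen <- as.integer(round(runif(n, 75, 300)))
    upmax <- pmax(0L, plen - 60L)
    pstart <- pmax(0L, regions$start - as.integer(floor(runif(n) * (upmax + 1))))
    probes <- tibble(
      chrom = chrom, start = pstart,
      end = pmin(L, pstart + plen),
      tf = tf, label = label, signal = regions$signal
    )
  } else {
    probes <- regions
  }
  list(genome = genome, regions = regions, probes = probes)
}

#' Simulate chromatin-state signal tracks over a genome tiling
#'
#' Chromatin state is a property of the locus, so the generator tiles
#' the whole chromosome with non-overlapping 150 bp probes and gives
#' each probe, per chromatin feature, a unit-variance Gaussian signal
#' whose mean is shifted by the configured effect size when the probe
#' overlaps a bound region by more than half of that region (the same
#' coverage rule the extractor uses, so a 60 bp analysis region is read
#' from exactly one qualifying probe and the planted standardized shift
#' is preserved). Signals are emitted directly on the H3-normalized
#' scale (extract with `normalize = "none"`); a negative H3 effect
#' encodes nucleosome depletion of bound regions. All 11 CS features are
#' emitted; features without a configured effect get shift 0.
#'
#' @param regions Truth region tibble with `chrom`, `start`, `end`,
#'   `label` (the planted 60 bp regions).
#' @param config A [synthetic_config()] (supplies the genome length and
#'   seed).
#' @param effects Named vector of per-feature shifts; defaults to the CS
#'   entries of `config$effect_sizes`. Names must be CS feature names.
#' @param probe_length Tiling probe length, default 150.
#' @return Track tibble (`feature`, `chrom`, `start`, `end`, `value`)
#'   covering the genome for every CS feature.
#' @export
simulate_chromatin_tracks <- function(regions, config, effects = NULL,
                                      probe_length = 150L) {
  cs <- feature_names("CS")
  if (is.null(effects)) {
    effects <- config$effect_sizes[names(config$effect_sizes) %in% cs]
  }
  unknown <- setdiff(names(effects), cs)
  if (length(unknown)) {
    abort(sprintf("unknown chromatin feature(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  set.seed(config$seed + 101L)
  shift <- setNames(rep(0, length(cs)), cs)
  shift[names(effects)] <- effects
  L <- config$genome_length
  starts <- seq(0L, max(0L, L - 1L), by = probe_length)
  ends <- pmin(L, starts + probe_length)
  chrom <- if (nrow(regions)) regions$chrom[1] else "chrS"
  # mark tiles overlapping a bound region by more than half the region
  is_bound_tile <- rep(FALSE, length(starts))
  bound <- regions[regions$label == "bound", ]
  for (i in seq_len(nrow(bound))) {
    overlap <- pmin(ends, bound$end[i]) - pmax(starts, bound$start[i])
    is_bound_tile <- is_bound_tile |
      overlap > (bound$end[i] - bound$start[i]) / 2
  }
  purrr::map_dfr(cs, function(f) {
    tibble(
      feature = f, chrom = chrom, start = starts, end = ends,
      value = rnorm(length(starts)) + shift[[f]] * is_bound_tile
    )
  })
}

#' Generate a block-correlated dinucleotide property table
#'
#' Stand-in for a DiProDB-style table of conformational and thermodynamic
#' dinucleotide properties: properties within a block share a latent
#' 16-vector (strong within-block correlation), latents of different
#' blocks are constructed orthogonal (weak across-block correlation).
#' Property names carry their block tag (`blk<i>_prop<j>`) so component
#' annotation is checkable.
#'
#' @param n_properties Total number of properties (default 125).
#' @param n_blocks Number of correlated blocks (default 5);
#'   `n_properties >= n_blocks >= 1`.
#' @param seed Integer seed.
#' @param within Latent weight in `[0, 1)` controlling within-block
#'   correlation (~`within` itself), default 0.9.
#' @return Dinucleotide property tibble (16 rows).
#' @export
generate_dinuc_property_table <- function(n_properties = 125L,
                                          n_blocks = 5L, seed = 1L,
                                          within = 0.9) {
  n_properties <- assert_count(n_properties, "n_properties")
  n_blocks <- assert_count(n_blocks, "n_blocks")
  if (n_properties < n_blocks) abort("n_properties must be >= n_blocks")
  assert_scalar_number(within, "within", 0, 1)
  set.seed(seed)
  # orthonormal centered latents so across-block correlation is ~0
  raw <- matrix(rnorm(16L * n_blocks), 16L, n_blocks)
  raw <- sweep(raw, 2, colMeans(raw))
  latents <- qr.Q(qr(raw)) * sqrt(15)  # unit sample variance columns
  # unequal block sizes separate the eigenvalues, so each component
  # aligns with one block instead of mixing near-degenerate ones
  w <- rev(seq_len(n_blocks))
  sizes <- pmax(1L, as.integer(floor(n_properties * w / sum(w))))
  while (sum(sizes) > n_properties) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  sizes[1] <- sizes[1] + (n_properties - sum(sizes))
  block_of <- rep(seq_len(n_blocks), times = sizes)
  vals <- vapply(seq_len(n_properties), function(j) {
    b <- block_of[j]
    sgn <- sample(c(-1, 1), 1)
    sgn * (sqrt(within) * latents[, b] +
             sqrt(1 - within) * rnorm(16L))
  }, numeric(16L))
  counter <- stats::ave(block_of, block_of, FUN = seq_along)
  colnames(vals) <- sprintf("blk%d_prop%03d", block_of, counter)
  dplyr::bind_cols(tibble(dinucleotide = DINUCLEOTIDES), as_tibble(vals))
}

#' Simulate a co-expressed module in an expression time course
#'
#' Genes in the bound set share a latent smooth profile mixed so that
#' within-pair Spearman correlation is approximately `module_rho`
#' (Gaussian-copula calibration: pairwise Pearson `2*sin(pi*rho/6)`
#' yields Spearman `rho`); a `lag_fraction` of module genes use the
#' latent profile shifted by exactly one time point. Unbound genes are
#' independent noise.
#'
#' @param config A [synthetic_config()].
#' @param gene_sets Named list with character vectors `bound` and
#'   `unbound` of gene identifiers.
#' @return Expression tibble: `gene` column plus `t1..tT` numeric
#'   columns.
#' @export
simulate_expression <- function(config, gene_sets) {
  stopifnot(is.list(gene_sets), all(c("bound", "unbound") %in%
                                      names(gene_sets)))
  set.seed(config$seed + 211L)
  tt <- config$n_timepoints
  rho <- config$module_rho
  r_pair <- 2 * sin(pi * rho / 6)
  a <- sqrt(r_pair)
  # smooth latent with one extra leading point for the lagged genes
  z <- as.numeric(scale(cumsum(rnorm(tt + 1L))))
  bound <- gene_sets$bound
  unbound <- gene_sets$unbound
  lagged <- rbinom(length(bound), 1L, config$lag_fraction) == 1L
  profiles <- lapply(seq_along(bound), function(i) {
    zi <- if (lagged[i]) z[seq_len(tt)] else z[seq_len(tt) + 1L]
    a * zi + sqrt(1 - a^2) * rnorm(tt)
  })
  noise <- lapply(seq_along(unbound), function(i) rnorm(tt))
  m <- do.call(rbind, c(profiles, noise))
  colnames(m) <- paste0("t", seq_len(tt))
  dplyr::bind_cols(tibble(gene = c(bound, unbound)), as_tibble(m))
}

#' Simulate a feature-level binding dataset
#'
#' Generates the 23-feature matrix (plus `occupancy`) for one TF directly
#' on the standardized feature scale: every feature is unit-variance
#' Gaussian, and bound rows are shifted by the configured effect size.
#' `tf_group_profiles` restricts which feature families carry signal for
#' a given TF, emulating TF groups predictable from only chromatin or
#' only structure features.
#'
#' @param config A [synthetic_config()].
#' @param tf TF identifier (also selects the group profile and the
#'   random stream).
#' @param tf_index Integer >= 1 separating random streams of different
#'   TFs.
#' @return Tibble with `tf`, `label` and the 23 + 1 feature columns.
#' @export
simulate_binding_dataset <- function(config, tf = "TF1", tf_index = 1L) {
  set.seed(config$seed + 1000L + tf_index)
  n_b <- config$n_bound_per_tf
  n_u <- config$n_unbound_per_tf
  feats <- c(feature_names(), "occupancy")
  shift <- setNames(rep(0, length(feats)), feats)
  eff <- config$effect_sizes
  shift[names(eff)] <- eff
  profile <- config$tf_group_profiles[[tf]]
  if (!is.null(profile)) {
    keep <- unlist(lapply(profile, function(fam) {
      if (fam == "SM") feature_names("SM")
      else if (fam == "CS") c(feature_names("CS"))
      else if (fam == "DS") c(feature_names("DS"), "occupancy")
      else abort(sprintf("unknown feature family '%s'", fam))
    }))
    shift[setdiff(feats, keep)] <- 0
  }
  label <- rep(c("bound", "unbound"), c(n_b, n_u))
  vals <- vapply(feats, function(f) {
    rnorm(n_b + n_u) + shift[[f]] * (label == "bound")
  }, numeric(n_b + n_u))
  dplyr::bind_cols(tibble(tf = tf, label = label), as_tibble(vals))
}
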