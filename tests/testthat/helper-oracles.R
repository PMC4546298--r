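# Shared fixtures and independent oracles used across the test files.

# random PWM with one dominant base per position (sharpness ~ concentration)
rand_pwm <- function(L, seed, sharp = 0.9, tf = "TF") {
  set.seed(seed)
  m <- matrix(runif(4 * L, 0.01, 1), L, 4)
  top <- sample(4, L, replace = TRUE)
  m[cbind(seq_len(L), top)] <- m[cbind(seq_len(L), top)] + sharp * 10
  pwm_record(m / rowSums(m), tf = tf)
}

random_seq <- function(n, seed = NULL, prob = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# brute-force survival function of the binned window score: enumerate all
# 4^L windows, score each with its own log-odds computation, and count
brute_survival <- function(pwm, background, bin_width = 1e-3,
                           pseudocount = 1e-3) {
  L <- nrow(pwm$matrix)
  m <- pwm$matrix + pseudocount
  m <- m / rowSums(m)
  lo <- log2(m) - matrix(log2(background), L, 4, byrow = TRUE)
  k <- round(lo / bin_width)
  grids <- do.call(expand.grid, rep(list(1:4), L))
  score <- numeric(nrow(grids))
  prob <- rep(1, nrow(grids))
  for (i in seq_len(L)) {
    score <- score + k[i, grids[[i]]]
    prob <- prob * background[grids[[i]]]
  }
  agg <- stats::aggregate(prob, list(k = score), sum)
  agg <- agg[order(agg$k), ]
  agg$survival <- rev(cumsum(rev(agg$x)))
  agg
}

# exhaustive pair-counting auROC (ties count one half)
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == "bound"]
  neg <- scores[labels != "bound"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# per-step PC scores computed from the raw property table, independent
# of the model's precomputed dinucleotide score matrix
naive_pc_scores <- function(sequence, table, model) {
  x <- as.matrix(table[setdiff(names(table), "dinucleotide")])
  rownames(x) <- table$dinucleotide
  x <- x[, names(model$property_means), drop = FALSE]
  z <- sweep(sweep(x, 2, model$property_means), 2,
             model$property_scales, `/`)
  chars <- strsplit(sequence, "")[[1]]
  steps <- paste0(chars[-length(chars)], chars[-1])
  steps <- steps[steps %in% rownames(x)]
  colMeans(z[steps, , drop = FALSE] %*% model$loadings)
}

# brute-force interval overlap: mean of probe values overlapping a
# region by strictly more than half its length
overlap_oracle <- function(probes, chrom, start, end) {
  vals <- c()
  for (i in seq_len(nrow(probes))) {
    if (probes$chrom[i] != chrom) next
    ov <- min(probes$end[i], end) - max(probes$start[i], start)
    if (ov > (end - start) / 2) vals <- c(vals, probes$value[i])
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# small feature-level dataset with a configurable planted effect
toy_dataset <- function(n = 100, effects = c(H3 = -1.5), seed = 1,
                        tf = "TF1") {
  cfg <- synthetic_config(n_bound_per_tf = n, n_unbound_per_tf = n,
                          effect_sizes = effects, seed = seed)
  simulate_binding_dataset(cfg, tf = tf)
}
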