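test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(gc_content = 1.5), "gc_content")
  expect_error(synthetic_config(module_rho = -0.1), "module_rho")
  expect_error(synthetic_config(n_timepoints = 2), "n_timepoints")
  expect_error(synthetic_config(effect_sizes = c(NotAFeature = 1)),
               "effect_sizes")
})

test_that("genome generation is deterministic with the stated GC", {
  cfg <- synthetic_config(genome_length = 10000, seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1$genome[["chrS"]]), 10000L)

  pure <- generate_genome(synthetic_config(genome_length = 2000,
                                           gc_content = 1, seed = 2))
  expect_true(grepl("^[GC]+$", pure$genome[["chrS"]]))

  big <- generate_genome(synthetic_config(genome_length = 1000000,
                                          gc_content = 0.38, seed = 3))
  chars <- strsplit(big$genome[["chrS"]], "")[[1]]
  expect_lt(abs(mean(chars %in% c("G", "C")) - 0.38), 0.01)
})

test_that("annotation leaves at least one intergenic base between genes", {
  cfg <- synthetic_config(genome_length = 60000, n_genes = 50, seed = 4)
  ann <- generate_genome(cfg)$annotation
  expect_equal(nrow(ann), 50L)
  gaps <- ann$start[-1] - ann$end[-nrow(ann)]
  expect_true(all(gaps >= 1))
  expect_error(generate_genome(synthetic_config(genome_length = 50,
                                                n_genes = 40)),
               "too short")
})

test_that("planted bound regions are recovered by rescanning", {
  cfg <- synthetic_config(genome_length = 120000, n_tfs = 1,
                          n_bound_per_tf = 50, n_unbound_per_tf = 50,
                          seed = 5)
  g <- generate_genome(cfg)
  pwm <- rand_pwm(8, seed = 5, sharp = 2)
  pl <- plant_binding_regions(g$genome, pwm, cfg)
  bg <- base_background(pl$genome)
  dist <- score_pvalue_distribution(pwm, bg)
  bound <- pl$regions[pl$regions$label == "bound", ]
  hit_rate <- mean(vapply(seq_len(nrow(bound)), function(i) {
    s <- substr(pl$genome[["chrS"]], bound$start[i] + 1L, bound$end[i])
    nrow(scan_region(pwm, s, bg, dist = dist)) >= 1
  }, logical(1)))
  expect_gte(hit_rate, 0.95)

  # determinism: identical BED output byte for byte
  pl2 <- plant_binding_regions(g$genome, pwm, cfg)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_regions(pl$regions, f1)
  write_regions(pl2$regions, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an empty positive set still yields a valid probe table", {
  cfg <- synthetic_config(genome_length = 60000, n_tfs = 1,
                          n_bound_per_tf = 0, n_unbound_per_tf = 20,
                          seed = 6)
  g <- generate_genome(cfg)
  pl <- plant_binding_regions(g$genome, rand_pwm(8, seed = 6), cfg)
  expect_equal(sum(pl$regions$label == "bound"), 0L)
  expect_equal(nrow(pl$probes), 20L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions(pl$probes, path)
  expect_equal(nrow(read_regions(path)), 20L)
})

test_that("probe lengths stay in the 75-300 bp range and cover regions", {
  cfg <- synthetic_config(genome_length = 120000, n_tfs = 1,
                          n_bound_per_tf = 60, n_unbound_per_tf = 60,
                          seed = 7)
  g <- generate_genome(cfg)
  pl <- plant_binding_regions(g$genome, rand_pwm(8, seed = 7), cfg)
  len <- pl$probes$end - pl$probes$start
  expect_true(all(len >= 75 & len <= 300))
  overlap <- pmin(pl$probes$end, pl$regions$end) -
    pmax(pl$probes$start, pl$regions$start)
  expect_true(all(overlap > 30))
})

test_that("track effects are recoverable by the rank-sum comparison", {
  cfg <- synthetic_config(genome_length = 180000, n_tfs = 1,
                          n_bound_per_tf = 200, n_unbound_per_tf = 200,
                          effect_sizes = c(H3 = -1.0), seed = 8)
  g <- generate_genome(cfg)
  pl <- plant_binding_regions(g$genome, rand_pwm(8, seed = 8), cfg)
  tracks <- simulate_chromatin_tracks(pl$regions, cfg)
  f <- extract_cs_features(pl$regions, tracks, normalize = "none")
  p <- stats::wilcox.test(f$H3[f$label == "bound"],
                          f$H3[f$label == "unbound"],
                          alternative = "less")$p.value
  expect_lt(p, 0.01)
  # untouched features carry no signal
  p_null <- stats::wilcox.test(f$H3K79me3[f$label == "bound"],
                               f$H3K79me3[f$label == "unbound"])$p.value
  expect_gt(p_null, 0.001)
})

test_that("a strong single-feature effect reaches its analytic AUC", {
  cfg <- synthetic_config(genome_length = 280000, n_tfs = 1,
                          n_bound_per_tf = 300, n_unbound_per_tf = 300,
                          effect_sizes = c(H3K4me1 = 2.0), seed = 9)
  g <- generate_genome(cfg)
  pl <- plant_binding_regions(g$genome, rand_pwm(8, seed = 9), cfg)
  tracks <- simulate_chromatin_tracks(pl$regions, cfg)
  f <- extract_cs_features(pl$regions, tracks, normalize = "none")
  expect_gt(auroc(f$H3K4me1, f$label), 0.9)
})

test_that("dinucleotide table generation is deterministic", {
  t1 <- generate_dinuc_property_table(30, 3, seed = 10)
  t2 <- generate_dinuc_property_table(30, 3, seed = 10)
  expect_identical(t1, t2)
  expect_error(generate_dinuc_property_table(0, 1), "n_properties")
  expect_error(generate_dinuc_property_table(3, 5), ">= n_blocks")
})

test_that("expression modules reach the requested coherence", {
  cfg <- synthetic_config(n_timepoints = 18, module_rho = 0.9,
                          lag_fraction = 0.2, seed = 11)
  gs <- list(bound = sprintf("b%02d", 1:20),
             unbound = sprintf("u%02d", 1:20))
  ex <- simulate_expression(cfg, gs)
  expect_identical(ex, simulate_expression(cfg, gs))
  res <- coherence_test(gs$bound, gs$unbound, ex)
  expect_lt(res$ks_pvalue, 0.01)
  expect_gt(mean(res$within_bound), mean(res$within_unbound))
})

test_that("group profiles silence the excluded feature families", {
  cfg <- synthetic_config(
    n_bound_per_tf = 400, n_unbound_per_tf = 400,
    effect_sizes = c(H3 = -1.5, PC1 = 1.5, ScerTFhit = 1.5),
    tf_group_profiles = list(TF1 = c("CS")),
    seed = 12
  )
  d <- simulate_binding_dataset(cfg, tf = "TF1")
  expect_lt(auroc(d$PC1, d$label), 0.56)
  expect_lt(auroc(d$ScerTFhit, d$label), 0.56)
  expect_gt(auroc(-d$H3, d$label), 0.8)
})
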