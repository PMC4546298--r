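uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("refinement centers the 60 bp region on the best hit midpoint", {
  pwm <- rand_pwm(8, seed = 1, sharp = 2)
  cons <- chromabind:::pwm_consensus(pwm)
  g <- random_seq(3000, seed = 2)
  substr(g, 1001, 1008) <- cons  # planted at 0-based position 1000
  genome <- c(chrS = g)
  probes <- tibble::tibble(chrom = "chrS", start = 950L, end = 1100L)
  r <- refine_regions(probes, pwm, genome, uniform_bg)
  expect_equal(r$start, 974L)
  expect_equal(r$end, 1034L)
  expect_false(r$clipped)
})

test_that("equal-score hits break ties to the leftmost", {
  pwm <- rand_pwm(8, seed = 3, sharp = 2)
  cons <- chromabind:::pwm_consensus(pwm)
  g <- paste0(random_seq(200, seed = 4), cons, random_seq(100, seed = 5),
              cons, random_seq(200, seed = 6))
  genome <- c(chrS = g)
  probes <- tibble::tibble(chrom = "chrS", start = 180L, end = 340L)
  r <- refine_regions(probes, pwm, genome, uniform_bg)
  expect_equal(r$start, 200L + 4L - 30L)
})

test_that("refinement falls back to the probe midpoint and clips at edges", {
  pwm <- rand_pwm(6, seed = 7, sharp = 2)
  genome <- c(chrS = strrep("N", 500))
  probes <- tibble::tibble(chrom = "chrS", start = 100L, end = 200L)
  r <- refine_regions(probes, pwm, genome, uniform_bg)
  expect_equal(r$start, 150L - 30L)

  # probe at the chromosome start still yields a 60 bp region
  edge <- tibble::tibble(chrom = "chrS", start = 0L, end = 20L)
  re <- refine_regions(edge, pwm, genome, uniform_bg,
                       centering = "midpoint")
  expect_equal(re$start, 0L)
  expect_equal(re$end - re$start, 60L)
  expect_false(re$clipped)

  # chromosome shorter than 60 bp: clipped and flagged
  short <- c(chrS = strrep("A", 40))
  rs <- refine_regions(tibble::tibble(chrom = "chrS", start = 5L,
                                      end = 20L),
                       pwm, short, uniform_bg, centering = "midpoint")
  expect_true(rs$clipped)
})

test_that("negative selection takes the lowest signals with stable ties", {
  probes <- tibble::tibble(
    chrom = "chrS", start = c(10L, 20L, 30L), end = c(70L, 80L, 90L),
    label = "unbound", signal = c(5, 1, 3)
  )
  sel <- select_negatives(probes, 2)
  expect_equal(sel$signal, c(1, 3))
  expect_equal(nrow(select_negatives(probes, 0)), 0L)
  expect_error(select_negatives(probes, 4), "unbound")

  ties <- tibble::tibble(chrom = "chrS", start = c(30L, 10L, 20L),
                         end = c(90L, 70L, 80L), label = "unbound",
                         signal = c(1, 1, 1))
  expect_equal(select_negatives(ties, 2)$start, c(10L, 20L))
})

make_pipeline_fixture <- function(n_bound, n_unbound, seed) {
  cfg <- synthetic_config(genome_length = 150000, n_tfs = 1,
                          n_bound_per_tf = n_bound,
                          n_unbound_per_tf = n_unbound, seed = seed)
  g <- generate_genome(cfg)
  pwm <- rand_pwm(8, seed = seed, sharp = 2)
  pl <- plant_binding_regions(g$genome, pwm, cfg)
  tracks <- simulate_chromatin_tracks(pl$regions, cfg)
  pcm <- fit_pca(generate_dinuc_property_table(40, 5, seed = seed))
  list(cfg = cfg, pwm = pwm, pl = pl, tracks = tracks, pcm = pcm)
}

test_that("a TF with 29 bound probes is skipped", {
  fx <- make_pipeline_fixture(29, 40, seed = 8)
  expect_message(
    ds <- build_tf_dataset(fx$pl$probes, fx$pwm, fx$pl$genome, fx$tracks,
                           fx$pcm, normalize = "none"),
    "skipping"
  )
  expect_null(ds)
})

test_that("rows with missing features are dropped and classes balanced", {
  fx <- make_pipeline_fixture(50, 70, seed = 9)
  # remove H3 coverage over three bound truth regions so their rows
  # lose the H3 feature and are filtered
  bound <- fx$pl$regions[fx$pl$regions$label == "bound", ][1:3, ]
  tracks <- fx$tracks
  for (i in 1:3) {
    drop <- tracks$feature == "H3" &
      pmin(tracks$end, bound$end[i]) - pmax(tracks$start, bound$start[i]) > 30
    tracks <- tracks[!drop, ]
  }
  ds <- build_tf_dataset(fx$pl$probes, fx$pwm, fx$pl$genome, tracks,
                         fx$pcm, normalize = "none")
  expect_equal(sum(ds$label == "bound"), sum(ds$label == "unbound"))
  expect_lte(sum(ds$label == "bound"), 47L)
  expect_true(all(stats::complete.cases(ds[feature_names()])))
})

test_that("full datasets keep every bound probe and exact 60 bp regions", {
  fx <- make_pipeline_fixture(40, 60, seed = 10)
  ds <- build_tf_dataset(fx$pl$probes, fx$pwm, fx$pl$genome, fx$tracks,
                         fx$pcm, normalize = "none")
  expect_equal(sum(ds$label == "bound"), 40L)
  expect_true(all(ds$end - ds$start == 60L))
  expect_equal(ncol(ds[feature_names()]), 23L)
  # serialization round-trip of the feature matrix
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ds, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back[feature_names()]),
               as.data.frame(ds[feature_names()]))
})

test_that("most refined bound regions contain their planted motif", {
  fx <- make_pipeline_fixture(60, 60, seed = 11)
  ds <- build_tf_dataset(fx$pl$probes, fx$pwm, fx$pl$genome, fx$tracks,
                         fx$pcm, normalize = "none")
  truth <- fx$pl$regions[fx$pl$regions$label == "bound", ]
  pos <- ds[ds$label == "bound", ]
  # planted instance (8 bp at truth center) fully inside refined region
  inside <- vapply(seq_len(nrow(pos)), function(i) {
    any(truth$start + 26 >= pos$start[i] & truth$start + 34 <= pos$end[i])
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("one-vs-rest builds one balanced pair per other TF", {
  d1 <- toy_dataset(40, seed = 1, tf = "TF1")
  d2 <- toy_dataset(30, seed = 2, tf = "TF2")
  d3 <- toy_dataset(50, seed = 3, tf = "TF3")
  all3 <- dplyr::bind_rows(d1, d2, d3)
  pairs <- build_one_vs_rest(all3, "TF1", seed = 4)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$other, c("TF2", "TF3"))
  for (d in pairs$data) {
    expect_equal(sum(d$label == "bound"), sum(d$label == "unbound"))
  }
  # downsampled to the smaller bound set
  expect_equal(sum(pairs$data[[which(pairs$other == "TF2")]]$label ==
                     "bound"), 30L)
  expect_error(build_one_vs_rest(d1, "TF1"), "2 TFs")
})
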