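test_that("f_measure matches its closed form and anchors", {
  expect_equal(f_measure(10, 0, 0), 1)
  expect_equal(f_measure(3, 1, 1), 0.75)
  expect_equal(f_measure(0, 5, 5), 0)
  expect_equal(f_measure(0, 0, 0), 0)
  expect_error(f_measure(-1, 0, 0), ">= 0")

  # a uniformly random classifier on balanced labels sits near 0.5
  set.seed(42)
  n <- 10000
  labels <- rep(c("bound", "unbound"), n / 2)
  pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
  pos <- labels == "bound"
  f <- f_measure(sum(pred & pos), sum(pred & !pos), sum(!pred & pos))
  expect_lt(abs(f - 0.5), 0.02)
})

test_that("auroc matches exhaustive pair counting, including ties", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12),
                     c(rep("unbound", 3), rep("bound", 3))), 1)
  set.seed(1)
  for (trial in 1:20) {
    n <- sample(6:20, 1)
    labels <- sample(c("bound", "unbound"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- sample(1:5, n, replace = TRUE)  # forces ties
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels))
  }
  expect_error(auroc(1:3, rep("bound", 3)), "both classes")

  set.seed(2)
  null_auc <- auroc(rnorm(10000), sample(c("bound", "unbound"), 10000,
                                         replace = TRUE))
  expect_lt(abs(null_auc - 0.5), 0.02)
})

test_that("forests use sqrt(p) feature sampling and are seed-reproducible", {
  d <- toy_dataset(50, effects = c(H3 = -1.5), seed = 1)
  fit23 <- train_random_forest(d, feature_names(), seed = 1, ntree = 50)
  expect_equal(fit23$mtry, 4)
  fit3 <- train_random_forest(d, c("H3", "PC1", "PC2"), seed = 1,
                              ntree = 50)
  expect_equal(fit3$mtry, 1)

  s1 <- predict(fit3, as.data.frame(d[c("H3", "PC1", "PC2")]),
                type = "prob")
  fit3b <- train_random_forest(d, c("H3", "PC1", "PC2"), seed = 1,
                               ntree = 50)
  s2 <- predict(fit3b, as.data.frame(d[c("H3", "PC1", "PC2")]),
                type = "prob")
  expect_identical(s1, s2)

  expect_error(train_random_forest(d[d$label == "bound", ],
                                   c("H3", "PC1"), seed = 1),
               "both classes")
  expect_error(train_random_forest(d, c("H3", "NoSuchFeature")),
               "missing feature")
})

test_that("repeated CV is calibrated on null data and sharp on separable data", {
  null_d <- toy_dataset(100, effects = c(H3 = 0), seed = 2)
  ev_null <- repeated_cv(null_d, c("H3", "PC1", "PC2"), folds = 5,
                         repeats = 3, ntree = 150, seed = 3)
  expect_lt(abs(ev_null$summary$f_measure - 0.5), 0.05)

  sep <- toy_dataset(100, effects = c(H3 = -8), seed = 4)
  ev_sep <- repeated_cv(sep, c("H3", "PC1", "PC2"), folds = 5,
                        repeats = 2, ntree = 150, seed = 5)
  expect_gte(ev_sep$summary$f_measure, 0.98)
  expect_gte(ev_sep$summary$auroc, 0.99)

  expect_equal(nrow(ev_sep$per_run), 2L)
  expect_true(all(ev_sep$per_run$f_measure >= 0 &
                    ev_sep$per_run$f_measure <= 1))
  td <- tidy(ev_sep)
  expect_equal(nrow(td), 2L)
  expect_equal(glance(ev_sep), ev_sep$summary)
})

test_that("too-small classes reduce the fold count with a warning", {
  d <- toy_dataset(6, effects = c(H3 = -2), seed = 6)
  expect_warning(folds <- make_cv_folds(d$label, folds = 10, repeats = 1,
                                        seed = 1),
                 "reducing folds")
  expect_equal(max(folds[[1]]), 6L)
})

test_that("feature-set models share folds and reproduce planted structure", {
  d <- toy_dataset(100, effects = c(H3 = -1.5, H3K4me1 = 1.5, PC1 = 1.5),
                   seed = 7)
  fs <- feature_set_models(d, folds = 5, repeats = 2, ntree = 150,
                           seed = 8)
  expect_equal(fs$model_tag,
               c("SM", "CS", "DS", "SM+CS", "SM+DS", "CS+DS", "SM+CS+DS"))
  f <- setNames(fs$f_measure, fs$model_tag)
  expect_gt(f[["CS+DS"]], f[["SM"]])
  expect_gt(f[["SM+CS+DS"]], f[["SM"]])
  # SM carries no planted signal here
  expect_lt(abs(f[["SM"]] - 0.5), 0.1)

  # identical feature columns produce identical metrics under shared folds
  d2 <- d
  d2$ScerTFhit <- d2$H3
  d2$ScerTFpvalue <- d2$H3K4me1
  fs2 <- feature_set_models(
    d2, sets = list(A = c("ScerTFhit", "ScerTFpvalue"),
                    B = c("H3", "H3K4me1")),
    folds = 5, repeats = 2, ntree = 150, seed = 9
  )
  expect_equal(fs2$f_measure[1], fs2$f_measure[2], tolerance = 1e-12)
})

test_that("drop-column importance singles out the informative feature", {
  d <- toy_dataset(120, effects = c(H3K4me1 = 2.5), seed = 10)
  feats <- c("H3K4me1", "H3", "ESA1", "PC1", "PC2", "ScerTFhit")
  imp <- drop_column_importance(d, feats, folds = 5, repeats = 2,
                                ntree = 150, seed = 11)
  expect_equal(imp$feature[which.max(imp$drop)], "H3K4me1")
  expect_equal(imp$normalized[imp$feature == "H3K4me1"], 1)
  expect_true(all(imp$normalized >= 0 & imp$normalized <= 1))
  # pure-noise features drop about nothing
  expect_lt(max(abs(imp$drop[imp$feature != "H3K4me1"])), 0.06)
  expect_error(drop_column_importance(d, "H3"), ">= 2 features")
})

test_that("redundant duplicated features each show a small drop", {
  d <- toy_dataset(120, effects = c(H3K4me1 = 2.5), seed = 12)
  d$H3 <- d$H3K4me1  # exact duplicate of the informative column
  # with a perfect duplicate the drops can all collapse to zero, which
  # the normalization reports with a warning
  imp <- suppressWarnings(
    drop_column_importance(d, c("H3K4me1", "H3", "PC1", "PC2"),
                           folds = 5, repeats = 2, ntree = 150,
                           seed = 13))
  dup <- imp$drop[imp$feature %in% c("H3K4me1", "H3")]
  expect_lt(max(abs(dup)), 0.05)
})

test_that("the intrinsic model is the CV restricted to its three features", {
  d <- toy_dataset(80, effects = c(occupancy = -1.5, PC1 = 1.5,
                                   PC2 = 1.0), seed = 14)
  ev <- intrinsic_model(d, folds = 5, repeats = 2, ntree = 150,
                        seed = 15)
  direct <- repeated_cv(d, c("occupancy", "PC1", "PC2"), folds = 5,
                        repeats = 2, ntree = 150, seed = 15,
                        model_tag = "INTRINSIC")
  expect_equal(ev$summary, direct$summary)
  expect_gt(ev$summary$f_measure, 0.75)

  expect_error(intrinsic_model(d[setdiff(names(d), "occupancy")]),
               "occupancy")

  null_d <- toy_dataset(80, effects = c(H3 = -3), seed = 16)
  ev_null <- intrinsic_model(null_d, folds = 5, repeats = 2, ntree = 150,
                             seed = 17)
  expect_lt(abs(ev_null$summary$f_measure - 0.5), 0.12)
})

test_that("cross-DBD transfer recovers shared and inverted signal", {
  shared <- function(seed, flip = 1) {
    toy_dataset(80, effects = c(occupancy = flip * -1.5,
                                PC1 = flip * 1.5, PC2 = flip * 1.0),
                seed = seed)
  }
  fams <- list(HTH = shared(20), ZF = shared(21), LZ = shared(22))
  res <- cross_dbd_eval(fams, folds = 5, seed = 23, ntree = 150,
                        bootstrap = 2000)
  expect_equal(dim(res$f), c(3L, 3L))
  off <- res$f[row(res$f) != col(res$f)]
  expect_true(all(off > 0.5))
  expect_true(all(res$p[row(res$p) != col(res$p)] < 0.01))
  expect_true(all(is.na(diag(res$p))))
  td <- tidy(res)
  expect_equal(nrow(td), 9L)
  expect_equal(sum(td$diagonal), 3L)

  # a family with inverted effects transfers below chance
  fams$WH <- shared(24, flip = -1)
  res2 <- cross_dbd_eval(fams[c("HTH", "WH")], folds = 5, seed = 25,
                         ntree = 150, bootstrap = 500)
  expect_lt(res2$f["HTH", "WH"], 0.5)

  expect_warning(
    res3 <- cross_dbd_eval(c(fams[1:2], list(EMPTY = NULL)),
                           folds = 5, seed = 26, ntree = 100,
                           bootstrap = 200),
    "empty"
  )
  expect_equal(length(res3$families), 2L)
})

test_that("rank-sum comparisons control FDR and find planted shifts", {
  # Benjamini-Hochberg arithmetic on a known vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))

  d <- toy_dataset(200, effects = c(H3 = -1.5, H3K4me1 = 1.5), seed = 27)
  cmp <- compare_feature_distributions(d)
  expect_equal(nrow(cmp), 23L)
  expect_lt(cmp$p_adjusted[cmp$feature == "H3"], 0.05)
  expect_equal(cmp$direction[cmp$feature == "H3"], -1)
  expect_lt(cmp$p_adjusted[cmp$feature == "H3K4me1"], 0.05)
  # null features mostly stay non-significant
  null_p <- cmp$p_adjusted[!cmp$feature %in% c("H3", "H3K4me1")]
  expect_gt(mean(null_p > 0.05), 0.8)

  few <- d[c(1:2, 201:202), ]
  cmp_few <- compare_feature_distributions(few, features = "H3")
  expect_true(is.na(cmp_few$p_value))
})

test_that("performance standardization z-scores rows and groups TFs", {
  perf <- tibble::tibble(
    tf = rep(c("A", "B"), each = 3),
    model_tag = rep(c("SM", "CS", "DS"), 2),
    f_measure = c(0.5, 0.7, 0.9, 0.6, 0.6, 0.6)
  )
  expect_warning(z <- standardize_performance(perf, groups = NULL),
                 "zero-variance")
  expect_equal(z$z[z$tf == "A"], c(-1, 0, 1))
  expect_equal(z$z[z$tf == "B"], c(0, 0, 0))
  expect_equal(mean(z$z[z$tf == "A"]), 0, tolerance = 1e-9)
  expect_equal(stats::var(z$z[z$tf == "A"]), 1, tolerance = 1e-9)

  # three TF archetypes cluster into three groups
  perf3 <- tibble::tibble(
    tf = rep(c("T1", "T2", "T3", "T4", "T5", "T6"), each = 2),
    model_tag = rep(c("CS", "DS"), 6),
    f_measure = c(0.9, 0.5, 0.9, 0.52, 0.5, 0.9, 0.51, 0.9, 0.7, 0.7,
                  0.71, 0.69)
  )
  # T5/T6 are deliberately flat rows (the "no preference" archetype)
  g <- suppressWarnings(standardize_performance(perf3, groups = 3))
  grp <- unique(g[c("tf", "group")])
  expect_equal(length(unique(grp$group)), 3L)
  expect_equal(grp$group[grp$tf == "T1"], grp$group[grp$tf == "T2"])
  expect_equal(grp$group[grp$tf == "T3"], grp$group[grp$tf == "T4"])
})
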