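# Random-forest evaluation layer: repeated stratified cross-validation,
# F-measure / auROC metrics, feature-set comparison with paired folds,
# drop-column importance, the 3-feature intrinsic model, cross-DBD
# transfer with bootstrap significance, rank-sum feature comparisons,
# and per-TF performance standardization.

#' F-measure from a confusion count
#'
#' Harmonic mean of precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)`; defined as 0 when precision and recall are both 0.
#' A perfect classifier scores 1; a random classifier on a balanced
#' dataset scores about 0.5.
#'
#' @param tp,fp,fn Non-negative confusion counts.
#' @return F-measure in `[0, 1]`.
#' @export
f_measure <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("confusion counts must be >= 0")
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, 0, 2 * tp / denom)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half (computed from average ranks,
#' the Mann-Whitney statistic).
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Logical, or character with `"bound"` as the positive
#'   class.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "bound"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort("auroc needs both classes present")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# label vector as a factor with the positive class first
as_label_factor <- function(labels) {
  factor(labels, levels = c("bound", "unbound"))
}

#' Train a random forest binding classifier
#'
#' 500 trees with `floor(sqrt(p))` candidate features per split (minimum
#' 1), the standard parameterization for this classifier; seeded for
#' reproducibility. Class-probability scores are available through
#' `predict(..., type = "prob")`.
#'
#' @param data Dataset tibble with a `label` column.
#' @param features Character vector of feature columns to use.
#' @param seed Integer seed.
#' @param ntree Number of trees, default 500.
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @return A `randomForest` fit.
#' @export
train_random_forest <- function(data, features, seed = 1L, ntree = 500L,
                                mtry = max(1L, floor(sqrt(length(features))))) {
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing feature column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  y <- as_label_factor(data$label)
  if (length(unique(y)) < 2L) abort("need both classes to train")
  x <- as.data.frame(data[features])
  set.seed(seed)
  randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry)
}

# positive-class probability scores of a fitted forest on new data
forest_scores <- function(fit, data, features) {
  predict(fit, newdata = as.data.frame(data[features]),
          type = "prob")[, "bound"]
}

#' Stratified fold assignments for repeated cross-validation
#'
#' One integer vector of fold ids per repeat, stratified by class, each
#' repeat reseeded from the master seed. Passing the same assignments to
#' several model evaluations makes their comparison paired.
#'
#' @param labels Label vector.
#' @param folds,repeats Cross-validation geometry.
#' @param seed Master seed.
#' @return List of `repeats` integer vectors.
#' @export
make_cv_folds <- function(labels, folds = 10L, repeats = 10L, seed = 1L) {
  pos <- labels == "bound"
  n_min <- min(sum(pos), sum(!pos))
  if (n_min < folds) {
    warn(sprintf("reducing folds from %d to %d (smallest class size)",
                 folds, n_min))
    folds <- n_min
  }
  lapply(seq_len(repeats), function(r) {
    set.seed(seed + 1000003L * r %% .Machine$integer.max)
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    fold
  })
}

# confusion metrics at probability threshold 0.5
threshold_metrics <- function(scores, labels) {
  pos <- labels == "bound"
  pred <- scores > 0.5
  tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos)
  c(
    f_measure = f_measure(tp, fp, fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn),
    accuracy = (tp + tn) / length(labels)
  )
}

#' Repeated stratified cross-validation of a random forest
#'
#' 10 independent runs of 10-fold stratified cross-validation (by
#' default). Within each run, out-of-fold class-probability scores are
#' pooled and the run's F-measure, precision, recall (at probability
#' threshold 0.5), accuracy and auROC are computed; the reported metrics
#' are means over runs, with per-run values retained.
#'
#' @inheritParams train_random_forest
#' @param folds,repeats Cross-validation geometry, defaults 10 x 10.
#' @param fold_assignments Optional list from [make_cv_folds()] for
#'   paired comparisons; defaults to fresh assignments from `seed`.
#' @param model_tag Name attached to the result (e.g. the feature-set
#'   name).
#' @return An object of class `binding_eval` with `$summary` (one-row
#'   tibble of mean metrics) and `$per_run` (one row per run); see
#'   [tidy.binding_eval()].
#' @export
repeated_cv <- function(data, features, folds = 10L, repeats = 10L,
                        seed = 1L, ntree = 500L,
                        fold_assignments = NULL,
                        model_tag = paste(features, collapse = "+")) {
  labels <- data$label
  if (is.null(fold_assignments)) {
    fold_assignments <- make_cv_folds(labels, folds, repeats, seed)
  }
  per_run <- purrr::imap_dfr(fold_assignments, function(fold, r) {
    scores <- numeric(length(labels))
    for (f in sort(unique(fold))) {
      test <- fold == f
      fit <- train_random_forest(data[!test, ], features,
                                 seed = seed + 13L * r + f,
                                 ntree = ntree)
      scores[test] <- forest_scores(fit, data[test, ], features)
    }
    m <- threshold_metrics(scores, labels)
    tibble(run = r, f_measure = m["f_measure"], precision = m["precision"],
           recall = m["recall"], accuracy = m["accuracy"],
           auroc = auroc(scores, labels))
  })
  structure(
    list(
      model_tag = model_tag,
      per_run = per_run,
      summary = dplyr::summarise(
        per_run,
        model_tag = model_tag,
        dplyr::across(c("f_measure", "precision", "recall", "accuracy",
                        "auroc"), mean),
        n_runs = dplyr::n(), .groups = "drop"
      )[c("model_tag", "f_measure", "precision", "recall", "accuracy",
          "auroc", "n_runs")]
    ),
    class = "binding_eval"
  )
}

#' @export
print.binding_eval <- function(x, ...) {
  cat(sprintf("<binding_eval> %s: F = %.3f, auROC = %.3f (%d runs)\n",
              x$model_tag, x$summary$f_measure, x$summary$auroc,
              x$summary$n_runs))
  invisible(x)
}

#' Tidy methods for cross-validation results
#'
#' `tidy()` returns one row per cross-validation run; `glance()` the
#' one-row summary of mean metrics.
#'
#' @param x,object A `binding_eval` from [repeated_cv()].
#' @param ... Unused.
#' @method tidy binding_eval
#' @export
tidy.binding_eval <- function(x, ...) {
  dplyr::bind_cols(tibble(model_tag = x$model_tag), x$per_run)
}

#' @rdname tidy.binding_eval
#' @method glance binding_eval
#' @export
glance.binding_eval <- function(x, ...) x$summary

#' Compare the seven feature-set models on one dataset
#'
#' Evaluates random forests on `SM`, `CS`, `DS`, the three pairwise
#' combinations and the full `SM+CS+DS` set (plus any extra sets given),
#' all with identical fold assignments per run so the comparison is
#' paired.
#'
#' @inheritParams repeated_cv
#' @param sets Named list of feature subsets; defaults to the seven
#'   family combinations of [model_feature_sets()].
#' @return Tibble with one row per feature set: mean metrics plus a
#'   `per_run` list-column.
#' @export
feature_set_models <- function(data, sets = model_feature_sets()[1:7],
                               folds = 10L, repeats = 10L, seed = 1L,
                               ntree = 500L) {
  fold_assignments <- make_cv_folds(data$label, folds, repeats, seed)
  purrr::imap_dfr(sets, function(features, tag) {
    ev <- repeated_cv(data, features, seed = seed, ntree = ntree,
                      fold_assignments = fold_assignments,
                      model_tag = tag)
    dplyr::bind_cols(ev$summary, tibble(per_run = list(ev$per_run)))
  })
}

#' Drop-column feature importance
#'
#' The importance of feature X is the reduction in cross-validated
#' accuracy (fraction correct at probability threshold 0.5) when the
#' model is retrained without X, using the same fold assignments as the
#' full model (paired). The drops are then min-max rescaled to `[0, 1]`
#' per dataset (per TF), matching how importances are displayed across
#' TFs.
#'
#' @inheritParams repeated_cv
#' @return An `importance_result`: tibble with `feature`, `drop`
#'   (accuracy of the full model minus accuracy without the feature) and
#'   `normalized`.
#' @export
drop_column_importance <- function(data, features = feature_names(),
                                   folds = 10L, repeats = 10L, seed = 1L,
                                   ntree = 500L) {
  if (length(features) < 2L) abort("need >= 2 features for importance")
  fold_assignments <- make_cv_folds(data$label, folds, repeats, seed)
  full <- repeated_cv(data, features, seed = seed, ntree = ntree,
                      fold_assignments = fold_assignments,
                      model_tag = "full")
  acc_full <- full$summary$accuracy
  drops <- vapply(features, function(f) {
    ev <- repeated_cv(data, setdiff(features, f), seed = seed,
                      ntree = ntree, fold_assignments = fold_assignments,
                      model_tag = paste0("drop_", f))
    acc_full - ev$summary$accuracy
  }, numeric(1))
  rng <- range(drops)
  normalized <- if (diff(rng) < .Machine$double.eps) {
    warn("all drop values identical; normalized importances set to 0")
    rep(0, length(drops))
  } else {
    (drops - rng[1]) / diff(rng)
  }
  structure(
    tibble(feature = features, drop = unname(drops),
           normalized = unname(normalized)),
    accuracy_full = acc_full,
    class = c("importance_result", class(tibble()))
  )
}

#' The three-feature intrinsic property model
#'
#' Cross-validates a random forest on exactly `occupancy` (in-silico
#' predicted nucleosome occupancy), `PC1` (major-groove geometry
#' component) and `PC2` (dinucleotide free-energy component) — three
#' features computable from genome sequence alone.
#'
#' @inheritParams repeated_cv
#' @return A `binding_eval`.
#' @export
intrinsic_model <- function(data, folds = 10L, repeats = 10L, seed = 1L,
                            ntree = 500L) {
  features <- model_feature_sets()$INTRINSIC
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    abort(sprintf("intrinsic model needs columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  repeated_cv(data, features, folds, repeats, seed, ntree,
              model_tag = "INTRINSIC")
}

# exact label-permutation null for the F-measure: with predictions
# fixed, permuting test labels makes TP hypergeometric
bootstrap_f_null <- function(n, n_label_pos, n_pred_pos, reps, seed) {
  set.seed(seed)
  tp <- stats::rhyper(reps, n_label_pos, n - n_label_pos, n_pred_pos)
  fp <- n_pred_pos - tp
  fn <- n_label_pos - tp
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, 0, 2 * tp / denom)
}

#' Cross-DNA-binding-domain transfer evaluation
#'
#' Trains one model per DBD family on the pooled datasets of that
#' family's TFs and tests it on every other family; diagonal entries are
#' 10-fold cross-validated within the family. Off-diagonal F-measures
#' get a label-permutation bootstrap p-value (default 10,000 resamples,
#' add-one pseudocount), testing whether transfer beats a random
#' predictor.
#'
#' @param family_datasets Named list of dataset tibbles, one per family
#'   (each with `label` and the feature columns).
#' @param features Feature subset, default the intrinsic set.
#' @param folds Folds for the diagonal cross-validation.
#' @param seed,ntree As in [repeated_cv()].
#' @param bootstrap Number of label-permutation resamples.
#' @return A `cross_dbd` object: `families`, `f` (k x k F-measure
#'   matrix), `p` (bootstrap p-values, `NA` on the diagonal); see
#'   `tidy()`.
#' @export
cross_dbd_eval <- function(family_datasets,
                           features = model_feature_sets()$INTRINSIC,
                           folds = 10L, seed = 1L, ntree = 500L,
                           bootstrap = 10000L) {
  keep <- vapply(family_datasets, function(d) !is.null(d) && nrow(d) > 0,
                 logical(1))
  if (any(!keep)) {
    warn(sprintf("excluding empty families: %s",
                 paste(names(family_datasets)[!keep], collapse = ", ")))
    family_datasets <- family_datasets[keep]
  }
  fams <- names(family_datasets)
  if (length(fams) < 2L) abort("need >= 2 non-empty families")
  k <- length(fams)
  f <- p <- matrix(NA_real_, k, k, dimnames = list(train = fams,
                                                   test = fams))
  fits <- purrr::imap(family_datasets, function(d, fam) {
    train_random_forest(d, features,
                        seed = seed + match(fam, fams), ntree = ntree)
  })
  for (i in seq_len(k)) {
    diag_ev <- repeated_cv(family_datasets[[i]], features, folds = folds,
                           repeats = 1L, seed = seed + 97L * i,
                           ntree = ntree, model_tag = fams[i])
    f[i, i] <- diag_ev$summary$f_measure
    for (j in setdiff(seq_len(k), i)) {
      test <- family_datasets[[j]]
      scores <- forest_scores(fits[[i]], test, features)
      m <- threshold_metrics(scores, test$label)
      f[i, j] <- m[["f_measure"]]
      null_f <- bootstrap_f_null(
        n = nrow(test), n_label_pos = sum(test$label == "bound"),
        n_pred_pos = sum(scores > 0.5), reps = bootstrap,
        seed = seed + 1009L * i + j
      )
      p[i, j] <- (1 + sum(null_f >= f[i, j])) / (1 + bootstrap)
    }
  }
  structure(list(families = fams, f = f, p = p, bootstrap = bootstrap),
            class = "cross_dbd")
}

#' @export
print.cross_dbd <- function(x, ...) {
  cat(sprintf("<cross_dbd> %d families (train rows x test columns)\n",
              length(x$families)))
  print(round(x$f, 3))
  invisible(x)
}

#' @describeIn cross_dbd_eval One row per (train family, test family)
#'   with the F-measure, whether it is the cross-validated diagonal, and
#'   the bootstrap p-value.
#' @param x A `cross_dbd`.
#' @param ... Unused.
#' @method tidy cross_dbd
#' @export
tidy.cross_dbd <- function(x, ...) {
  k <- length(x$families)
  tibble(
    train = rep(x$families, times = k),
    test = rep(x$families, each = k),
    f_measure = as.vector(x$f),
    diagonal = rep(x$families, times = k) == rep(x$families, each = k),
    p_value = as.vector(x$p)
  )
}

#' Rank-sum comparison of feature distributions
#'
#' For every (TF, feature) pair, a two-sided Wilcoxon rank-sum test of
#' bound versus unbound feature values, with Benjamini-Hochberg FDR
#' adjustment across the whole tested family, plus the direction of the
#' effect (sign of the bound-minus-unbound median difference).
#'
#' @param data Dataset tibble with `tf`, `label` and feature columns.
#' @param features Feature columns to test, default all 23.
#' @param min_n Minimum values per side to attempt the test (pairs below
#'   get `NA`), default 3.
#' @return Tibble with `tf`, `feature`, `direction`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_feature_distributions <- function(data,
                                          features = feature_names(),
                                          min_n = 3L) {
  out <- tidyr::expand_grid(tf = unique(data$tf), feature = features)
  res <- purrr::pmap(out, function(tf, feature) {
    d <- data[data$tf == tf, ]
    b <- d[[feature]][d$label == "bound"]
    u <- d[[feature]][d$label == "unbound"]
    b <- b[!is.na(b)]; u <- u[!is.na(u)]
    if (length(b) < min_n || length(u) < min_n) {
      return(c(direction = NA_real_, p_value = NA_real_))
    }
    p <- suppressWarnings(wilcox.test(b, u)$p.value)
    c(direction = sign(median(b) - median(u)), p_value = p)
  })
  out$direction <- vapply(res, `[[`, numeric(1), "direction")
  out$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Standardize per-TF model performance
#'
#' Rescales each TF's F-measures across models to mean zero and unit
#' variance so the relative strengths of feature sets are comparable
#' across TFs, and optionally groups TFs by average-linkage hierarchical
#' clustering of the standardized rows (default 3 groups: predictable by
#' either family, CS-dependent, DS-dependent).
#'
#' @param performance Tidy tibble with columns `tf`, `model_tag`,
#'   `f_measure`.
#' @param groups Number of hierarchical-clustering groups to cut, or
#'   `NULL` to skip grouping.
#' @return Tibble `tf`, `model_tag`, `f_measure`, `z`, plus `group` when
#'   requested.
#' @export
standardize_performance <- function(performance, groups = 3L) {
  out <- dplyr::group_by(performance, .data$tf)
  out <- dplyr::mutate(
    out,
    z = {
      s <- sd(.data$f_measure)
      if (dplyr::n() < 2L || is.na(s) || s < 1e-12) {
        if (dplyr::n() >= 2L) warn("zero-variance TF row; z set to 0")
        rep(0, dplyr::n())
      } else {
        (.data$f_measure - mean(.data$f_measure)) / s
      }
    }
  )
  out <- dplyr::ungroup(out)
  if (!is.null(groups)) {
    wide <- tidyr::pivot_wider(out[c("tf", "model_tag", "z")],
                               names_from = "model_tag",
                               values_from = "z")
    m <- as.matrix(wide[-1])
    rownames(m) <- wide$tf
    k <- min(groups, nrow(m))
    grp <- if (nrow(m) < 2L) {
      setNames(rep(1L, nrow(m)), rownames(m))
    } else {
      cutree(hclust(dist(m), method = "average"), k = k)
    }
    out$group <- unname(grp[out$tf])
  }
  out
}
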