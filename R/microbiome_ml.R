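#' Two classes from the tails of a continuous trait
#'
#' Bottom quartile becomes class 0, top quartile class 1, the middle half is
#' left unassigned (`NA`). Quartiles are rank-based (average ranks cut into
#' four equal rank intervals), so `n = 8` yields two members per tail.
#'
#' @param values Continuous trait, `n >= 8`, not all equal.
#' @return Factor of `"0"`/`"1"`/`NA`, same length as `values`.
#' @export
define_classes <- function(values) {
  n <- length(values)
  if (n < 8) stop("need at least 8 values to define quartile classes")
  if (length(unique(values)) == 1) stop("degenerate trait: all values equal")
  bin <- .quantile_bin(values, 4)
  cls <- rep(NA_character_, n)
  cls[bin == 1] <- "0"
  cls[bin == 4] <- "1"
  factor(cls, levels = c("0", "1"))
}

#' Twin-aware train/test split
#'
#' Random split at `test_fraction`, after which any training sample whose
#' twin is in the test set is removed, so no twin pair ever straddles the
#' split.
#'
#' @param ids Sample identifiers.
#' @param twin_pair Twin-pair identifier per sample (`NA` for singletons).
#' @param test_fraction Fraction held out (default 0.2).
#' @return `list(train, test)` of identifiers.
#' @export
twin_aware_split <- function(ids, twin_pair, test_fraction = 0.2) {
  n <- length(ids)
  n_test <- max(1L, round(test_fraction * n))
  test <- sample(ids, n_test)
  train <- setdiff(ids, test)
  test_pairs <- twin_pair[match(test, ids)]
  test_pairs <- test_pairs[!is.na(test_pairs)]
  train_pair <- twin_pair[match(train, ids)]
  train <- train[is.na(train_pair) | !(train_pair %in% test_pairs)]
  list(train = train, test = test)
}

.auc_score <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 levels = c("0", "1"), direction = "<")))
}

#' Cross-validated random-forest prediction from microbiome composition
#'
#' Repeats, for `n_iter` bootstrap iterations: a twin-aware 80/20 split,
#' random-forest fitting on the training fold, and test-fold evaluation.
#' Classification reports the area under the ROC curve per iteration;
#' regression fits a simple linear calibration of truth on training-fold
#' predictions, applies it to test predictions, clips to the training target
#' range, and reports the Pearson correlation. Iterations whose training
#' fold collapses to a single class are skipped and logged.
#'
#' @param features Sample-by-species relative-abundance matrix (rows sum
#'   to 1), rownames = sample ids.
#' @param target Named vector (by sample id): a factor from
#'   [define_classes()] for classification (NA values are dropped), or a
#'   numeric trait for regression.
#' @param task `"classification"` or `"regression"`.
#' @param twin_pair Named twin-pair ids per sample (`NA` for singletons).
#' @param n_iter Bootstrap iterations (default 100).
#' @param seed Integer seed.
#' @param num_trees Forest size.
#' @param test_fraction Held-out fraction per iteration.
#' @param null_permute Permutation null: re-permute the target across
#'   samples at the start of every iteration, so the per-iteration scores
#'   draw from the no-association distribution.
#' @return `list(task, scores, median_score, n_iterations, skipped)`;
#'   `scores` holds the per-iteration AUC or correlation.
#' @export
run_cv <- function(features, target, task = c("classification", "regression"),
                   twin_pair = NULL, n_iter = 100, seed = 1,
                   num_trees = 200, test_fraction = 0.2, null_permute = FALSE) {
  task <- match.arg(task)
  ids <- names(target)
  if (is.null(ids)) {
    ids <- rownames(features)
    names(target) <- ids
  }
  keep <- !is.na(target)
  ids <- ids[keep]
  target <- target[keep]
  if (is.null(twin_pair)) {
    twin_pair <- stats::setNames(rep(NA_character_, length(ids)), ids)
  }
  X <- features[ids, , drop = FALSE]
  colnames(X) <- make.names(colnames(X))
  set.seed(seed)
  scores <- rep(NA_real_, n_iter)
  skipped <- 0L
  for (it in seq_len(n_iter)) {
    target_it <- if (null_permute) stats::setNames(sample(target), ids) else target
    sp <- twin_aware_split(ids, twin_pair[ids], test_fraction)
    ytr <- target_it[sp$train]; yte <- target_it[sp$test]
    if (task == "classification" && length(unique(ytr[!is.na(ytr)])) < 2) {
      skipped <- skipped + 1L
      next
    }
    dtr <- data.frame(.y = unname(ytr), X[sp$train, , drop = FALSE])
    dte <- data.frame(X[sp$test, , drop = FALSE])
    if (task == "classification") {
      rf <- ranger::ranger(.y ~ ., data = dtr, num.trees = num_trees,
                           probability = TRUE, seed = seed + it)
      prob <- stats::predict(rf, dte)$predictions[, "1"]
      scores[it] <- .auc_score(yte, prob)
    } else {
      rf <- ranger::ranger(.y ~ ., data = dtr, num.trees = num_trees,
                           seed = seed + it)
      pred_tr <- stats::predict(rf, dtr)$predictions
      cal <- stats::lm(y ~ p, data = data.frame(y = unname(ytr), p = pred_tr))
      pred_te <- stats::predict(cal,
                                data.frame(p = stats::predict(rf, dte)$predictions))
      pred_te <- pmin(pmax(pred_te, min(ytr)), max(ytr))
      scores[it] <- stats::cor(pred_te, unname(yte))
    }
  }
  list(task = task, scores = scores,
       median_score = stats::median(scores, na.rm = TRUE),
       n_iterations = n_iter, skipped = skipped)
}

.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Confounder-matched subset resampling
#'
#' Draws random subsets of `size_per_class` high-trait and `size_per_class`
#' low-trait participants, accepting a subset only when (i) the nuisance
#' score (main-meal quality) does not differ between the classes by a
#' Mann-Whitney U test at `p_floor`, and (ii) the subset's Jaccard overlap
#' with every previously accepted subset is below `jaccard_cap`. Rejection
#' sampling continues until `n_subsets` are accepted or `max_tries` draws
#' are spent (a partial collection is returned with a warning).
#'
#' @param high_ids,low_ids Candidate participants per class.
#' @param nuisance Named numeric nuisance score covering all candidates.
#' @param n_subsets Number of subsets wanted (default 100).
#' @param size_per_class Participants per class per subset (default 100).
#' @param p_floor Minimum rank-test p for balance (default 0.05).
#' @param jaccard_cap Maximum pairwise Jaccard overlap (default 0.5,
#'   strict).
#' @param seed Integer seed.
#' @param max_tries Draw budget.
#' @return List of `matched_subset` records (`high`, `low`, `balance_p`,
#'   `jaccard_max`).
#' @export
matched_subsets <- function(high_ids, low_ids, nuisance, n_subsets = 100,
                            size_per_class = 100, p_floor = 0.05,
                            jaccard_cap = 0.5, seed = 1, max_tries = 50 * n_subsets) {
  stopifnot(length(high_ids) >= size_per_class, length(low_ids) >= size_per_class)
  set.seed(seed)
  accepted <- list()
  tries <- 0L
  while (length(accepted) < n_subsets && tries < max_tries) {
    tries <- tries + 1L
    hi <- sample(high_ids, size_per_class)
    lo <- sample(low_ids, size_per_class)
    p <- suppressWarnings(stats::wilcox.test(nuisance[hi], nuisance[lo])$p.value)
    if (is.na(p) || p <= p_floor) next
    members <- c(hi, lo)
    jmax <- if (length(accepted)) {
      max(vapply(accepted, function(s) .jaccard(members, c(s$high, s$low)), 0))
    } else 0
    if (jmax >= jaccard_cap) next
    accepted[[length(accepted) + 1L]] <- list(high = hi, low = lo,
                                              balance_p = p, jaccard_max = jmax)
  }
  if (length(accepted) < n_subsets) {
    warning(sprintf("matched_subsets: %d of %d subsets found within %d tries",
                    length(accepted), n_subsets, max_tries))
  }
  accepted
}
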