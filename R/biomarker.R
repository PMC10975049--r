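# Biomarker discovery: univariate ROC curves and repeatedly subsampled
# random-forest classification models with class-probability accumulation.

# Rank-based AUC of `values` for RS over NRS (midranks handle ties), i.e.
# P(X_RS > X_NRS) + 0.5 P(X_RS = X_NRS). This is the Mann-Whitney U
# statistic divided by n1 * n2.
.auc_rs_high <- function(values, labels) {
  rs <- values[labels == "RS"]
  nrs <- values[labels == "NRS"]
  n1 <- length(rs)
  n2 <- length(nrs)
  if (n1 == 0L || n2 == 0L) {
    abort("both classes (RS, NRS) must be present",
          class = "dietresponder_validation_error")
  }
  r <- rank(c(rs, nrs))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Univariate ROC analysis per feature
#'
#' For each feature, the area under the ROC curve separating RS from NRS
#' study samples, computed rank-wise (Mann-Whitney U / (n1 n2)) with the
#' RS-high orientation: AUC > 0.5 means the feature tends to be more
#' intense in responders. A `higher_in` flag records the direction of the
#' mean difference.
#'
#' @param ft A [feature_table()] whose study samples carry RS/NRS labels,
#'   or a numeric matrix (samples x features).
#' @param labels Class labels per row when `ft` is a matrix; ignored for a
#'   `feature_table`.
#' @return Tibble `feature`, `auc` (RS-high orientation), `auc_folded`
#'   (max(auc, 1 - auc), the discriminative magnitude), `higher_in`.
#' @export
univariate_roc <- function(ft, labels = NULL) {
  if (inherits(ft, "feature_table")) {
    keep <- ft$sample_roles == "study" & !is.na(ft$class_labels)
    mat <- ft$intensities[keep, , drop = FALSE]
    labels <- ft$class_labels[keep]
  } else {
    mat <- as.matrix(ft)
  }
  if (is.null(labels) || length(unique(labels)) < 2L) {
    abort("both classes (RS, NRS) must be present",
          class = "dietresponder_validation_error")
  }
  auc <- apply(mat, 2, .auc_rs_high, labels = labels)
  mean_rs <- colMeans(mat[labels == "RS", , drop = FALSE])
  mean_nrs <- colMeans(mat[labels == "NRS", , drop = FALSE])
  tibble::tibble(
    feature = colnames(mat),
    auc = unname(auc),
    auc_folded = pmax(auc, 1 - auc),
    higher_in = ifelse(mean_rs >= mean_nrs, "RS", "NRS")
  )
}

# stratified train indices: ~2/3 of each class
.stratified_split <- function(labels, train_frac) {
  idx <- seq_along(labels)
  train <- unlist(lapply(unique(labels), function(cl) {
    pool <- idx[labels == cl]
    sample(pool, max(1L, round(length(pool) * train_frac)))
  }))
  sort(train)
}

#' Random-forest multivariate ROC with repeated subsampling
#'
#' The biomarker-model stage: over `n_repeats` stratified splits
#' (`train_frac` of each class for training, the rest held out), a random
#' forest is grown on all features of the training fold, features are
#' ranked by its importance, the forest is refitted on the top-k features
#' for each requested subset size, and held-out RS class probabilities
#' are accumulated. The headline model uses the largest feasible subset
#' size (100 by default). The pooled per-sample probabilities (averaged
#' over the repeats in which a sample was held out) give the reported
#' ROC AUC and the majority-vote predictive accuracy; the confidence
#' interval is a seeded percentile bootstrap over the per-repeat held-out
#' AUCs.
#'
#' @param ft A [feature_table()] with labelled study samples (>= 3 per
#'   class).
#' @param subset_sizes Feature-subset sizes to evaluate; sizes exceeding
#'   the feature count are dropped. Default `c(5, 10, 15, 25, 50, 100)`.
#' @param n_repeats Number of subsampling repeats (default 50).
#' @param train_frac Fraction of each class used for training (default
#'   2/3).
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param ntree Trees per forest (default 500).
#' @param seed Integer seed; the whole procedure is deterministic given
#'   the seed and input.
#' @return Object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `predictive_accuracy` (percent), `class_probabilities` (named,
#'   probability of RS), `predicted_class`, `feature_ranking` (tibble
#'   `feature`, `importance` averaged over repeats), `per_subset` (tibble
#'   of mean per-repeat AUC by subset size), `auc_per_repeat`,
#'   `headline_subset`, `settings`.
#' @export
multivariate_roc <- function(ft, subset_sizes = c(5, 10, 15, 25, 50, 100),
                             n_repeats = 50, train_frac = 2 / 3,
                             n_boot = 1000, ntree = 500, seed = 7) {
  stopifnot(inherits(ft, "feature_table"))
  keep <- ft$sample_roles == "study" & !is.na(ft$class_labels)
  x <- ft$intensities[keep, , drop = FALSE]
  y <- factor(ft$class_labels[keep], levels = c("NRS", "RS"))
  if (any(table(y) < 3L)) {
    abort("at least 3 labelled study samples per class are required",
          class = "dietresponder_validation_error")
  }
  nf <- ncol(x)
  subset_sizes <- sort(unique(pmin(subset_sizes, nf)))
  headline <- max(subset_sizes)
  n <- nrow(x)

  set.seed(seed)
  prob_sum <- matrix(0, n, length(subset_sizes),
                     dimnames = list(rownames(x), subset_sizes))
  prob_cnt <- matrix(0L, n, length(subset_sizes))
  auc_rep <- matrix(NA_real_, n_repeats, length(subset_sizes))
  imp_sum <- setNames(numeric(nf), colnames(x))

  for (r in seq_len(n_repeats)) {
    repeat {
      tr <- .stratified_split(as.character(y), train_frac)
      te <- setdiff(seq_len(n), tr)
      if (length(unique(y[tr])) == 2L && length(unique(y[te])) == 2L) break
      message("degenerate split resampled")
    }
    rf_all <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                         ntree = ntree, importance = FALSE)
    imp <- rf_all$importance[, "MeanDecreaseGini"]
    imp_sum <- imp_sum + imp[names(imp_sum)]
    ranked <- names(sort(imp, decreasing = TRUE))
    for (k_i in seq_along(subset_sizes)) {
      k <- subset_sizes[k_i]
      feats <- ranked[seq_len(k)]
      rf_k <- randomForest::randomForest(x[tr, feats, drop = FALSE], y[tr],
                                         ntree = ntree)
      p <- predict(rf_k, x[te, feats, drop = FALSE], type = "prob")[, "RS"]
      prob_sum[te, k_i] <- prob_sum[te, k_i] + p
      prob_cnt[te, k_i] <- prob_cnt[te, k_i] + 1L
      auc_rep[r, k_i] <- .auc_rs_high(p, as.character(y[te]))
    }
  }

  pooled <- prob_sum / ifelse(prob_cnt == 0, NA_real_, prob_cnt)
  h <- match(headline, subset_sizes)
  probs <- pooled[, h]
  tested <- !is.na(probs)
  auc <- .auc_rs_high(probs[tested], as.character(y)[tested])
  predicted <- ifelse(probs > 0.5, "RS", "NRS")
  accuracy <- 100 * mean(predicted[tested] == as.character(y)[tested])

  boot_means <- vapply(seq_len(n_boot), function(i) {
    mean(sample(auc_rep[, h], n_repeats, replace = TRUE))
  }, numeric(1))
  ci <- unname(quantile(boot_means, c(0.025, 0.975)))

  ranking <- tibble::tibble(feature = names(imp_sum),
                            importance = unname(imp_sum) / n_repeats) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature)

  structure(
    list(auc = auc,
         ci_low = ci[1], ci_high = ci[2],
         predictive_accuracy = accuracy,
         class_probabilities = probs,
         predicted_class = predicted,
         labels = setNames(as.character(y), rownames(x)),
         feature_ranking = ranking,
         per_subset = tibble::tibble(subset_size = subset_sizes,
                                     mean_auc = colMeans(auc_rep)),
         auc_per_repeat = auc_rep[, h],
         headline_subset = headline,
         settings = list(n_repeats = n_repeats, train_frac = train_frac,
                         n_boot = n_boot, ntree = ntree, seed = seed)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Random-forest ROC model (top %d features, %d repeats)\n",
              x$headline_subset, x$settings$n_repeats))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f), predictive accuracy %.1f%%\n",
              x$auc, x$ci_low, x$ci_high, x$predictive_accuracy))
  invisible(x)
}

#' Rank discriminating features and flag candidate predictors
#'
#' Merges the model's importance ranking with the per-feature univariate
#' AUCs, the direction of the intensity difference and the class mean
#' intensities. The report also carries the fraction of features more
#' intense in NRS; since a usable predictive biomarker of response should
#' be elevated in responders, the RS-high features form the
#' candidate-predictor subset.
#'
#' @param result A `roc_result` from [multivariate_roc()].
#' @param ft The [feature_table()] the model was fitted on.
#' @return Tibble sorted by importance with columns `feature`,
#'   `importance`, `auc`, `higher_in`, `mean_RS`, `mean_NRS`,
#'   `candidate_predictor`; attributes `fraction_higher_in_nrs` and
#'   `candidate_predictors`.
#' @export
rank_discriminating_features <- function(result, ft) {
  stopifnot(inherits(result, "roc_result"), inherits(ft, "feature_table"))
  uni <- univariate_roc(ft)
  keep <- ft$sample_roles == "study" & !is.na(ft$class_labels)
  mat <- ft$intensities[keep, , drop = FALSE]
  lab <- ft$class_labels[keep]
  means <- tibble::tibble(
    feature = colnames(mat),
    mean_RS = colMeans(mat[lab == "RS", , drop = FALSE]),
    mean_NRS = colMeans(mat[lab == "NRS", , drop = FALSE]))
  rep <- result$feature_ranking |>
    dplyr::left_join(uni, by = "feature") |>
    dplyr::left_join(means, by = "feature") |>
    dplyr::mutate(candidate_predictor = .data$higher_in == "RS")
  attr(rep, "fraction_higher_in_nrs") <- mean(rep$higher_in == "NRS")
  attr(rep, "candidate_predictors") <-
    rep$feature[rep$candidate_predictor]
  rep
}
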