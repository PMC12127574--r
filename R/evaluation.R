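#' Min-max scaling to [0, 1]
#'
#' `x -> (x - min) / (max - min)`. Used to map enrichment scores from
#' methods that can go negative onto the unit interval. A constant input
#' has no spread to scale; by convention it returns all zeros with a
#' warning.
#'
#' @param x numeric vector with at least one finite value.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @examples
#' min_max_scale(c(1, 2, 4))  # 0, 1/3, 1
#' @export
min_max_scale <- function(x) {
  .assert(length(x) >= 1L, "input", "empty input")
  .assert(all(is.finite(x)), "data", "non-finite values in input")
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    warning("constant input: min-max scale returns all zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Sensitivity, specificity and balanced accuracy
#'
#' sensitivity = TP / (TP + FN); specificity = TN / (FP + TN); balanced
#' accuracy = their mean. A rate with a zero denominator is reported as
#' `NaN` and listed in the `undefined` field rather than raising an error.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return List with `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `undefined` (character vector naming any undefined rate).
#' @examples
#' confusion_metrics(tp = 8, fp = 1, tn = 9, fn = 2)  # 0.8, 0.9, 0.85
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  .assert(all(counts >= 0) && all(counts == round(counts)), "input",
          "counts must be non-negative integers")
  .assert(sum(counts) >= 1, "input", "at least one count must be positive")
  undefined <- character()
  sens <- if (tp + fn == 0) { undefined <- c(undefined, "sensitivity"); NaN
  } else tp / (tp + fn)
  spec <- if (fp + tn == 0) { undefined <- c(undefined, "specificity"); NaN
  } else tn / (fp + tn)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2, undefined = undefined)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement between two labelings of the
#' same items: 1 for identical partitions (up to relabeling), about 0 for
#' agreement expected by chance. The true (possibly slightly negative)
#' value is returned, not truncated at 0.
#'
#' @param labels_a,labels_b equal-length label vectors over the same items.
#' @return A single number, at most 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  .assert(length(labels_a) == length(labels_b), "input",
          "label vectors must have equal length")
  .assert(length(labels_a) >= 2L, "input", "need at least two items")
  mclust::adjustedRandIndex(as.character(labels_a), as.character(labels_b))
}

#' Average silhouette coefficient of a clustering
#'
#' Mean per-sample silhouette width over the columns of an enrichment (or
#' any feature) matrix under the given cluster labels; lies in `[-1, 1]`,
#' with large positive values indicating well-separated clusters and
#' negative values suggesting misassigned samples. Clusters of size one
#' contribute a silhouette of 0.
#'
#' @param scores a `gdgse` fit or a numeric matrix with samples in columns.
#' @param cluster_labels cluster label per sample (at least two clusters).
#' @param distance distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return Mean silhouette width (single number).
#' @export
silhouette_summary <- function(scores, cluster_labels,
                               distance = "euclidean") {
  m <- if (inherits(scores, "gdgse")) scores$scores else scores
  .assert(is.matrix(m), "input", "'scores' must be a matrix or gdgse fit")
  .assert(length(cluster_labels) == ncol(m), "input",
          "one cluster label per sample (column) is required")
  cl <- as.integer(factor(cluster_labels))
  .assert(length(unique(cl)) >= 2L, "config",
          "silhouette needs at least two clusters")
  sil <- cluster::silhouette(cl, dist(t(m), method = distance))
  mean(sil[, "sil_width"])
}

#' Coefficient of variation (percent)
#'
#' Sample standard deviation (n - 1 divisor) expressed as a percentage of
#' the mean: `100 * sd(x) / mean(x)`. Used to quantify stability of
#' enrichment scores across noise-injected datasets. Note this deliberately
#' differs from the population-divisor standard deviation used for the
#' binarization threshold. A zero mean is flagged and returns `NaN`.
#'
#' @param x numeric vector of length >= 2.
#' @return Percentage (single number), or `NaN` with a warning if the mean
#'   is zero.
#' @examples
#' coefficient_of_variation(c(1, 2, 3, 4))  # 100 * sqrt(5/3) / 2.5
#' @export
coefficient_of_variation <- function(x) {
  .assert(length(x) >= 2L, "input", "need at least two values")
  m <- mean(x)
  if (m == 0) {
    warning("zero mean: coefficient of variation undefined")
    return(NaN)
  }
  100 * sd(x) / m
}

#' Per-class one-vs-rest classification metrics
#'
#' Reduces a multi-class prediction to binary confusion counts per class
#' (class vs all others) and macro-averages sensitivity, specificity and
#' balanced accuracy across classes. Predicted labels must already use the
#' same vocabulary as the truth (map cluster ids to class names first).
#'
#' @param predicted,truth equal-length label vectors.
#' @return List with `per_class` (data.frame of counts and rates per class)
#'   and `macro` (named vector of macro-averaged rates).
#' @export
classification_metrics <- function(predicted, truth) {
  .assert(length(predicted) == length(truth), "input",
          "'predicted' and 'truth' lengths differ")
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tn <- sum(predicted != cl & truth != cl)
    cm <- confusion_metrics(tp, fp, tn, fn)
    data.frame(class = cl, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               balanced_accuracy = cm$balanced_accuracy)
  }))
  rownames(per_class) <- NULL
  list(per_class = per_class,
       macro = c(sensitivity = mean(per_class$sensitivity),
                 specificity = mean(per_class$specificity),
                 balanced_accuracy = mean(per_class$balanced_accuracy)))
}
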