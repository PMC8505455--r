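#' Train a Gaussian naive Bayes classifier
#'
#' Class-conditional Gaussian model with per-feature means and, by default,
#' a single pooled within-class variance per feature (per-class variances
#' behind a flag; with very few exemplars per class the pooled estimate is
#' far more stable). Priors are uniform. Variances are floored at
#' `1e-6` times the feature's overall variance (and at an absolute 1e-12)
#' so constant features never cause division errors.
#'
#' @param features items x features numeric matrix.
#' @param labels class label per item; every class needs >= 1 exemplar.
#' @param variance `"pooled"` (default) or `"per_class"`.
#' @return An object of class `gnb_model`: list with `means` (classes x
#'   features), `var` (features, or classes x features), `log_prior`,
#'   `levels`, `variance`.
#' @export
train_gnb <- function(features, labels, variance = c("pooled", "per_class")) {
  variance <- match.arg(variance)
  X <- as.matrix(features)
  y <- as.factor(labels)
  counts <- table(y)
  if (any(counts == 0)) {
    stop("class with 0 exemplars: ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  K <- nlevels(y)
  mu <- rowsum(X, y) / as.vector(counts)
  centered <- X - mu[as.integer(y), , drop = FALSE]
  overall <- apply(X, 2, stats::var)
  overall[!is.finite(overall)] <- 0
  floor_v <- pmax(1e-6 * overall, 1e-12)
  if (variance == "pooled") {
    df <- max(nrow(X) - K, 1)
    v <- colSums(centered^2) / df
    v <- pmax(v, floor_v)
  } else {
    v <- rowsum(centered^2, y) / pmax(as.vector(counts) - 1, 1)
    v <- pmax(v, rep(floor_v, each = K))
  }
  structure(list(means = mu, var = v,
                 log_prior = stats::setNames(rep(-log(K), K), levels(y)),
                 levels = levels(y), variance = variance),
            class = "gnb_model")
}

#' Posterior scores from a Gaussian naive Bayes model
#'
#' @param object a `gnb_model`.
#' @param newdata items x features matrix (same feature order as training).
#' @param type `"log_posterior"` (unnormalized log posterior, default),
#'   `"posterior"` (normalized probabilities) or `"class"`.
#' @param ... unused.
#' @return items x classes matrix of scores (or a class label vector).
#' @export
predict.gnb_model <- function(object, newdata,
                              type = c("log_posterior", "posterior", "class"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  K <- length(object$levels)
  lp <- matrix(NA_real_, nrow(X), K, dimnames = list(NULL, object$levels))
  for (k in seq_len(K)) {
    v <- if (object$variance == "pooled") object$var else object$var[k, ]
    D <- sweep(X, 2, object$means[k, ], "-")
    lp[, k] <- -0.5 * (D^2 %*% (1 / v)) - 0.5 * sum(log(2 * pi * v)) +
      object$log_prior[k]
  }
  if (type == "log_posterior") return(lp)
  post <- exp(lp - apply(lp, 1, max))
  post <- post / rowSums(post)
  if (type == "posterior") return(post)
  object$levels[max.col(lp, ties.method = "first")]
}

#' Normalized rank accuracy of classifier scores
#'
#' For each item, the rank `r` of the true class in the descending ordering
#' of the classifier's scores (ties receive their average rank) is
#' normalized to `(n - r) / (n - 1)`, so a top-ranked true class scores 1,
#' a bottom-ranked one 0, and uniformly random orderings average 0.5. The
#' measure is invariant under any strictly monotone transform of the
#' scores.
#'
#' @param class_scores items x classes matrix of scores with class column
#'   names (higher = more likely), or a single named score vector.
#' @param true_labels true class per item.
#' @return An object of class `rank_accuracy`: list with `per_item`,
#'   `mean`, `n_classes`, `n_items`.
#' @export
rank_accuracy <- function(class_scores, true_labels) {
  if (is.null(dim(class_scores))) {
    class_scores <- matrix(class_scores, nrow = 1,
                           dimnames = list(NULL, names(class_scores)))
  }
  n <- ncol(class_scores)
  if (n < 2) stop("need at least 2 classes")
  cls <- colnames(class_scores)
  if (is.null(cls)) stop("class_scores must have class column names")
  true_labels <- as.character(true_labels)
  miss <- setdiff(unique(true_labels), cls)
  if (length(miss)) stop("true label(s) absent from score columns: ",
                         paste(miss, collapse = ", "))
  per <- vapply(seq_len(nrow(class_scores)), function(i) {
    r <- rank(-class_scores[i, ], ties.method = "average")[true_labels[i]]
    (n - r) / (n - 1)
  }, 1.0)
  structure(list(per_item = per, mean = mean(per),
                 n_classes = n, n_items = length(per)),
            class = "rank_accuracy")
}

#' @export
print.rank_accuracy <- function(x, ...) {
  cat(sprintf("rank_accuracy: mean %.4f over %d item(s), %d classes\n",
              x$mean, x$n_items, x$n_classes))
  invisible(x)
}
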