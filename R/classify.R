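# ---------------------------------------------------------------------------
# Linear discriminant analysis with leave-one-out jackknife validation.
# Shared-covariance Gaussian classifier; posteriors by maximum posterior.
# ---------------------------------------------------------------------------

#' Fit a linear discriminant classifier
#'
#' Gaussian classifier with per-group means and a pooled within-group
#' covariance matrix. Classification and posterior probabilities follow the
#' maximum-posterior rule under the shared-covariance model. When the pooled
#' covariance is ill-conditioned a ridge term `1e-8 * tr(S)/k * I` is added
#' (reported via a message and the `ridged` flag).
#'
#' @param x numeric matrix, specimens x variables.
#' @param groups group labels, one per row.
#' @param priors `"proportional"` (to group sizes, default) or `"uniform"`,
#'   or a named numeric vector of prior probabilities.
#' @return object of class `lda_shape`.
#' @export
lda_fit <- function(x, groups, priors = c("proportional", "uniform")) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(groups) != nrow(x)) stop("one group label per row required")
  counts <- table(groups)
  if (any(counts < 2))
    warning("group(s) with < 2 specimens contribute a mean only: ",
            paste(names(counts)[counts < 2], collapse = ", "))
  k <- ncol(x)
  n <- nrow(x)
  means <- rowsum(x, groups) / as.vector(counts)
  centred <- x - means[as.integer(groups), , drop = FALSE]
  S <- crossprod(centred) / (n - nlevels(groups))
  ridged <- FALSE
  ok <- FALSE
  Sinv <- tryCatch({
    if (kappa(S, exact = FALSE) < 1e12) { ok <- TRUE; solve(S) } else NULL
  }, error = function(e) NULL)
  if (!ok) {
    lambda <- 1e-8 * sum(diag(S)) / k
    S <- S + diag(lambda, k)
    Sinv <- solve(S)
    ridged <- TRUE
    message("pooled covariance ill-conditioned; ridge term ",
            format(lambda), " added")
  }
  pr <- if (is.numeric(priors)) {
    p <- priors[levels(groups)]
    if (anyNA(p)) stop("numeric priors must be named by group")
    p / sum(p)
  } else if (match.arg(priors) == "proportional") {
    as.vector(counts) / n
  } else {
    rep(1 / nlevels(groups), nlevels(groups))
  }
  names(pr) <- levels(groups)
  structure(list(means = means, cov = S, cov_inv = Sinv, priors = pr,
                 counts = counts, levels = levels(groups), ridged = ridged),
            class = "lda_shape")
}

#' @export
print.lda_shape <- function(x, ...) {
  cat("Linear discriminant model:", length(x$levels), "groups,",
      ncol(x$means), "variables", if (x$ridged) "(ridge-regularized)", "\n")
  invisible(x)
}

#' Predict group membership from a fitted discriminant model
#'
#' @param object an `lda_shape` model.
#' @param newdata numeric matrix of specimens to classify.
#' @param ... unused.
#' @return list with `class` (factor of predictions) and `posterior`
#'   (matrix of posterior probabilities, one column per group).
#' @export
predict.lda_shape <- function(object, newdata, ...) {
  newdata <- rbind(as.matrix(newdata))
  g <- length(object$levels)
  logp <- matrix(0, nrow(newdata), g, dimnames = list(NULL, object$levels))
  for (j in seq_len(g)) {
    d <- sweep(newdata, 2, object$means[j, ])
    logp[, j] <- -0.5 * rowSums((d %*% object$cov_inv) * d) +
      log(object$priors[j])
  }
  shifted <- exp(logp - apply(logp, 1, max))
  posterior <- shifted / rowSums(shifted)
  cls <- factor(object$levels[max.col(posterior, ties.method = "first")],
                levels = object$levels)
  list(class = cls, posterior = posterior)
}

#' Leave-one-out jackknife classification
#'
#' Each specimen is predicted by a model refitted without it (the full model
#' is recomputed per fold). Folds whose removal empties a group are predicted
#' among the remaining groups and flagged.
#'
#' @inheritParams lda_fit
#' @return object of class `confusion_table`: `counts` (prior x predicted),
#'   `per_group_accuracy`, `overall_accuracy`, `predicted`,
#'   `posterior` (per-specimen posterior probabilities), and
#'   `flagged` (indices of folds with an emptied group).
#' @export
jackknife_classify <- function(x, groups, priors = c("proportional", "uniform")) {
  x <- as.matrix(x)
  groups <- factor(groups)
  n <- nrow(x)
  if (n < nlevels(groups) + 2)
    stop("too few specimens for leave-one-out validation")
  levs <- levels(groups)
  predicted <- character(n)
  posterior <- matrix(NA_real_, n, length(levs),
                      dimnames = list(rownames(x), levs))
  flagged <- integer(0)
  for (i in seq_len(n)) {
    gi <- droplevels(groups[-i])
    if (nlevels(gi) < nlevels(groups)) flagged <- c(flagged, i)
    fit <- suppressWarnings(lda_fit(x[-i, , drop = FALSE], gi, priors))
    pr <- predict(fit, x[i, , drop = FALSE])
    predicted[i] <- as.character(pr$class)
    posterior[i, colnames(pr$posterior)] <- pr$posterior[1, ]
  }
  predicted <- factor(predicted, levels = levs)
  counts <- table(prior = groups, predicted = predicted)
  per_group <- diag(counts) / rowSums(counts)
  structure(list(counts = counts,
                 per_group_accuracy = per_group,
                 overall_accuracy = sum(diag(counts)) / n,
                 predicted = predicted, posterior = posterior,
                 flagged = flagged),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Leave-one-out classification: overall accuracy %.1f%% (n = %d)\n",
              100 * x$overall_accuracy, sum(x$counts)))
  acc <- sort(x$per_group_accuracy)
  cat(sprintf("  per-group accuracy from %.1f%% (%s) to %.1f%% (%s)\n",
              100 * acc[1], names(acc)[1],
              100 * acc[length(acc)], names(acc)[length(acc)]))
  invisible(x)
}

#' Per-group accuracy from a confusion table
#'
#' The proportion of a prior group's specimens assigned back to that group.
#'
#' @param ct a `confusion_table`.
#' @param group group label (row of the table).
#' @return fraction in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(ct, group) {
  stopifnot(inherits(ct, "confusion_table"))
  if (!group %in% rownames(ct$counts)) stop("unknown group '", group, "'")
  row <- ct$counts[group, ]
  total <- sum(row)
  if (total == 0) stop("group '", group, "' has no specimens")
  unname(row[group] / total)
}
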