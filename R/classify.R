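#' Train a cell-type classifier on pivot cells
#'
#' Pivot cells — the subset of imaging cells with high-confidence
#' cross-modality matches and transferred type labels — seed annotation of
#' the whole imaging dataset: a linear multiclass support vector machine is
#' fit on their scaled protein features and then applied to every remaining
#' cell. A stratified holdout is carved from the pivots to report per-class
#' F1 scores.
#'
#' @param pivots A `protein_matrix` (scaled cells) restricted to pivot cells.
#' @param labels Character vector of pivot cell-type labels.
#' @param markers Feature columns; defaults to [marker_names()].
#' @param holdout_fraction Fraction of pivots held out per class for the F1
#'   report. Default 0.2.
#' @param cost SVM cost parameter. Default 1.
#' @param seed Integer seed for the stratified split.
#' @return A `label_classifier`; see [predict_labels()], `glance()` gives
#'   overall holdout accuracy, `tidy()` the per-class precision/recall/F1.
#' @export
train_label_classifier <- function(pivots, labels, markers = NULL,
                                   holdout_fraction = 0.2, cost = 1,
                                   seed = 1L) {
  markers <- markers %||% marker_names(pivots)
  X <- as.matrix(as_tibble(pivots)[, markers, drop = FALSE])
  y <- as.character(labels)
  if (length(y) != nrow(X)) abort("`labels` must match the pivot rows.")
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("At least 2 classes are required to train the classifier.")
  tab <- table(y)
  if (any(tab < 5)) {
    abort(paste0("Every class needs >= 5 pivot cells; short: ",
                 paste(names(tab)[tab < 5], collapse = ", ")))
  }
  holdout <- withr::with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1, round(length(idx) * holdout_fraction)))
    }))
  })
  train <- setdiff(seq_along(y), holdout)
  fit <- e1071::svm(x = X[train, , drop = FALSE],
                    y = factor(y[train], levels = classes),
                    kernel = "linear", cost = cost, scale = FALSE)
  pred_hold <- as.character(predict(fit, X[holdout, , drop = FALSE]))
  truth_hold <- y[holdout]
  per_class <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(pred_hold == cl & truth_hold == cl)
    fp <- sum(pred_hold == cl & truth_hold != cl)
    fn <- sum(pred_hold != cl & truth_hold == cl)
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
      NA_real_ else 2 * precision * recall / (precision + recall)
    tibble(label = cl, n_holdout = tp + fn, precision = precision,
           recall = recall, f1 = f1)
  })
  structure(list(fit = fit, markers = markers, classes = classes,
                 holdout_report = per_class,
                 holdout_accuracy = mean(pred_hold == truth_hold),
                 n_train = length(train), n_holdout = length(holdout)),
            class = "label_classifier")
}

#' Predict cell-type labels from protein features
#'
#' Applies a trained [train_label_classifier()] model. Labels come from the
#' SVM argmax; per-class scores are a softmax over the one-vs-one decision
#' values, reported for auditing only.
#'
#' @param classifier A `label_classifier`.
#' @param cells A `protein_matrix` (or any tibble carrying the classifier's
#'   marker columns).
#' @return Tibble with `label` plus one `score_<class>` column per class.
#' @export
predict_labels <- function(classifier, cells) {
  X <- as.matrix(as_tibble(cells)[, classifier$markers, drop = FALSE])
  pr <- predict(classifier$fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # fold one-vs-one decision values into per-class votes, then softmax
  classes <- classifier$classes
  votes <- matrix(0, nrow(X), length(classes),
                  dimnames = list(NULL, classes))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    votes[, pair[1]] <- votes[, pair[1]] + dv[, cn]
    votes[, pair[2]] <- votes[, pair[2]] - dv[, cn]
  }
  sm <- exp(votes - apply(votes, 1, max))
  sm <- sm / rowSums(sm)
  colnames(sm) <- paste0("score_", classes)
  dplyr::bind_cols(tibble(label = as.character(pr)), as_tibble(sm))
}

#' @rdname train_label_classifier
#' @param x A `label_classifier`.
#' @param ... Unused.
#' @export
glance.label_classifier <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_train = x$n_train,
         n_holdout = x$n_holdout, holdout_accuracy = x$holdout_accuracy,
         macro_f1 = mean(x$holdout_report$f1, na.rm = TRUE))
}

#' @rdname train_label_classifier
#' @export
tidy.label_classifier <- function(x, ...) {
  x$holdout_report
}

#' @export
print.label_classifier <- function(x, ...) {
  cat(sprintf("<label_classifier> linear SVM, %d classes, %d features; holdout accuracy %.3f\n",
              length(x$classes), length(x$markers), x$holdout_accuracy))
  invisible(x)
}
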