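#' n-agreement ensemble vote
#'
#' Positive prediction if and only if at least `n` of the base models call
#' positive.
#'
#' @param calls samples x models matrix of binary calls (0/1); typically 8
#'   columns (4 classifiers x 2 feature-selection filters).
#' @param n agreement threshold, between 1 and the number of base models.
#' @return integer vector of 0/1 ensemble calls.
#' @export
n_agreement <- function(calls, n) {
  calls <- as.matrix(calls)
  if (length(n) != 1 || n < 1 || n > ncol(calls)) {
    stop("n must be a single integer between 1 and ", ncol(calls))
  }
  as.integer(rowSums(calls) >= n)
}

#' Turn base-model scores into binary calls
#'
#' @param scores samples x models score matrix.
#' @param threshold call threshold on the scores (default 0.5).
#' @return 0/1 matrix of the same shape.
#' @export
binary_calls <- function(scores, threshold = 0.5) {
  m <- (as.matrix(scores) > threshold) + 0L
  dimnames(m) <- dimnames(scores)
  m
}

#' Best agreement threshold per fold
#'
#' Within each fold's test samples, evaluates the n-agreement ensemble at
#' every `n` from 1 to the number of base models and records the `n` with
#' the maximum AUC (ties go to the smaller `n`). Per-fold optima are then
#' averaged, mirroring how the tuned threshold is reported.
#'
#' @param calls samples x models binary call matrix (out-of-fold calls).
#' @param y 0/1 labels aligned with `calls`.
#' @param fold integer fold assignment per sample.
#' @return list with `per_fold` (data.frame `fold`, `n_star`, `auc`),
#'   `mean_n`, `sd_n`, `mean_auc`.
#' @export
best_n_per_fold <- function(calls, y, fold) {
  calls <- as.matrix(calls)
  stopifnot(nrow(calls) == length(y), length(fold) == length(y))
  nb <- ncol(calls)
  res <- lapply(sort(unique(fold)), function(f) {
    idx <- which(fold == f)
    if (length(unique(y[idx])) < 2) {
      warning("fold ", f, " has a single class; skipped")
      return(NULL)
    }
    aucs <- vapply(seq_len(nb), function(n) {
      auc(n_agreement(calls[idx, , drop = FALSE], n), y[idx])
    }, numeric(1))
    n_star <- which.max(aucs) # which.max takes the first (smallest n) on ties
    data.frame(fold = f, n_star = n_star, auc = aucs[n_star])
  })
  per_fold <- do.call(rbind, res)
  list(per_fold = per_fold,
       mean_n = mean(per_fold$n_star), sd_n = stats::sd(per_fold$n_star),
       mean_auc = mean(per_fold$auc))
}

#' Stacked ensemble supervisor
#'
#' Trains a supervisor model on the 8-column matrix of out-of-fold base
#' scores: the samples are shuffled (seeded) and re-partitioned into
#' `n_folds` new folds; the supervisor is trained on the base scores of the
#' other folds and predicts each held-out fold, so no sample's own label
#' enters its supervisor prediction.
#'
#' @param scores samples x models matrix of *out-of-fold* base scores.
#' @param y 0/1 labels.
#' @param supervisor `"logistic"` (glm, binomial) or `"random_forest"`
#'   (500 trees).
#' @param seed RNG seed for the re-partition.
#' @param n_folds number of supervisor folds.
#' @return list with `scores` (out-of-fold supervisor scores, original
#'   sample order), `fold` (supervisor fold per sample), `auc`.
#' @export
stack <- function(scores, y, supervisor = c("logistic", "random_forest"),
                  seed = 1, n_folds = 10) {
  supervisor <- match.arg(supervisor)
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(y))
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("base", seq_len(ncol(scores)))
  }
  n <- nrow(scores)
  set.seed(seed)
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(n_folds), n)
  out <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- fold == f
    if (supervisor == "logistic") {
      df <- data.frame(y = y, scores, check.names = FALSE)
      m <- stats::glm(y ~ ., data = df[tr, , drop = FALSE], family = stats::binomial())
      out[te] <- stats::predict(m, newdata = df[te, , drop = FALSE],
                                type = "response")
    } else {
      m <- ranger::ranger(y = factor(y[tr], levels = c(0, 1)),
                          x = as.data.frame(scores[tr, , drop = FALSE]),
                          num.trees = 500, probability = TRUE,
                          seed = seed + f, num.threads = 1)
      out[te] <- stats::predict(m, data = as.data.frame(scores[te, , drop = FALSE]),
                                num.threads = 1)$predictions[, "1"]
    }
  }
  list(scores = out, fold = fold, auc = auc(out, y))
}
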