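# Lagged-sample feature extraction and shrinkage LDA decoding.

#' Feature extraction window configuration
#'
#' Features are raw narrow-band EEG samples taken at lags spaced
#' `spacing` seconds apart within a window of `length` seconds (lag count
#' `floor(length/spacing) + 1`; a zero-length window yields one sample per
#' channel). With `alignment = "center"` (offline analysis) the lags are
#' placed symmetrically about the evaluation time; with
#' `alignment = "causal"` (online path) all lags lie at or before it.
#'
#' @param length window length in seconds (0 to 1.4 studied).
#' @param spacing lag spacing in seconds (default 0.2).
#' @param alignment `"center"` or `"causal"`.
#' @param step sliding-window step in seconds (default 1/16).
#' @export
feature_window_config <- function(length = 1.4, spacing = 0.2,
                                  alignment = c("center", "causal"),
                                  step = 1 / 16) {
  alignment <- match.arg(alignment)
  stopifnot(length >= 0, spacing > 0, step > 0)
  n_lags <- floor(length / spacing + 1e-9) + 1
  structure(list(length = length, spacing = spacing,
                 alignment = alignment, step = step, n_lags = n_lags,
                 span = (n_lags - 1) * spacing),
            class = "feature_window_config")
}

#' Lag times of a feature window at a reference time
#' @param cfg a [feature_window_config()].
#' @param t_ref evaluation time (s).
#' @return Numeric vector of lag times (s).
#' @export
lag_times <- function(cfg, t_ref) {
  base <- (seq_len(cfg$n_lags) - 1) * cfg$spacing
  if (cfg$alignment == "center") t_ref - cfg$span / 2 + base
  else t_ref - cfg$span + base
}

#' Extract lagged-sample features from an epoch set
#'
#' Builds the trials x features matrix of raw microvolt samples of the
#' good EEG channels at the window's lag grid. Feature ordering is
#' channel-major: all lags of the first channel, then all lags of the
#' second, and so on. Rejected trials are retained here (filter with
#' [drop_rejected()] first if desired).
#'
#' @param epochs an [epoch_set()].
#' @param t_ref evaluation time in seconds (same axis as
#'   [epoch_times()]).
#' @param cfg a [feature_window_config()].
#' @return Numeric matrix, trials x (channels * lags), with column names
#'   `<channel>@<lag>s`.
#' @export
extract_features <- function(epochs, t_ref, cfg) {
  lt <- lag_times(cfg, t_ref)
  tax <- epoch_times(epochs)
  idx <- round((lt - epochs$t0_offset) * epochs$rate) + 1
  if (any(idx < 1 | idx > length(tax)))
    stop("feature lag outside the epoch window: lag time(s) ",
         paste(signif(lt[idx < 1 | idx > length(tax)], 4), collapse = ", "),
         " s not within [", signif(tax[1], 4), ", ",
         signif(tax[length(tax)], 4), "] s")
  chans <- which(epochs$channels$kind == "EEG" & !epochs$channels$is_bad)
  n_tr <- dim(epochs$data)[1]
  X <- matrix(0, n_tr, length(chans) * length(idx))
  col <- 1
  cn <- character(ncol(X))
  for (ci in chans) {
    for (li in seq_along(idx)) {
      X[, col] <- epochs$data[, ci, idx[li]]
      cn[col] <- paste0(epochs$channels$name[ci], "@",
                        signif(lt[li], 4), "s")
      col <- col + 1
    }
  }
  colnames(X) <- cn
  X
}

#' Fit a multiclass shrinkage LDA classifier
#'
#' Linear discriminant analysis with the pooled within-class covariance
#' shrunk towards a scaled identity: `Sigma(lambda) = (1 - lambda) * S +
#' lambda * nu * I`, where `nu` is the mean diagonal of `S`. The shrinkage
#' intensity is estimated analytically from the data with the
#' Ledoit-Wolf/Schaefer-Strimmer formula (ratio of the summed sampling
#' variances of the entries of `S` to the summed squared deviations from
#' the target, clipped to [0, 1]) unless `lambda` is forced. Discriminant
#' weights are `w_c = Sigma^-1 mu_c` with the standard LDA bias
#' `-mu_c' Sigma^-1 mu_c / 2 + log pi_c`.
#'
#' @param X trials x features matrix.
#' @param y class labels (factor or character).
#' @param lambda optional fixed shrinkage in [0, 1]; `NULL` = analytic.
#' @param priors `"empirical"` (class proportions) or `"uniform"`.
#' @return An object of class `slda` with elements `classes`, `means`
#'   (features x classes), `W`, `b`, `lambda`, `nu`.
#' @export
fit_slda <- function(X, y, lambda = NULL, priors = c("empirical",
                                                     "uniform")) {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("feature count is 0")
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2) stop("need at least 2 classes")
  counts <- table(y)
  if (any(counts < 2)) stop("every class needs at least 2 trials")
  n <- nrow(X); d <- ncol(X); K <- length(classes)

  means <- sapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  means <- matrix(means, nrow = d,
                  dimnames = list(colnames(X), classes))
  Z <- X - t(means)[y, , drop = FALSE]          # class-centered
  neff <- n - K
  S <- crossprod(Z) / neff
  nu <- mean(diag(S))

  if (is.null(lambda)) {
    # Schaefer-Strimmer estimate of sum Var(s_ij), target nu * I
    wbar <- crossprod(Z) / n
    w2 <- crossprod(Z^2) / n
    varS <- n / (n - 1)^3 * n * (w2 - wbar^2)
    target <- diag(nu, d)
    denom <- sum((S - target)^2)
    lambda <- if (denom > 0) sum(varS) / denom else 1
    lambda <- min(1, max(0, lambda))
  }
  Sig <- (1 - lambda) * S + lambda * nu * diag(d)
  W <- tryCatch(solve(Sig, means), error = function(e)
    stop("pooled covariance is singular at lambda = ", signif(lambda, 3),
         "; refit with lambda > 0", call. = FALSE))
  pri <- if (priors == "empirical") as.numeric(counts) / n
         else rep(1 / K, K)
  b <- -0.5 * colSums(means * W) + log(pri)
  structure(list(classes = classes, means = means, W = W, b = b,
                 lambda = lambda, nu = nu, priors = pri,
                 n_features = d),
            class = "slda")
}

#' @export
print.slda <- function(x, ...) {
  cat("<slda> ", length(x$classes), " classes, ", x$n_features,
      " features, lambda = ", signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Class probabilities / predictions of a shrinkage LDA model
#'
#' Discriminant scores are passed through a softmax to obtain class
#' probabilities (rows sum to 1). Predicted class is the probability
#' argmax; exact ties resolve to the lowest class index.
#'
#' @param object an `slda` model.
#' @param newdata trials x features matrix.
#' @param type `"prob"`, `"class"` or `"score"`.
#' @param ... unused.
#' @export
predict.slda <- function(object, newdata,
                         type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature dimension (", ncol(newdata),
         ") does not match model (", object$n_features, ")")
  sc <- newdata %*% object$W
  sc <- sweep(sc, 2, object$b, "+")
  colnames(sc) <- object$classes
  if (type == "score") return(sc)
  p <- exp(sc - apply(sc, 1, max))
  p <- p / rowSums(p)
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

# stratified fold assignments: one integer matrix column per repeat
.make_folds <- function(y, folds, repeats) {
  y <- factor(y)
  if (any(table(y) < folds))
    stop("every class needs at least as many trials as folds")
  n <- length(y)
  out <- matrix(0L, n, repeats)
  for (r in seq_len(repeats)) {
    f <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    out[, r] <- f
  }
  out
}

# CV predictions at one window position; returns factor of predictions
# pooled over folds for each repeat (list of factors)
.cv_predict <- function(X, y, fold_mat, lambda = NULL) {
  folds <- max(fold_mat)
  lapply(seq_len(ncol(fold_mat)), function(r) {
    pred <- factor(rep(levels(factor(y))[1], length(y)),
                   levels = levels(factor(y)))
    for (k in seq_len(folds)) {
      te <- fold_mat[, r] == k
      model <- fit_slda(X[!te, , drop = FALSE], y[!te], lambda = lambda)
      pred[te] <- predict(model, X[te, , drop = FALSE], type = "class")
    }
    pred
  })
}

#' Sliding-window cross-validated accuracy curve
#'
#' At each window position (step `cfg$step` along the epoch) the lagged
#' features are extracted and classified with repeated stratified
#' trial-based k-fold cross-validation (folds partition trials, never
#' samples). Accuracy at a position is the mean over all folds and
#' repeats of the per-fold percentage of correctly classified trials, and
#' is aligned to the center of the feature extraction window. Rejected
#' trials are excluded. Deterministic given `seed`.
#'
#' @param epochs an [epoch_set()].
#' @param cfg a [feature_window_config()].
#' @param folds,repeats cross-validation setup (default 10 x 10).
#' @param seed RNG seed for the fold assignments.
#' @param times evaluation times (s); defaults to all positions where the
#'   window fits inside the epoch.
#' @param lambda optional fixed shrinkage passed to [fit_slda()].
#' @return An `accuracy_curve`: `data.frame` with `time` and `accuracy`
#'   (%), with the per-fold matrix in attribute `"folds"` (rows = times).
#' @export
sliding_accuracy <- function(epochs, cfg = feature_window_config(),
                             folds = 10, repeats = 10, seed = 1,
                             times = NULL, lambda = NULL) {
  epochs <- drop_rejected(epochs)
  y <- factor(epochs$labels)
  tax <- epoch_times(epochs)
  if (is.null(times)) {
    half_lo <- if (cfg$alignment == "center") cfg$span / 2 else cfg$span
    half_hi <- if (cfg$alignment == "center") cfg$span / 2 else 0
    lo <- tax[1] + half_lo
    hi <- tax[length(tax)] - half_hi - 1 / epochs$rate
    times <- seq(ceiling(lo / cfg$step) * cfg$step, hi, by = cfg$step)
  }
  set.seed(seed)
  fold_mat <- .make_folds(y, folds, repeats)
  acc <- matrix(0, length(times), folds * ncol(fold_mat))
  for (ti in seq_along(times)) {
    X <- extract_features(epochs, times[ti], cfg)
    preds <- .cv_predict(X, y, fold_mat, lambda = lambda)
    col <- 1
    for (r in seq_along(preds)) {
      for (k in seq_len(folds)) {
        te <- fold_mat[, r] == k
        acc[ti, col] <- 100 * mean(preds[[r]][te] == y[te])
        col <- col + 1
      }
    }
  }
  out <- data.frame(time = times, accuracy = rowMeans(acc))
  attr(out, "folds") <- acc
  attr(out, "n_trials") <- length(y)
  class(out) <- c("accuracy_curve", class(out))
  out
}

#' Cross-validated confusion matrix at one window position
#'
#' Row-normalized to 100% per true class, pooled over folds and repeats.
#'
#' @inheritParams sliding_accuracy
#' @param t_peak evaluation time (s), typically the accuracy peak.
#' @return classes x classes matrix in percent (rows = true class).
#' @export
confusion_at <- function(epochs, t_peak, cfg = feature_window_config(),
                         folds = 10, repeats = 10, seed = 1,
                         lambda = NULL) {
  epochs <- drop_rejected(epochs)
  y <- factor(epochs$labels)
  set.seed(seed)
  fold_mat <- .make_folds(y, folds, repeats)
  X <- extract_features(epochs, t_peak, cfg)
  preds <- .cv_predict(X, y, fold_mat, lambda = lambda)
  cm <- matrix(0, nlevels(y), nlevels(y),
               dimnames = list(true = levels(y), predicted = levels(y)))
  for (p in preds) cm <- cm + table(y, p)
  100 * cm / rowSums(cm)
}
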