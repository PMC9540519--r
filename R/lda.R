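#' Train a two-class shrinkage LDA classifier
#'
#' Linear discriminant analysis with a shared, shrinkage-regularized
#' within-class covariance: `Sigma = (1 - gamma) S + gamma (tr(S)/d) I`
#' where `S` is the pooled within-class covariance and `gamma` is either
#' given or set by a Ledoit-Wolf-style estimate (sample sizes of ~30 per
#' class with 10 features make some regularization advisable). The weight
#' vector is `w = Sigma^-1 (mu_pos - mu_neg)`; the bias places the boundary
#' at the pooled midpoint plus the log prior ratio (priors are the
#' empirical class frequencies).
#'
#' @param X Numeric matrix, trials x features.
#' @param y Labels containing `"positive"` and `"negative"`, at least two
#'   trials each.
#' @param gamma Shrinkage intensity in `[0, 1]`, or `"lw"` for the
#'   Ledoit-Wolf estimate.
#' @return An object of class `bci_lda`: class means, pooled covariance,
#'   shrunk covariance, `w`, `bias`, priors, per-class counts, feature
#'   names.
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' fit <- train_lda(X, rep(c("negative", "positive"), each = 20))
#' predict(fit, X[1, ])$label
#' @export
train_lda <- function(X, y, gamma = "lw") {
  X <- as.matrix(X)
  oldClass(X) <- NULL
  attr(X, "provenance") <- NULL
  attr(X, "labels") <- NULL
  attr(X, "feature_type") <- NULL
  if (!all(c("positive", "negative") %in% y))
    stop("train_lda: both classes must be present")
  if (any(table(y) < 2)) stop("train_lda: each class needs >= 2 trials")
  d <- ncol(X)
  n <- nrow(X)
  mu_p <- colMeans(X[y == "positive", , drop = FALSE])
  mu_n <- colMeans(X[y == "negative", , drop = FALSE])
  ctr <- X
  ctr[y == "positive", ] <- sweep(X[y == "positive", , drop = FALSE], 2, mu_p)
  ctr[y == "negative", ] <- sweep(X[y == "negative", , drop = FALSE], 2, mu_n)
  S <- crossprod(ctr) / (n - 2)
  if (identical(gamma, "lw")) gamma <- lw_shrinkage(ctr)
  Sg <- (1 - gamma) * S + gamma * (sum(diag(S)) / d) * diag(d)
  w <- tryCatch(solve(Sg, mu_p - mu_n),
                error = function(e)
                  stop("train_lda: covariance singular despite shrinkage: ",
                       conditionMessage(e)))
  priors <- c(positive = mean(y == "positive"), negative = mean(y == "negative"))
  bias <- -sum(w * (mu_p + mu_n)) / 2 + log(priors["positive"] / priors["negative"])
  if (!all(is.finite(c(w, bias))))
    stop("train_lda: non-finite model parameters")
  structure(list(mu_pos = mu_p, mu_neg = mu_n, cov_pooled = S, cov = Sg,
                 gamma = gamma, w = as.numeric(w), bias = as.numeric(bias),
                 priors = priors,
                 n_per_class = c(positive = sum(y == "positive"),
                                 negative = sum(y == "negative")),
                 features = colnames(X)),
            class = "bci_lda")
}

# Ledoit-Wolf shrinkage intensity toward the scaled identity, computed on
# class-mean-centered rows.
lw_shrinkage <- function(ctr) {
  n <- nrow(ctr); d <- ncol(ctr)
  S <- crossprod(ctr) / n
  m <- sum(diag(S)) / d
  d2 <- sum((S - m * diag(d))^2)
  if (d2 == 0) return(0)
  b2 <- 0
  for (i in seq_len(n)) b2 <- b2 + sum((tcrossprod(ctr[i, ]) - S)^2)
  b2 <- min(b2 / n^2, d2)
  min(1, max(0, b2 / d2))
}

#' @export
print.bci_lda <- function(x, ...) {
  cat(sprintf("bci_lda: %d features, n = %d + %d, shrinkage %.3f\n",
              length(x$w), x$n_per_class[1], x$n_per_class[2], x$gamma))
  invisible(x)
}

#' @export
coef.bci_lda <- function(object, ...) {
  out <- c(object$w, bias = object$bias)
  if (!is.null(object$features)) names(out)[seq_along(object$w)] <- object$features
  out
}

#' Predict valence from feature vectors
#'
#' The discriminant value is `g(x) = w'x + bias` and the positive-class
#' posterior its logistic transform; the label is positive iff the
#' posterior is at least 0.5 (exact ties classify positive).
#'
#' @param object A [train_lda()] model.
#' @param newdata Numeric vector (one trial) or matrix (trials x features)
#'   in the model's feature order.
#' @param ... Unused.
#' @return Data frame with `label`, `posterior` (positive class, in
#'   `[0, 1]`) and `discriminant`.
#' @export
predict.bci_lda <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != length(object$w))
    stop("predict.bci_lda: feature dimension mismatch (got ", ncol(X),
         ", model has ", length(object$w), ")")
  if (!is.null(object$features) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$features))
    stop("predict.bci_lda: feature provenance mismatch")
  # row-wise products: identical arithmetic whether trials are scored one
  # at a time (online) or as a batch, so replays are bit-for-bit equal
  g <- as.numeric(rowSums(X * matrix(object$w, nrow(X), ncol(X),
                                     byrow = TRUE)) + object$bias)
  post <- plogis(g)
  data.frame(label = ifelse(post >= 0.5, "positive", "negative"),
             posterior = post, discriminant = g)
}

#' Serialize / restore an LDA model as JSON
#'
#' Enables session-to-session reuse of trained models.
#'
#' @param model A `bci_lda` object.
#' @param path Output (input) JSON path.
#' @return `write_lda`: `path` invisibly; `read_lda`: the restored model.
#' @export
write_lda <- function(model, path) {
  obj <- unclass(model)
  obj$cov_pooled <- as.numeric(obj$cov_pooled)
  obj$cov_dim <- length(obj$w)
  obj$cov <- as.numeric(obj$cov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda
#' @export
read_lda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$cov_dim
  obj$cov_pooled <- matrix(obj$cov_pooled, d, d)
  obj$cov <- matrix(obj$cov, d, d)
  obj$cov_dim <- NULL
  obj$priors <- unlist(obj$priors)
  obj$n_per_class <- unlist(obj$n_per_class)
  obj$mu_pos <- unlist(obj$mu_pos)
  obj$mu_neg <- unlist(obj$mu_neg)
  structure(obj, class = "bci_lda")
}
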