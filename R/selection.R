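#' Fisher criterion for class separability
#'
#' Multivariate Fisher criterion `J = trace(S_W^-1 S_B)` with
#' ridge-regularized within-class scatter (`S_W + eps I`,
#' `eps = ridge * trace(S_W)/d`). `S_W` is the pooled within-class scatter
#' (sum of squared deviations from class means) and `S_B` the between-class
#' scatter (`sum_c n_c (mu_c - mu)(mu_c - mu)'`). For a single feature this
#' reduces to the scalar separation ratio; `J >= 0`, and `J` is invariant
#' under invertible affine feature maps in the `eps -> 0` limit.
#'
#' @param X Numeric matrix, trials x features.
#' @param y Class labels, two classes, each with at least two trials.
#' @param ridge Relative ridge on the within-class scatter.
#' @return Scalar criterion value.
#' @examples
#' fisher_score(matrix(c(0, 1, 10, 11)), c("a", "a", "b", "b"))  # 100
#' @export
fisher_score <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  cls <- unique(y)
  if (length(cls) != 2) stop("fisher_score: need exactly two classes, got ",
                             length(cls))
  if (any(table(y) < 2)) stop("fisher_score: each class needs >= 2 trials")
  d <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in cls) {
    Xc <- X[y == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    ctr <- sweep(Xc, 2, mc)
    Sw <- Sw + crossprod(ctr)
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - mu)
  }
  eps <- ridge * (sum(diag(Sw)) / d)
  if (eps <= 0) eps <- ridge
  J <- sum(diag(solve(Sw + diag(eps, d), Sb)))
  max(J, 0)
}

#' Sequential floating forward selection of channels
#'
#' Pudil-style floating search with `l = r = 1` steps: repeatedly add the
#' candidate maximizing the Fisher criterion of the grown subset, then
#' conditionally remove members while removal improves the best known
#' criterion value at the smaller size. The search floats a few sizes above
#' the target and returns the best subset of exactly `target` channels.
#' Ties in the criterion are broken toward the lowest channel id, making
#' the search deterministic.
#'
#' @param X Numeric matrix, trials x candidate channels (one feature column
#'   per channel).
#' @param y Two-class labels.
#' @param target Subset size to return.
#' @param channel_ids Ids reported for the columns of `X` (default 1..d).
#' @param float_above How far above `target` the search may float.
#' @param max_iter Iteration cap (guards non-convergence).
#' @param ridge Passed to [fisher_score()].
#' @return Sorted integer vector of `target` channel ids, with the achieved
#'   criterion value as attribute `score`.
#' @export
sffs_select <- function(X, y, target = 5, channel_ids = seq_len(ncol(X)),
                        float_above = 5, max_iter = 500, ridge = 1e-6) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (d < target) stop("sffs_select: fewer candidate channels (", d,
                       ") than target (", target, ")")
  if (length(unique(y)) != 2) stop("sffs_select: need two classes")
  kmax <- min(d, target + float_above)
  bestJ <- rep(-Inf, kmax)
  best <- vector("list", kmax)
  # precomputed within/between scatter; subset criteria are then small solves,
  # numerically identical to fisher_score() on the subset columns
  S <- scatter_matrices(X, y)
  J_of <- function(idx) J_subset(S, idx, ridge)

  cur <- integer(0)
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    k <- length(cur)
    if (k < kmax) {
      # forward: most significant candidate (ties -> lowest column index)
      cand <- setdiff(seq_len(d), cur)
      js <- vapply(cand, function(f) J_of(c(cur, f)), 0)
      f <- cand[which.max(js)]
      cur <- c(cur, f)
      k <- k + 1
      if (js[match(f, cand)] > bestJ[k] + 1e-12) {
        bestJ[k] <- js[match(f, cand)]
        best[[k]] <- sort(cur)
      }
    }
    # conditional exclusion while it improves the best at the smaller size
    while (length(cur) > 2) {
      kk <- length(cur)
      js <- vapply(seq_along(cur), function(i) J_of(cur[-i]), 0)
      i <- which.max(js)
      if (js[i] > bestJ[kk - 1] + 1e-12) {
        cur <- cur[-i]
        bestJ[kk - 1] <- js[i]
        best[[kk - 1]] <- sort(cur)
      } else break
    }
    if (length(cur) >= kmax) break
  }
  if (is.null(best[[target]]))
    stop("sffs_select: search did not reach the target size (iteration cap ",
         max_iter, ")")
  structure(sort(channel_ids[best[[target]]]), score = bestJ[target])
}

#' Select the five best channels per chromophore
#'
#' Runs [sffs_select()] independently on the 22 oxygenated and the 22
#' deoxygenated feature columns of a feature matrix, yielding the combined
#' 10-feature subset used by the classifier.
#'
#' @param fm A [build_feature_matrix()] result (both chromophores present).
#' @param y Labels; defaults to the labels attached to `fm`.
#' @param target Channels per chromophore.
#' @return An object of class `bci_channel_subset`: list with `hbo`, `hbr`
#'   (channel ids), `score_hbo`, `score_hbr`, and `columns` (the 10 column
#'   indices into the feature matrix, oxygenated first).
#' @export
select_channels <- function(fm, y = attr(fm, "labels"), target = 5) {
  prov <- attr(fm, "provenance")
  if (is.null(prov)) stop("select_channels: feature matrix has no provenance")
  out <- list()
  cols <- integer(0)
  for (chrom in c("hbo", "hbr")) {
    j <- which(prov$chromophore == chrom)
    if (!length(j)) stop("select_channels: chromophore ", chrom, " absent")
    sel <- sffs_select(fm[, j, drop = FALSE], y, target = target,
                       channel_ids = prov$channel[j])
    out[[chrom]] <- as.integer(sel)
    out[[paste0("score_", chrom)]] <- attr(sel, "score")
    cols <- c(cols, j[match(out[[chrom]], prov$channel[j])])
  }
  out$columns <- cols
  class(out) <- "bci_channel_subset"
  out
}

#' @export
print.bci_channel_subset <- function(x, ...) {
  cat("channel subset: HbO {", paste(x$hbo, collapse = ","), "} J =",
      signif(x$score_hbo, 4), "; Hb {", paste(x$hbr, collapse = ","),
      "} J =", signif(x$score_hbr, 4), "\n")
  invisible(x)
}

scatter_matrices <- function(X, y) {
  X <- as.matrix(X)
  d <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (cl in unique(y)) {
    Xc <- X[y == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    ctr <- sweep(Xc, 2, mc)
    Sw <- Sw + crossprod(ctr)
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - mu)
  }
  list(Sw = Sw, Sb = Sb)
}

J_subset <- function(S, idx, ridge = 1e-6) {
  k <- length(idx)
  Sw <- S$Sw[idx, idx, drop = FALSE]
  eps <- ridge * (sum(diag(Sw)) / k)
  if (eps <= 0) eps <- ridge
  max(sum(diag(solve(Sw + diag(eps, k), S$Sb[idx, idx, drop = FALSE]))), 0)
}

# exhaustive-search oracle over all size-`target` subsets (small d only)
exhaustive_select <- function(X, y, target = 5, ridge = 1e-6) {
  S <- scatter_matrices(X, y)
  combos <- utils::combn(ncol(X), target)
  js <- apply(combos, 2, function(idx) J_subset(S, idx, ridge))
  structure(sort(combos[, which.max(js)]), score = max(js))
}
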