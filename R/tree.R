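# Minimal regression trees used by the random-forest and gradient-boosting
# families. Splits minimize within-node squared error (variance reduction);
# the "Gini criterion" sometimes quoted for regression forests is a
# classification impurity and has no regression analogue, so variance
# reduction is the substituted criterion. At benchmark scale (<= 8 rows)
# exhaustive split search is trivially cheap, so no compiled code is needed.

fit_regression_tree <- function(X, y, mtry = ncol(X), max_depth = Inf,
                                min_split = 2L) {
  grow <- function(idx, depth) {
    node_mean <- mean(y[idx])
    if (length(idx) < min_split || depth >= max_depth ||
        stats::var(y[idx]) == 0 || is.na(stats::var(y[idx])))
      return(list(leaf = TRUE, value = node_mean))
    feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
    best <- list(sse = Inf)
    base_sse <- sum((y[idx] - node_mean)^2)
    yi <- y[idx]; ni <- length(idx)
    for (j in feats) {
      xv <- X[idx, j]
      ord <- order(xv)
      xs <- xv[ord]; ys <- yi[ord]
      distinct <- which(diff(xs) > 0)        # split after these positions
      if (!length(distinct)) next
      csum <- cumsum(ys); csq <- cumsum(ys^2)
      nl <- distinct
      sl <- csum[nl]; ql <- csq[nl]
      sr <- csum[ni] - sl; qr <- csq[ni] - ql
      sse <- (ql - sl^2 / nl) + (qr - sr^2 / (ni - nl))
      k <- which.min(sse)
      if (sse[k] < best$sse - 1e-12)
        best <- list(sse = sse[k], j = j,
                     s = (xs[distinct[k]] + xs[distinct[k] + 1L]) / 2)
    }
    if (!is.finite(best$sse) || best$sse >= base_sse - 1e-12)
      return(list(leaf = TRUE, value = node_mean))
    keep <- X[idx, best$j] <= best$s
    list(leaf = FALSE, feature = best$j, threshold = best$s,
         left = grow(idx[keep], depth + 1L),
         right = grow(idx[!keep], depth + 1L))
  }
  grow(seq_along(y), 0L)
}

predict_regression_tree <- function(tree, X) {
  one <- function(node, x) {
    while (!node$leaf)
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    node$value
  }
  apply(X, 1L, function(x) one(tree, x))
}

# Random forest: bootstrap rows, random feature subset per node is
# approximated by a random subset per tree (adequate at these problem
# sizes), variance-reduction splits, unrestricted depth.
fit_random_forest <- function(X, y, n_trees = 100L,
                              mtry = max(1L, floor(ncol(X) / 3)),
                              max_depth = Inf) {
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
    trees[[b]] <- fit_regression_tree(X[idx, , drop = FALSE], y[idx],
                                      mtry = mtry, max_depth = max_depth)
  }
  structure(list(trees = trees), class = "phx_forest")
}

predict_random_forest <- function(forest, X) {
  preds <- vapply(forest$trees,
                  function(tr) predict_regression_tree(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
}

# Gradient boosting with squared-error loss: each round fits a depth-limited
# tree to the residuals and moves the fit by `learning_rate` times it.
fit_gbt <- function(X, y, n_rounds = 200L, learning_rate = 0.1,
                    max_depth = 6L) {
  f0 <- mean(y)
  fit <- rep(f0, length(y))
  trees <- vector("list", n_rounds)
  for (b in seq_len(n_rounds)) {
    r <- y - fit
    tr <- fit_regression_tree(X, r, max_depth = max_depth)
    trees[[b]] <- tr
    fit <- fit + learning_rate * predict_regression_tree(tr, X)
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate),
            class = "phx_gbt")
}

predict_gbt <- function(model, X) {
  pred <- rep(model$f0, nrow(X))
  for (tr in model$trees)
    pred <- pred + model$learning_rate * predict_regression_tree(tr, X)
  pred
}

# Partial least squares (NIPALS, univariate response): components are
# extracted from centered data and regression is rebuilt from the deflation
# history. ncomp must be below the training rank.
fit_pls <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  W <- P <- matrix(0, ncol(X), ncomp)
  qv <- numeric(ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) { ncomp <- a - 1L; break }
    p <- drop(crossprod(Xc, t_)) / tt
    q <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p)
    yc <- yc - q * t_
    W[, a] <- w; P[, a] <- p; qv[a] <- q; Tm[, a] <- t_
  }
  if (ncomp == 0L)
    return(structure(list(coef = rep(0, ncol(X)), intercept = ym, xm = xm),
                     class = "phx_pls"))
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  R <- W %*% solve(crossprod(P, W))
  beta <- drop(R %*% qv)
  structure(list(coef = beta, intercept = ym, xm = xm), class = "phx_pls")
}

predict_pls <- function(model, X) {
  drop(sweep(X, 2L, model$xm) %*% model$coef) + model$intercept
}

# Ridge regression in closed form: coefficients solve
# (Xc'Xc + lambda I) beta = Xc'y on centered data; the intercept is not
# penalized. Kept in-package (rather than glmnet) so the estimator matches
# the textbook closed form exactly.
fit_ridge <- function(X, y, lambda) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  p <- ncol(X)
  beta <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc))
  structure(list(coef = drop(beta), intercept = ym, xm = xm,
                 lambda = lambda), class = "phx_ridge")
}

predict_ridge <- function(model, X) {
  drop(sweep(X, 2L, model$xm) %*% model$coef) + model$intercept
}
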