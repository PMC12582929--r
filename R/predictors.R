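#' Assemble the cross-phase supervised table
#'
#' Builds the regression problem "predict later-phase protein abundance
#' from earlier multi-omics profiles": rows are samples aligned by
#' (strain, replicate) across phases; predictor columns are metabolite
#' abundances at both phases and protein abundances at the earlier phase;
#' targets are protein abundances at the later phase. Features or targets
#' with any missing value are dropped and logged. Values are stored raw —
#' the per-modality scaling scheme (minmax for metabolomics, standardize
#' for proteomics, standardize for targets) is recorded here and applied
#' inside each cross-validation fold by [run_loocv()], so no scaling
#' statistics ever leak across folds.
#'
#' @param metab_t0,metab_t1 metabolomics `AbundanceMatrix` at the earlier
#'   and later phase.
#' @param prot_t0,prot_t1 proteomics `AbundanceMatrix` at the earlier and
#'   later phase (`prot_t1` supplies the targets).
#' @param target_ids optional subset of target protein ids.
#' @param log2_input log2-transform abundances before assembly (default
#'   TRUE): stabilizes variance and keeps the regression on the scale the
#'   fold-change analytics use. Predictions are transformed back to the
#'   abundance scale by the cross-validation drivers.
#' @return a `FeatureTable`: `features` (n x p matrix), `targets`
#'   (n x q matrix), `col_modality` (per feature column), `meta`
#'   (strain/replicate per row), `dropped` (drop log), `log2` flag.
#' @export
build_supervised_table <- function(metab_t0, metab_t1, prot_t0, prot_t1,
                                   target_ids = NULL, log2_input = TRUE) {
  mats <- list(met0 = metab_t0, met1 = metab_t1,
               prot0 = prot_t0, prot1 = prot_t1)
  for (m in mats) stopifnot(inherits(m, "AbundanceMatrix"))
  if (log2_input) mats <- lapply(mats, log2_transform)
  key <- function(m) paste(m$samples$strain, m$samples$replicate, sep = ":")
  keys <- lapply(mats, key)
  ref <- sort(keys[[1L]])
  for (nm in names(keys)) {
    extra <- setdiff(keys[[nm]], ref)
    gone <- setdiff(ref, keys[[nm]])
    if (length(extra) || length(gone))
      stop("unpairable replicate ", c(extra, gone)[1L], " in ", nm,
           call. = FALSE)
  }
  # canonical row order: WT replicates ascending, then MUT
  ord_key <- ref[order(!grepl("^WT", ref),
                       as.integer(sub(".*:", "", ref)))]
  aligned <- lapply(mats, function(m) {
    idx <- match(ord_key, key(m))
    vals <- t(m$values[feature_ids(m), idx, drop = FALSE])
    rownames(vals) <- ord_key
    vals
  })
  dropped <- list()
  complete_cols <- function(x, tag) {
    bad <- colnames(x)[colSums(is.na(x)) > 0L]
    if (length(bad)) dropped[[tag]] <<- bad
    x[, colSums(is.na(x)) == 0L, drop = FALSE]
  }
  met0 <- complete_cols(aligned$met0, "metab_t0")
  met1 <- complete_cols(aligned$met1, "metab_t1")
  pr0 <- complete_cols(aligned$prot0, "prot_t0")
  pr1 <- complete_cols(aligned$prot1, "prot_t1")
  if (!is.null(target_ids)) {
    miss <- setdiff(target_ids, colnames(pr1))
    if (length(miss))
      stop("target protein unavailable (missing values?): ", miss[1L],
           call. = FALSE)
    pr1 <- pr1[, target_ids, drop = FALSE]
  }
  features <- cbind(met0, met1, pr0)
  colnames(features) <- c(paste0("met0_", colnames(met0)),
                          paste0("met1_", colnames(met1)),
                          paste0("prot0_", colnames(pr0)))
  col_modality <- rep(c("metabolomics", "metabolomics", "proteomics"),
                      c(ncol(met0), ncol(met1), ncol(pr0)))
  meta <- data.frame(strain = sub(":.*", "", ord_key),
                     replicate = as.integer(sub(".*:", "", ord_key)),
                     stringsAsFactors = FALSE)
  structure(list(features = features, targets = pr1,
                 col_modality = col_modality, meta = meta,
                 dropped = dropped, log2 = log2_input),
            class = "FeatureTable")
}

#' Model specification for the regression benchmark
#'
#' Families and their fixed hyperparameters: `ridge`/`lasso` pick their
#' regularization strength from a logarithmic grid (1e-3..1e3, 7 points) by
#' inner leave-one-out within each training fold; `rf` uses 100 trees with
#' unrestricted depth and variance-reduction splits; `gbt` uses learning
#' rate 0.1, depth 6, 200 rounds; `pls` uses `min(3, rank - 1)` components;
#' `mean` is the intercept-only baseline.
#'
#' @param family one of `"pls"`, `"ridge"`, `"lasso"`, `"rf"`, `"gbt"`,
#'   `"mean"`.
#' @param seed integer seed for the stochastic families.
#' @param ... family-specific overrides (`lambda`, `lambda_grid`, `ncomp`,
#'   `n_trees`, `n_rounds`, `learning_rate`, `max_depth`).
#' @return a `ModelSpec` list.
#' @export
model_spec <- function(family = c("pls", "ridge", "lasso", "rf", "gbt",
                                  "mean"),
                       seed = 1L, ...) {
  family <- match.arg(family)
  hp <- switch(family,
    ridge = list(lambda_grid = 10^seq(-3, 3, length.out = 7), lambda = NULL),
    lasso = list(lambda_grid = 10^seq(-3, 3, length.out = 7), lambda = NULL),
    pls = list(ncomp = NULL),
    rf = list(n_trees = 100L, max_depth = Inf),
    gbt = list(n_rounds = 200L, learning_rate = 0.1, max_depth = 6L),
    mean = list())
  dots <- list(...)
  hp[names(dots)] <- dots
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "ModelSpec")
}

scale_fold <- function(train, test, modality) {
  ctr <- numeric(ncol(train)); scl <- numeric(ncol(train))
  for (j in seq_len(ncol(train))) {
    x <- train[, j]
    if (modality[j] == "metabolomics") {         # minmax on train stats
      ctr[j] <- min(x); r <- max(x) - min(x)
      scl[j] <- if (r == 0) 1 else r
    } else {                                     # standardize on train stats
      ctr[j] <- mean(x)
      s <- if (length(x) > 1L) stats::sd(x) else 0
      scl[j] <- if (is.na(s) || s == 0) 1 else s
    }
  }
  list(train = sweep(sweep(train, 2L, ctr), 2L, scl, "/"),
       test = sweep(sweep(test, 2L, ctr), 2L, scl, "/"),
       center = ctr, scale = scl)
}

fit_family <- function(spec, X, y, fold, target) {
  hp <- spec$hyperparameters
  switch(spec$family,
    mean = {
      mu <- mean(y)
      list(predict = function(Xn) rep(mu, nrow(Xn)))
    },
    ridge = {
      lam <- hp$lambda
      if (is.null(lam)) lam <- pick_lambda_inner(X, y, hp$lambda_grid,
                                                 ridge = TRUE)
      mod <- fit_ridge(X, y, lam)
      list(predict = function(Xn) predict_ridge(mod, Xn), lambda = lam)
    },
    lasso = {
      lam <- hp$lambda
      if (is.null(lam)) lam <- pick_lambda_inner(X, y, hp$lambda_grid,
                                                 ridge = FALSE)
      mod <- fit_lasso(X, y, lam)
      list(predict = function(Xn) predict_lasso(mod, Xn), lambda = lam)
    },
    pls = {
      nc <- hp$ncomp
      if (is.null(nc)) nc <- max(1L, min(3L, qr(scale(X, scale = FALSE))$rank - 1L))
      mod <- fit_pls(X, y, nc)
      list(predict = function(Xn) predict_pls(mod, Xn))
    },
    rf = {
      set.seed(spec$seed * 10000L + fold * 100L + target)
      mod <- fit_random_forest(X, y, n_trees = hp$n_trees,
                               max_depth = hp$max_depth)
      list(predict = function(Xn) predict_random_forest(mod, Xn))
    },
    gbt = {
      set.seed(spec$seed * 10000L + fold * 100L + target)
      mod <- fit_gbt(X, y, n_rounds = hp$n_rounds,
                     learning_rate = hp$learning_rate,
                     max_depth = hp$max_depth)
      list(predict = function(Xn) predict_gbt(mod, Xn))
    })
}

fit_lasso <- function(X, y, lambda) {
  Xg <- if (ncol(X) < 2L) cbind(X, `.pad` = 0) else X
  mod <- glmnet::glmnet(Xg, y, alpha = 1, lambda = lambda,
                        standardize = FALSE)
  structure(list(mod = mod, pad = ncol(X) < 2L), class = "phx_lasso")
}

predict_lasso <- function(model, X) {
  Xg <- if (model$pad) cbind(X, `.pad` = 0) else X
  drop(stats::predict(model$mod, newx = Xg))
}

pick_lambda_inner <- function(X, y, grid, ridge = TRUE) {
  n <- nrow(X)
  if (n < 3L) return(grid[ceiling(length(grid) / 2)])
  err <- numeric(length(grid))
  for (g in seq_along(grid)) {
    se <- 0
    for (i in seq_len(n)) {
      mod <- if (ridge) fit_ridge(X[-i, , drop = FALSE], y[-i], grid[g])
             else fit_lasso(X[-i, , drop = FALSE], y[-i], grid[g])
      pr <- if (ridge) predict_ridge(mod, X[i, , drop = FALSE])
            else predict_lasso(mod, X[i, , drop = FALSE])
      se <- se + (pr - y[i])^2
    }
    err[g] <- se
  }
  grid[which.min(err)]  # which.min breaks ties toward the smaller lambda
}

#' Leave-one-out cross-validation of one model family
#'
#' For every row i: scaling statistics are estimated on the remaining rows
#' only (no leakage), the model is fit per target on the scaled training
#' fold, and row i is predicted. MSE is the mean squared error over all
#' (fold, target) pairs on the standardized target scale; predictions are
#' also inverse-transformed back to the abundance scale. Targets that are
#' constant within a training fold are skipped with a warning.
#'
#' @param table a [build_supervised_table()] result.
#' @param spec a [model_spec()].
#' @return a `CVResult`: `family`, `mse`, `per_target_mse`,
#'   `predictions` (held-out, abundance scale), `predictions_scaled`,
#'   `observed_scaled`, `fold_scalers`, `folds`, `table_signature`.
#' @export
run_loocv <- function(table, spec) {
  stopifnot(inherits(table, "FeatureTable"), inherits(spec, "ModelSpec"))
  X <- table$features; Y <- table$targets
  n <- nrow(X); q <- ncol(Y)
  if (n < 3L && spec$family != "mean")
    stop("need at least 3 rows for LOOCV", call. = FALSE)
  pred_scaled <- obs_scaled <- pred_raw <-
    matrix(NA_real_, n, q, dimnames = dimnames(Y))
  fold_scalers <- vector("list", n)
  skipped <- character(0)
  for (i in seq_len(n)) {
    sx <- scale_fold(X[-i, , drop = FALSE], X[i, , drop = FALSE],
                     table$col_modality)
    sy <- scale_fold(Y[-i, , drop = FALSE], Y[i, , drop = FALSE],
                     rep("proteomics", q))
    fold_scalers[[i]] <- list(features = sx[c("center", "scale")],
                              targets = sy[c("center", "scale")])
    for (t in seq_len(q)) {
      ytr <- sy$train[, t]
      if (stats::var(ytr) == 0 || is.na(stats::var(ytr))) {
        if (spec$family != "mean") { skipped <- c(skipped, colnames(Y)[t]); next }
      }
      mod <- fit_family(spec, sx$train, ytr, i, t)
      ps <- mod$predict(sx$test)
      pred_scaled[i, t] <- ps
      obs_scaled[i, t] <- sy$test[, t]
      pr <- ps * sy$scale[t] + sy$center[t]
      pred_raw[i, t] <- if (isTRUE(table$log2)) 2^pr else pr
    }
  }
  if (length(skipped))
    warning("constant target skipped in some folds: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  sq <- (pred_scaled - obs_scaled)^2
  structure(list(family = spec$family,
                 mse = mean(sq, na.rm = TRUE),
                 per_target_mse = colMeans(sq, na.rm = TRUE),
                 predictions = pred_raw,
                 predictions_scaled = pred_scaled,
                 observed_scaled = obs_scaled,
                 fold_scalers = fold_scalers,
                 folds = seq_len(n),
                 table_signature = table_signature(table)),
            class = "CVResult")
}

table_signature <- function(table) {
  c(dim(table$features), dim(table$targets),
    sum(table$features), sum(table$targets))
}

#' Rank benchmarked models by LOOCV error
#'
#' @param results list of `CVResult` objects from the same table.
#' @return data.frame ordered by ascending MSE (alphabetical tiebreak on
#'   the family name), with the per-target breakdown attached as attribute
#'   `per_target`.
#' @export
rank_models <- function(results) {
  if (length(results) < 2L)
    stop("need at least two results to rank", call. = FALSE)
  sigs <- lapply(results, `[[`, "table_signature")
  if (!all(vapply(sigs, identical, logical(1), sigs[[1L]])))
    stop("results come from different tables", call. = FALSE)
  fam <- vapply(results, `[[`, character(1), "family")
  mse <- vapply(results, `[[`, numeric(1), "mse")
  ord <- order(mse, fam)
  out <- data.frame(rank = seq_along(ord), family = fam[ord],
                    mse = mse[ord], stringsAsFactors = FALSE)
  attr(out, "per_target") <- do.call(
    rbind, lapply(results[ord], function(r)
      data.frame(family = r$family, target = names(r$per_target_mse),
                 mse = unname(r$per_target_mse), stringsAsFactors = FALSE)))
  out
}
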