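#' Scale an abundance matrix per feature
#'
#' `standardize` centers each feature to mean 0, sd 1 (sample sd, n-1
#' denominator — the convention of the usual ML preprocessing stacks);
#' `minmax` maps each feature to \[0, 1\]. Constant features are dropped
#' with a warning under `standardize` and set to all-0 under `minmax`;
#' all-missing features are dropped with a warning either way. Statistics
#' are computed over non-missing cells and missing cells stay missing.
#'
#' @param m an `AbundanceMatrix`.
#' @param method `"standardize"`, `"minmax"` or `"none"`.
#' @return the scaled `AbundanceMatrix` (`scale = "scaled"`), with the
#'   per-feature scaling record in attribute `scaling`.
#' @export
scale_matrix <- function(m, method = c("standardize", "minmax", "none")) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  method <- match.arg(method)
  if (method == "none") return(m)
  if (ncol(m$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  vals <- m$values
  n_obs <- rowSums(!is.na(vals))
  if (any(n_obs == 0L)) {
    warning("dropping ", sum(n_obs == 0L), " all-missing feature(s)",
            call. = FALSE)
    keep <- n_obs > 0L
    vals <- vals[keep, , drop = FALSE]
    m$is_standard <- m$is_standard[keep]
  }
  if (method == "standardize") {
    mu <- rowMeans(vals, na.rm = TRUE)
    sd_ <- apply(vals, 1L, stats::sd, na.rm = TRUE)
    zero <- !is.na(sd_) & sd_ == 0
    if (any(zero)) {
      warning("dropping ", sum(zero), " zero-variance feature(s)",
              call. = FALSE)
      vals <- vals[!zero, , drop = FALSE]
      mu <- mu[!zero]; sd_ <- sd_[!zero]
      m$is_standard <- m$is_standard[!zero]
    }
    scaled <- (vals - mu) / sd_
    record <- data.frame(feature_id = rownames(vals), center = mu,
                         scale = sd_, method = "standardize",
                         stringsAsFactors = FALSE)
  } else {
    lo <- apply(vals, 1L, min, na.rm = TRUE)
    hi <- apply(vals, 1L, max, na.rm = TRUE)
    rng <- hi - lo
    scaled <- (vals - lo) / ifelse(rng == 0, 1, rng)
    scaled[rng == 0, ] <- 0  # constant feature -> all 0 by convention
    record <- data.frame(feature_id = rownames(vals), center = lo,
                         scale = rng, method = "minmax",
                         stringsAsFactors = FALSE)
  }
  out <- abundance_matrix(scaled, m$samples, m$modality, scale = "scaled",
                          is_standard = m$is_standard)
  attr(out, "scaling") <- record
  out
}

#' Principal component analysis by SVD
#'
#' Columns (variables) are centered internally; components come from the
#' singular value decomposition of the centered matrix, with explained
#' variance `100 * sigma_k^2 / sum(sigma^2)`. Each loading column is flipped
#' so its largest-magnitude entry is positive — a deterministic sign
#' convention that makes plots bit-reproducible across platforms.
#'
#' @param x numeric matrix, observations in rows, variables in columns.
#' @param n_components number of components to keep (truncated to the rank
#'   of the centered matrix, with a warning, if it exceeds it).
#' @return `PCAResult` list: `scores` (observations x components),
#'   `loadings` (variables x components, orthonormal),
#'   `explained_variance_pct` (all components, sums to 100), `center`,
#'   `rank`.
#' @export
fit_pca <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("PCA input must be complete (exclude missing rows)",
                     call. = FALSE)
  if (n_components < 1L || n_components > min(dim(x)))
    stop("n_components must be in 1..min(dim(x))", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc)
  d2 <- sv$d^2
  tol <- max(dim(x)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("input has rank 0 after centering", call. = FALSE)
  if (n_components > rank) {
    warning("requested ", n_components, " components; rank is ", rank,
            call. = FALSE)
    n_components <- rank
  }
  expl <- if (sum(d2) > 0) 100 * d2 / sum(d2) else rep(0, length(d2))
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  scores <- xc %*% loadings
  # sign convention: dominant entry of each loading column positive
  for (j in k) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", k))
  dimnames(loadings) <- list(colnames(x), paste0("PC", k))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_pct = expl[seq_len(rank)],
                 center = ctr, rank = rank),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("PCAResult: %d observations, %d components kept (rank %d)\n",
              nrow(x$scores), k, x$rank))
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance_pct[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' PCA of an abundance matrix
#'
#' Convenience wrapper wiring [scale_matrix()] and [fit_pca()] together.
#' `level = "samples"` treats samples as observations (strain/phase
#' separation plots); `level = "features"` treats features as observations
#' (the biplot layout that positions metabolites). Features with any
#' missing value are excluded — at panel sizes of tens of features,
#' imputation would distort more than it saves.
#'
#' @param m an `AbundanceMatrix`.
#' @param level `"samples"` or `"features"`.
#' @param scale_method passed to [scale_matrix()].
#' @param n_components number of components.
#' @param features optional feature subset (e.g. the significant set).
#' @return a `PCAResult`.
#' @export
pca_abundance <- function(m, level = c("samples", "features"),
                          scale_method = "standardize", n_components = 2L,
                          features = NULL) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  level <- match.arg(level)
  if (!is.null(features)) m <- subset_abundance(m, features = features)
  keep <- feature_ids(m)
  keep <- keep[rowSums(is.na(m$values[keep, , drop = FALSE])) == 0L]
  if (!length(keep)) stop("no complete features for PCA", call. = FALSE)
  m <- subset_abundance(m, features = keep)
  scaled <- scale_matrix(m, scale_method)
  x <- if (level == "samples") t(scaled$values) else scaled$values
  fit_pca(x, n_components)
}

#' Pathway-annotated biplot table
#'
#' Restricts a feature-level PCA to the significant features and attaches
#' pathway labels: one output row per (feature, pathway) pair, with
#' `"unannotated"` for features lacking any annotation.
#'
#' @param pca a `PCAResult` fit with features as observations.
#' @param ann a `PathwayAnnotation`.
#' @param significant_features non-empty character vector of feature ids.
#' @return data.frame: `feature_id`, `PC1`, `PC2`, `pathway`.
#' @export
project_biplot <- function(pca, ann, significant_features) {
  stopifnot(inherits(pca, "PCAResult"))
  if (!length(significant_features))
    stop("significant feature set is empty", call. = FALSE)
  idx <- match(significant_features, rownames(pca$scores))
  if (anyNA(idx))
    stop("feature absent from PCA scores: ",
         significant_features[is.na(idx)][1L], call. = FALSE)
  pc2 <- if (ncol(pca$scores) >= 2L) pca$scores[idx, 2L] else
    rep(0, length(idx))
  rows <- lapply(seq_along(significant_features), function(i) {
    f <- significant_features[i]
    pws <- ann$pathway[ann$feature_id == f]
    if (!length(pws)) pws <- "unannotated"
    data.frame(feature_id = f, PC1 = unname(pca$scores[idx[i], 1L]),
               PC2 = unname(pc2[i]), pathway = pws,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
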