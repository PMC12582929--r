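#' Presence/absence screen
#'
#' A feature counts as detected in a strain iff it has at least
#' `min_detected` non-missing values among that strain's replicates.
#' Features detected in only one strain (the pyruvate-style pattern, where a
#' metabolite is consistently seen in one strain and undetectable in the
#' other) carry real biology but no defensible fold change, so they are
#' reported separately rather than tested.
#'
#' @param m an `AbundanceMatrix` with both strains present.
#' @param min_detected minimum non-missing replicates per strain (default 3
#'   of the 4-replicate design).
#' @return data.frame: `feature_id`, `n_WT`, `n_MUT`, `detection` (one of
#'   `both`, `WT_only`, `MUT_only`, `neither`).
#' @export
presence_absence_screen <- function(m, min_detected = 3L) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  wt <- m$samples$strain == "WT"
  mut <- m$samples$strain == "MUT"
  if (!any(wt) || !any(mut))
    stop("need at least one sample per strain", call. = FALSE)
  if (min_detected > sum(wt) || min_detected > sum(mut))
    stop("min_detected exceeds group size", call. = FALSE)
  keep <- !m$is_standard
  vals <- m$values[keep, , drop = FALSE]
  n_wt <- rowSums(!is.na(vals[, wt, drop = FALSE]))
  n_mut <- rowSums(!is.na(vals[, mut, drop = FALSE]))
  det_wt <- n_wt >= min_detected
  det_mut <- n_mut >= min_detected
  detection <- ifelse(det_wt & det_mut, "both",
               ifelse(det_wt, "WT_only",
               ifelse(det_mut, "MUT_only", "neither")))
  data.frame(feature_id = rownames(vals), n_WT = n_wt, n_MUT = n_mut,
             detection = detection, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-feature log2 fold change (MUT vs WT)
#'
#' `log2(mean_MUT / mean_WT)` with arithmetic means of the normalized
#' abundances over non-missing replicates.
#'
#' @param m an `AbundanceMatrix` on a raw/normalized scale.
#' @param features optional feature subset (default: all non-standard rows).
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(m, features = NULL) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (m$scale == "log2")
    stop("fold changes are computed from abundance-scale values", call. = FALSE)
  if (is.null(features)) features <- feature_ids(m)
  vals <- m$values[features, , drop = FALSE]
  wt <- m$samples$strain == "WT"
  mut <- m$samples$strain == "MUT"
  mean_wt <- rowMeans(vals[, wt, drop = FALSE], na.rm = TRUE)
  mean_mut <- rowMeans(vals[, mut, drop = FALSE], na.rm = TRUE)
  bad <- !is.na(mean_wt) & !is.na(mean_mut) & (mean_wt <= 0 | mean_mut <= 0)
  if (any(bad))
    stop("non-positive group mean for ", features[bad][1L], call. = FALSE)
  stats::setNames(log2(mean_mut / mean_wt), features)
}

#' Two-sample t-test per feature
#'
#' Two-sided Student (pooled-variance) t-test on log2-transformed
#' abundances; Welch's unequal-variance variant behind `welch = TRUE`.
#' Degenerate features (zero pooled variance) give p = 1 when the group
#' means agree and the smallest representable positive p, with a warning,
#' when they differ.
#'
#' @param m an `AbundanceMatrix` (log2-transformed internally if needed).
#' @param features optional feature subset.
#' @param welch use Welch's t-test instead of the pooled-variance Student
#'   test.
#' @return data.frame: `feature_id`, `t`, `df`, `p_value`.
#' @export
ttest_two_sample <- function(m, features = NULL, welch = FALSE) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  lm2 <- if (m$scale == "log2") m else log2_transform(m)
  if (is.null(features)) features <- feature_ids(lm2)
  vals <- lm2$values[features, , drop = FALSE]
  wt <- lm2$samples$strain == "WT"
  mut <- lm2$samples$strain == "MUT"
  out <- data.frame(feature_id = features, t = NA_real_, df = NA_real_,
                    p_value = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  warned <- FALSE
  for (i in seq_along(features)) {
    x <- vals[i, mut]; x <- x[!is.na(x)]   # group 1: MUT
    y <- vals[i, wt]; y <- y[!is.na(y)]    # group 2: WT
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2L || n2 < 2L) next
    d <- mean(x) - mean(y)
    if (welch) {
      v1 <- stats::var(x) / n1; v2 <- stats::var(y) / n2
      se2 <- v1 + v2
      df <- if (se2 > 0) se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
            else n1 + n2 - 2
    } else {
      sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
        (n1 + n2 - 2)
      se2 <- sp2 * (1 / n1 + 1 / n2)
      df <- n1 + n2 - 2
    }
    if (se2 <= 0) {
      if (d == 0) {
        out$t[i] <- 0; out$df[i] <- df; out$p_value[i] <- 1
      } else {
        out$t[i] <- sign(d) * Inf; out$df[i] <- df
        out$p_value[i] <- .Machine$double.xmin
        warned <- TRUE
      }
      next
    }
    tt <- d / sqrt(se2)
    out$t[i] <- tt; out$df[i] <- df
    out$p_value[i] <- 2 * stats::pt(-abs(tt), df)
  }
  if (warned)
    warning("zero within-group variance with unequal means; p reported as ",
            "smallest positive double", call. = FALSE)
  out$p_value[!is.na(out$p_value)] <-
    pmax(out$p_value[!is.na(out$p_value)], .Machine$double.xmin)
  out
}

#' Storey q-values
#'
#' False-discovery-rate estimates in Storey's framework. The null
#' proportion pi0 is estimated as `mean(p > lambda) / (1 - lambda)` at a
#' fixed `lambda` (default 0.5 — transparent and stable for panels of ~80
#' features), clipped to (0, 1]; with `smooth = TRUE` a spline fit over a
#' lambda grid is extrapolated to its right end instead. With pi0 fixed at
#' 1 the q-values reduce exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param lambda fixed tuning point (default 0.5), or the grid when
#'   `smooth = TRUE`.
#' @param smooth use the cubic-smoother grid estimate of pi0.
#' @return numeric q-values in input order, with the pi0 estimate attached
#'   as attribute `pi0`.
#' @export
storey_qvalues <- function(p, lambda = 0.5, smooth = FALSE) {
  if (length(p) < 1L) stop("need at least one p-value", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (smooth) {
    grid <- if (length(lambda) > 1L) lambda else seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(grid, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(grid))$y
  } else {
    pi0 <- mean(p > lambda[1L]) / (1 - lambda[1L])
  }
  pi0 <- min(pi0, 1)
  pi0 <- max(pi0, 1 / m)  # clip away a degenerate zero estimate
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- rev(cummin(rev(pi0 * m * p_sorted / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Classify features by the joint significance gate
#'
#' A feature is significant iff `p < alpha` AND `|log2fc| >= fc_threshold`
#' (defaults 0.05 and 0.58, i.e. a 1.5-fold change). q-values are reported
#' alongside but do not gate significance.
#'
#' @param log2fc,p_value,q_value aligned numeric vectors.
#' @param alpha p-value gate (default 0.05).
#' @param fc_threshold absolute log2 fold-change gate (default 0.58).
#' @return data.frame: `log2fc`, `p_value`, `q_value`, `significant`,
#'   `direction` (`up`/`down`/`none`).
#' @export
classify_features <- function(log2fc, p_value, q_value = NULL,
                              alpha = 0.05, fc_threshold = 0.58) {
  n <- length(log2fc)
  if (length(p_value) != n ||
      (!is.null(q_value) && length(q_value) != n))
    stop("mismatched vector lengths", call. = FALSE)
  if (is.null(q_value)) q_value <- rep(NA_real_, n)
  significant <- !is.na(p_value) & !is.na(log2fc) &
    p_value < alpha & abs(log2fc) >= fc_threshold
  direction <- rep("none", n)
  direction[significant & log2fc > 0] <- "up"
  direction[significant & log2fc < 0] <- "down"
  data.frame(log2fc = log2fc, p_value = p_value, q_value = q_value,
             significant = significant, direction = direction,
             stringsAsFactors = FALSE)
}

#' Differential abundance between strains
#'
#' Full per-feature two-group analysis of one phase: presence/absence
#' screen, log2 fold changes and Student t-tests on the features detected in
#' both strains, Storey q-values over the tested set, and the joint
#' `p < alpha` and `|log2fc| >= fc_threshold` significance gate. Features
#' detected in a single strain are reported with their detection flag and no
#' test statistics.
#'
#' @param m an `AbundanceMatrix` (normalized scale).
#' @param alpha,fc_threshold significance gates (defaults 0.05 / 0.58).
#' @param min_detected detection rule, see [presence_absence_screen()].
#' @param lambda,smooth_pi0 passed to [storey_qvalues()].
#' @param welch use Welch's t-test.
#' @return data.frame of class `DifferentialResult`: `feature_id`,
#'   `log2fc`, `p_value`, `q_value`, `significant`, `direction`,
#'   `detection`, `n_WT`, `n_MUT`; analysis parameters in attributes.
#' @export
differential_abundance <- function(m, alpha = 0.05, fc_threshold = 0.58,
                                   min_detected = 3L, lambda = 0.5,
                                   smooth_pi0 = FALSE, welch = FALSE) {
  screen <- presence_absence_screen(m, min_detected)
  tested <- screen$feature_id[screen$detection == "both"]
  res <- data.frame(feature_id = screen$feature_id,
                    log2fc = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, significant = FALSE,
                    direction = "none", detection = screen$detection,
                    n_WT = screen$n_WT, n_MUT = screen$n_MUT,
                    stringsAsFactors = FALSE)
  if (length(tested)) {
    fc <- log2_fold_change(m, tested)
    tt <- ttest_two_sample(m, tested, welch = welch)
    ok <- !is.na(tt$p_value)
    q <- rep(NA_real_, length(tested))
    if (any(ok)) q[ok] <- storey_qvalues(tt$p_value[ok], lambda = lambda,
                                         smooth = smooth_pi0)
    cls <- classify_features(fc, tt$p_value, q, alpha, fc_threshold)
    idx <- match(tested, res$feature_id)
    res$log2fc[idx] <- cls$log2fc
    res$p_value[idx] <- cls$p_value
    res$q_value[idx] <- cls$q_value
    res$significant[idx] <- cls$significant
    res$direction[idx] <- cls$direction
  }
  attr(res, "alpha") <- alpha
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "min_detected") <- min_detected
  class(res) <- c("DifferentialResult", "data.frame")
  res
}

#' Write a differential result table
#'
#' @param res a `DifferentialResult`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
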