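#' Per-protein predicted fold changes
#'
#' Collapses per-sample abundance-scale predictions to one log2 fold
#' change per protein: replicate means per strain, then
#' `log2(mean_MUT / mean_WT)`.
#'
#' @param preds samples x proteins matrix of predictions on the abundance
#'   scale.
#' @param meta data.frame with a `strain` column aligned to the rows.
#' @return named numeric vector of log2 fold changes.
#' @export
predicted_fold_changes <- function(preds, meta) {
  stopifnot(nrow(preds) == nrow(meta))
  wt <- meta$strain == "WT"; mut <- meta$strain == "MUT"
  if (!any(wt) || !any(mut))
    stop("both strains must be present", call. = FALSE)
  mean_wt <- colMeans(preds[wt, , drop = FALSE])
  mean_mut <- colMeans(preds[mut, , drop = FALSE])
  ok <- !is.na(mean_wt) & !is.na(mean_mut)
  if (any(ok & (mean_wt <= 0 | mean_mut <= 0)))
    stop("non-positive mean prediction; fold change undefined",
         call. = FALSE)
  fc <- rep(NA_real_, ncol(preds))
  names(fc) <- colnames(preds)
  fc[ok] <- log2(mean_mut[ok] / mean_wt[ok])
  fc
}

#' Pearson concordance between predicted and observed fold changes
#'
#' Standard product-moment correlation; undefined (returned as `NA` with a
#' warning) when either vector has zero variance or fewer than 3 pairs.
#'
#' @param pred_fc,obs_fc aligned numeric vectors.
#' @return scalar correlation, or `NA`.
#' @export
pearson_concordance <- function(pred_fc, obs_fc) {
  stopifnot(length(pred_fc) == length(obs_fc))
  ok <- !is.na(pred_fc) & !is.na(obs_fc)
  x <- pred_fc[ok]; y <- obs_fc[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Pearson r undefined (n < 3 or zero variance)", call. = FALSE)
    return(NA_real_)
  }
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

#' Direction-call table for predicted vs observed fold changes
#'
#' Each fold change is called `down` (<= -band), `up` (>= +band) or
#' `minimal` otherwise; the band defaults to the 0.58 log2 significance
#' threshold so one effect-size convention runs through the whole
#' pipeline. Agreement means identical calls from both sources.
#'
#' @param pred_fc,obs_fc aligned named numeric vectors.
#' @param minimal_band half-width of the minimal-change band (log2 units).
#' @return `ConcordanceResult`: data.frame of per-protein calls with
#'   `pearson_r` and `n_proteins` in attributes.
#' @export
direction_table <- function(pred_fc, obs_fc, minimal_band = 0.58) {
  stopifnot(length(pred_fc) == length(obs_fc))
  call_of <- function(fc) ifelse(fc <= -minimal_band, "down",
                          ifelse(fc >= minimal_band, "up", "minimal"))
  pred_call <- call_of(pred_fc)
  obs_call <- call_of(obs_fc)
  out <- data.frame(
    protein = if (!is.null(names(pred_fc))) names(pred_fc)
              else seq_along(pred_fc),
    predicted_log2fc = unname(pred_fc), observed_log2fc = unname(obs_fc),
    predicted_call = pred_call, observed_call = obs_call,
    agreement = pred_call == obs_call,
    stringsAsFactors = FALSE)
  attr(out, "pearson_r") <- suppressWarnings(
    pearson_concordance(pred_fc, obs_fc))
  attr(out, "n_proteins") <- length(pred_fc)
  attr(out, "minimal_band") <- minimal_band
  class(out) <- c("ConcordanceResult", "data.frame")
  out
}

#' Cross-phase summary of differential results
#'
#' Set algebra over the per-phase significant feature sets (shared core,
#' per-phase unique sets) and a heatmap-ready table of log2 fold changes
#' for the union, normalized per feature by its maximum absolute value so
#' every row spans \[-1, 1\].
#'
#' @param results named list of `DifferentialResult` objects, one per
#'   phase (>= 2 phases).
#' @return list: `significant` (per-phase sets), `shared` (intersection),
#'   `unique` (per-phase exclusive sets), `heatmap` (features x phases
#'   normalized log2FC data.frame).
#' @export
cross_phase_summary <- function(results) {
  if (length(results) < 2L) stop("need at least two phases", call. = FALSE)
  if (is.null(names(results)))
    names(results) <- paste0("phase", seq_along(results))
  sig <- lapply(results, function(r) r$feature_id[r$significant])
  shared <- Reduce(intersect, sig)
  uniq <- lapply(seq_along(sig), function(i)
    setdiff(sig[[i]], unique(unlist(sig[-i]))))
  names(uniq) <- names(results)
  union_feats <- sort(unique(unlist(sig)))
  hm <- sapply(results, function(r)
    r$log2fc[match(union_feats, r$feature_id)])
  hm <- matrix(hm, nrow = length(union_feats),
               dimnames = list(union_feats, names(results)))
  maxabs <- apply(abs(hm), 1L, max, na.rm = TRUE)
  maxabs[!is.finite(maxabs) | maxabs == 0] <- 1
  hm_norm <- hm / maxabs
  list(significant = sig, shared = shared, unique = uniq,
       heatmap = as.data.frame(hm_norm))
}
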