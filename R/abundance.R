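#' Abundance matrix container
#'
#' `AbundanceMatrix` is the common currency of every pipeline stage: a dense
#' features x samples grid of non-negative abundances (`NA` encodes a
#' missing/undetected cell) together with per-sample metadata, the omics
#' modality, and a record of the scale the values currently live on.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing cells.
#' @param samples data.frame with columns `sample_id`, `strain` (one of
#'   `"WT"`, `"MUT"`), `phase` (growth-phase label such as `"OD0.6"`) and
#'   `replicate` (positive integer). Row order defines column order.
#' @param modality `"metabolomics"` or `"proteomics"`.
#' @param scale one of `"raw"`, `"normalized"`, `"log2"`, `"scaled"`.
#' @param is_standard logical vector, one flag per feature, marking
#'   internal-standard rows that are excluded from all statistics.
#'
#' @return an object of class `AbundanceMatrix`.
#' @export
abundance_matrix <- function(values, samples, modality,
                             scale = "raw", is_standard = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs feature rownames and sample colnames", call. = FALSE)
  samples <- validate_sample_meta(samples)
  if (!identical(colnames(values), samples$sample_id))
    stop("column order of `values` must match `samples$sample_id`",
         call. = FALSE)
  modality <- match.arg(modality, c("metabolomics", "proteomics"))
  scale <- match.arg(scale, c("raw", "normalized", "log2", "scaled"))
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L], call. = FALSE)
  if (is.null(is_standard)) is_standard <- rep(FALSE, nrow(values))
  stopifnot(length(is_standard) == nrow(values))
  finite_ok <- is.na(values) | is.finite(values)
  if (!all(finite_ok))
    stop("non-finite abundance values present", call. = FALSE)
  if (scale %in% c("raw", "normalized") && any(values < 0, na.rm = TRUE))
    stop("negative abundance on the ", scale, " scale", call. = FALSE)
  structure(
    list(values = values, samples = samples, modality = modality,
         scale = scale, is_standard = is_standard),
    class = "AbundanceMatrix"
  )
}

validate_sample_meta <- function(samples) {
  req <- c("sample_id", "strain", "phase", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stop("sample metadata needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  samples <- as.data.frame(samples)[, req]
  samples$sample_id <- as.character(samples$sample_id)
  samples$strain <- as.character(samples$strain)
  samples$phase <- as.character(samples$phase)
  samples$replicate <- as.integer(samples$replicate)
  if (!all(samples$strain %in% c("WT", "MUT")))
    stop("strain must be 'WT' or 'MUT'", call. = FALSE)
  if (any(samples$replicate < 1L))
    stop("replicate indices must be positive", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  key <- paste(samples$strain, samples$phase, samples$replicate)
  if (anyDuplicated(key))
    stop("duplicate (strain, phase, replicate) triple in metadata",
         call. = FALSE)
  rownames(samples) <- NULL
  samples
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d features x %d samples [%s, scale=%s]\n",
              nrow(x$values), ncol(x$values), x$modality, x$scale))
  cat(sprintf("  strains: %s | phases: %s\n",
              paste(unique(x$samples$strain), collapse = "/"),
              paste(unique(x$samples$phase), collapse = ", ")))
  if (any(x$is_standard))
    cat("  internal standard rows:",
        paste(rownames(x$values)[x$is_standard], collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' Feature ids of an abundance matrix
#'
#' @param m an `AbundanceMatrix`.
#' @param include_standard keep internal-standard rows? Default drops them,
#'   so statistics never see the spiked standard.
#' @return character vector of feature ids.
#' @export
feature_ids <- function(m, include_standard = FALSE) {
  ids <- rownames(m$values)
  if (!include_standard) ids <- ids[!m$is_standard]
  ids
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read sample metadata
#'
#' Delimited table with columns `sample_id`, `strain`, `phase`, `replicate`.
#'
#' @param path file path (.tsv tab-delimited, .csv comma; `delim` overrides).
#' @param delim optional delimiter override.
#' @return validated data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path, delim = NULL) {
  df <- utils::read.delim(path, sep = infer_delim(path, delim),
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_meta(df)
}

#' Read a wide abundance table
#'
#' First column is the feature id; remaining columns are sample ids that must
#' all be present in the metadata table. Cells that are empty, `NA`, or any of
#' `missing_codes` are recorded as missing. By convention a literal `0` is
#' additionally treated as missing for proteomics LFQ data (the MaxQuant
#' convention) but kept as a value for metabolomics; override with
#' `zero_as_missing`.
#'
#' @param path abundance table path.
#' @param modality `"metabolomics"` or `"proteomics"`.
#' @param meta_path sample-metadata table path (or a data.frame).
#' @param zero_as_missing logical; default depends on modality (see above).
#' @param missing_codes character cell values treated as missing.
#' @param delim optional delimiter override for both files.
#' @return an `AbundanceMatrix` with `scale = "raw"`.
#' @export
read_abundance_table <- function(path, modality, meta_path,
                                 zero_as_missing = NULL,
                                 missing_codes = c("", "NA"),
                                 delim = NULL) {
  modality <- match.arg(modality, c("metabolomics", "proteomics"))
  meta <- if (is.data.frame(meta_path)) validate_sample_meta(meta_path)
          else read_sample_metadata(meta_path, delim)
  df <- utils::read.delim(path, sep = infer_delim(path, delim),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  fids <- df[[1L]]
  if (anyDuplicated(fids))
    stop("duplicate feature id: ", fids[duplicated(fids)][1L], call. = FALSE)
  sids <- colnames(df)[-1L]
  unknown <- setdiff(sids, meta$sample_id)
  if (length(unknown))
    stop("unknown sample ", unknown[1L], call. = FALSE)
  missing_samples <- setdiff(meta$sample_id, sids)
  if (length(missing_samples))
    stop("metadata sample absent from table: ", missing_samples[1L],
         call. = FALSE)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[raw %in% missing_codes] <- NA
  vals <- matrix(suppressWarnings(as.numeric(raw)), nrow = nrow(raw),
                 dimnames = list(fids, sids))
  if (any(!is.na(raw) & is.na(vals)))
    stop("non-numeric abundance cell encountered", call. = FALSE)
  if (is.null(zero_as_missing)) zero_as_missing <- modality == "proteomics"
  if (zero_as_missing) vals[!is.na(vals) & vals == 0] <- NA
  if (any(vals < 0, na.rm = TRUE))
    stop("negative abundance value in ", path, call. = FALSE)
  vals <- vals[, meta$sample_id, drop = FALSE]  # metadata defines order
  abundance_matrix(vals, meta, modality, scale = "raw")
}

#' Write an abundance matrix as a wide delimited table
#'
#' Inverse of [read_abundance_table()]: non-missing cells round-trip
#' bit-exactly (values are printed with full double precision).
#'
#' @param m an `AbundanceMatrix`.
#' @param path output path (.tsv or .csv; `delim` overrides).
#' @param delim optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(m, path, delim = NULL) {
  sep <- infer_delim(path, delim)
  vals <- m$values
  chr <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
  chr[is.na(vals)] <- "NA"
  df <- data.frame(feature_id = rownames(vals), chr, check.names = FALSE)
  colnames(df) <- c("feature_id", colnames(vals))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Internal-standard normalization
#'
#' Divides every abundance by the sample's internal-standard signal (the
#' spiked compound, e.g. L-methionine sulfone in targeted metabolomics),
#' making samples comparable on a per-injection basis. The standard's row
#' becomes all 1 and is flagged `is_standard` so downstream statistics skip
#' it; it is retained for provenance rather than deleted.
#'
#' @param m an `AbundanceMatrix` on the raw scale.
#' @param standard_id feature id of the internal-standard row.
#' @return normalized `AbundanceMatrix` (scale stays `"raw"`).
#' @export
normalize_internal_standard <- function(m, standard_id) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (!standard_id %in% rownames(m$values))
    stop("internal standard '", standard_id, "' not found", call. = FALSE)
  is_vals <- m$values[standard_id, ]
  bad <- is.na(is_vals) | is_vals <= 0
  if (any(bad))
    stop("internal standard zero in ", names(is_vals)[bad][1L], call. = FALSE)
  vals <- sweep(m$values, 2L, is_vals, "/")
  flags <- m$is_standard
  flags[match(standard_id, rownames(m$values))] <- TRUE
  abundance_matrix(vals, m$samples, m$modality, scale = m$scale,
                   is_standard = flags)
}

#' Wet-weight normalization
#'
#' Divides each sample column by that sample's cell-pellet wet weight (g),
#' converting abundances to a per-biomass basis. Canonical order in this
#' package is internal standard first, then wet weight. Note the orders are
#' not interchangeable: because the internal-standard divisor is itself a
#' row of the matrix, normalizing by it after wet-weight scaling cancels
#' the weights again; only the canonical order yields per-gram abundances.
#'
#' @param m an `AbundanceMatrix`.
#' @param weights named numeric vector of positive weights, one per sample
#'   (names = sample ids), or an unnamed vector in sample order.
#' @return normalized `AbundanceMatrix` with `scale = "normalized"`.
#' @export
normalize_wet_weight <- function(m, weights) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  sids <- m$samples$sample_id
  if (!is.null(names(weights))) {
    missing_w <- setdiff(sids, names(weights))
    if (length(missing_w))
      stop("missing wet weight for sample ", missing_w[1L], call. = FALSE)
    weights <- weights[sids]
  } else if (length(weights) != length(sids)) {
    stop("need one wet weight per sample", call. = FALSE)
  }
  if (any(!is.finite(weights) | weights <= 0))
    stop("non-positive wet weight for sample ",
         sids[!is.finite(weights) | weights <= 0][1L], call. = FALSE)
  vals <- sweep(m$values, 2L, weights, "/")
  abundance_matrix(vals, m$samples, m$modality, scale = "normalized",
                   is_standard = m$is_standard)
}

#' Import a MaxQuant proteinGroups table
#'
#' Reads the tab-delimited `proteinGroups.txt` produced by a MaxQuant search,
#' keeps the `LFQ intensity <sample>` columns matching the metadata, removes
#' reverse-database hits and potential contaminants, and converts LFQ zeros
#' to missing (MaxQuant reports 0 when a protein is not quantified).
#'
#' @param path proteinGroups-style file (tab-delimited).
#' @param meta_path sample-metadata path or data.frame.
#' @param id_column column holding protein ids (default `"Protein IDs"`).
#' @return a proteomics `AbundanceMatrix` with `scale = "raw"`.
#' @export
read_maxquant_protein_groups <- function(path, meta_path,
                                         id_column = "Protein IDs") {
  meta <- if (is.data.frame(meta_path)) validate_sample_meta(meta_path)
          else read_sample_metadata(meta_path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!id_column %in% names(df))
    stop("missing protein id column '", id_column, "'", call. = FALSE)
  lfq_cols <- paste("LFQ intensity", meta$sample_id)
  found <- lfq_cols %in% names(df)
  if (!any(found))
    stop("no LFQ intensity columns match the metadata sample ids",
         call. = FALSE)
  if (!all(found))
    stop("no LFQ intensity column for sample ",
         meta$sample_id[!found][1L], call. = FALSE)
  drop <- rep(FALSE, nrow(df))
  for (flag in c("Reverse", "Potential contaminant")) {
    if (flag %in% names(df)) drop <- drop | df[[flag]] %in% "+"
  }
  df <- df[!drop, , drop = FALSE]
  vals <- as.matrix(df[, lfq_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[vals == 0] <- NA
  dimnames(vals) <- list(df[[id_column]], meta$sample_id)
  abundance_matrix(vals, meta, "proteomics", scale = "raw")
}

#' Read pathway annotations
#'
#' Two-column delimited table `(feature_id, pathway)`; a feature may map to
#' several pathways. Duplicate pairs are collapsed.
#'
#' @param path annotation table path.
#' @param delim optional delimiter override.
#' @return data.frame of class `PathwayAnnotation` with columns
#'   `feature_id`, `pathway`.
#' @export
read_pathway_annotations <- function(path, delim = NULL) {
  df <- utils::read.delim(path, sep = infer_delim(path, delim),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  pathway_annotation(df[[1L]], df[[2L]])
}

#' Construct a pathway annotation set
#'
#' @param feature_id,pathway parallel character vectors.
#' @return deduplicated data.frame of class `PathwayAnnotation`.
#' @export
pathway_annotation <- function(feature_id, pathway) {
  stopifnot(length(feature_id) == length(pathway))
  feature_id <- as.character(feature_id)
  pathway <- as.character(pathway)
  if (any(is.na(pathway) | !nzchar(trimws(pathway))))
    stop("empty pathway label", call. = FALSE)
  df <- unique(data.frame(feature_id = feature_id, pathway = pathway,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("PathwayAnnotation", "data.frame")
  df
}

#' Subset an abundance matrix
#'
#' @param m an `AbundanceMatrix`.
#' @param features optional feature ids to keep (order preserved).
#' @param sample_ids optional sample ids to keep.
#' @return the subsetted `AbundanceMatrix`.
#' @export
subset_abundance <- function(m, features = NULL, sample_ids = NULL) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  vals <- m$values; flags <- m$is_standard; meta <- m$samples
  if (!is.null(features)) {
    idx <- match(features, rownames(vals))
    if (anyNA(idx))
      stop("unknown feature: ", features[is.na(idx)][1L], call. = FALSE)
    vals <- vals[idx, , drop = FALSE]; flags <- flags[idx]
  }
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, colnames(vals))
    if (anyNA(idx))
      stop("unknown sample: ", sample_ids[is.na(idx)][1L], call. = FALSE)
    vals <- vals[, idx, drop = FALSE]; meta <- meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
  }
  abundance_matrix(vals, meta, m$modality, scale = m$scale,
                   is_standard = flags)
}

#' Log2-transform an abundance matrix
#'
#' @param m an `AbundanceMatrix` on a raw/normalized scale.
#' @return the matrix on the log2 scale (missing cells stay missing).
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (m$scale == "log2") return(m)
  if (any(m$values <= 0, na.rm = TRUE))
    stop("non-positive values cannot be log2-transformed", call. = FALSE)
  out <- m
  out$values <- log2(m$values)
  out$scale <- "log2"
  out
}
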