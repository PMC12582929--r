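# Shared fixture builders. Everything is generated in code; no data files.

make_meta <- function(n_per = 2L, phase = "OD0.6") {
  data.frame(
    sample_id = paste0(rep(c("WT", "MUT"), each = n_per), "_", phase,
                       "_r", rep(seq_len(n_per), 2L)),
    strain = rep(c("WT", "MUT"), each = n_per),
    phase = phase,
    replicate = rep(seq_len(n_per), 2L),
    stringsAsFactors = FALSE
  )
}

make_am <- function(values, meta = NULL, modality = "metabolomics",
                    scale = "normalized") {
  if (is.null(meta)) meta <- make_meta(ncol(values) / 2L)
  colnames(values) <- meta$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  abundance_matrix(values, meta, modality, scale = scale)
}

# matrix with log2 group means fixed exactly (n replicates per strain)
am_from_log2 <- function(wt_rows, mut_rows, meta = NULL) {
  vals <- 2^cbind(wt_rows, mut_rows)
  make_am(vals, meta)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent textbook Student t-test (oracle; no shared code with the
# package implementation)
oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t_ <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(t_), n1 + n2 - 2)
}

# independent Storey q-value enumeration at fixed lambda
oracle_storey <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, max(mean(p > lambda) / (1 - lambda), 1 / m))
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) pi0 * m * p[ord][j] / j)
    q[ord[i]] <- min(vals, 1)
  }
  q
}

tiny_graph <- function() {
  # 3 metabolites, 3 proteins; P3 isolated (pathway no metabolite shares)
  ann <- pathway_annotation(
    c("M1", "M2", "M3", "P1", "P2", "P3"),
    c("Glycolysis", "Glycolysis", "PPP", "Glycolysis", "PPP", "TCA"))
  build_graph(ann, c("M1", "M2", "M3"), c("P1", "P2", "P3"))
}

# tiny supervised fixture built directly (bypasses file IO)
make_feature_table <- function(X, Y, modality = NULL, log2 = FALSE) {
  if (is.null(modality)) modality <- rep("proteomics", ncol(X))
  n <- nrow(X)
  structure(list(
    features = X, targets = Y, col_modality = modality,
    meta = data.frame(strain = rep(c("WT", "MUT"), length.out = n),
                      replicate = seq_len(n), stringsAsFactors = FALSE),
    dropped = list(), log2 = log2), class = "FeatureTable")
}
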