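make_sim_tables <- function(seed = 5, nm = 12, np = 6, ...) {
  cfg <- simulation_config(n_metabolites = nm, n_proteins = np,
                           n_pathways = 2, phases = c("OD0.6", "OD2.0"),
                           censor_rate = 0, seed = seed, ...)
  sim <- simulate_dataset(cfg)
  list(sim = sim,
       table = build_supervised_table(sim$metabolomics[[1L]],
                                      sim$metabolomics[[2L]],
                                      sim$proteomics[[1L]],
                                      sim$proteomics[[2L]]))
}

test_that("the supervised table aligns replicates and drops incomplete columns", {
  st <- make_sim_tables()
  tab <- st$table
  expect_equal(nrow(tab$features), 8L)  # 4 + 4 replicates
  expect_equal(ncol(tab$features), 12 * 2 + 6)
  expect_identical(tab$meta$strain, rep(c("WT", "MUT"), each = 4L))

  # a metabolite missing in one sample disappears from columns, is logged
  sim <- st$sim
  sim$metabolomics[[1L]]$values[3, 2] <- NA
  tab2 <- build_supervised_table(sim$metabolomics[[1L]],
                                 sim$metabolomics[[2L]],
                                 sim$proteomics[[1L]], sim$proteomics[[2L]])
  gone <- rownames(sim$metabolomics[[1L]]$values)[3]
  expect_false(paste0("met0_", gone) %in% colnames(tab2$features))
  expect_identical(tab2$dropped$metab_t0, gone)

  # mismatched replicate sets are an error
  short <- subset_abundance(sim$metabolomics[[1L]],
                            sample_ids = sim$metabolomics[[1L]]$samples$sample_id[-1])
  expect_error(build_supervised_table(short, sim$metabolomics[[2L]],
                                      sim$proteomics[[1L]],
                                      sim$proteomics[[2L]]),
               "unpairable replicate")
})

test_that("mean-baseline LOOCV matches its closed form on hand-built tables", {
  # 2 rows, targets (0, 2): single-row training folds have sd fallback 1,
  # so scaled and raw errors agree: predictions (2, 0), MSE 4
  t2 <- make_feature_table(matrix(stats::rnorm(4), 2), cbind(y = c(0, 2)))
  r2 <- run_loocv(t2, model_spec("mean"))
  expect_equal(unname(r2$predictions[, "y"]), c(2, 0))
  expect_equal(r2$mse, 4)

  # 4 rows: analytic LOOCV of the mean predictor under per-fold
  # standardization: e_i = (y_i - mean(y_-i)) / sd(y_-i)
  y <- c(1, 2, 4, 9)
  t4 <- make_feature_table(matrix(stats::rnorm(8), 4), cbind(y = y))
  r4 <- run_loocv(t4, model_spec("mean"))
  analytic <- mean(sapply(1:4, function(i)
    ((y[i] - mean(y[-i])) / stats::sd(y[-i]))^2))
  expect_equal(r4$mse, analytic, tolerance = 1e-12)
  expect_equal(unname(r4$predictions[, "y"]),
               sapply(1:4, function(i) mean(y[-i])), tolerance = 1e-12)
})

test_that("ridge interpolates an exactly linear noiseless table as lambda -> 0", {
  set.seed(11)
  X <- matrix(stats::rnorm(16), 8, 2)
  y <- drop(X %*% c(2, -1)) + 3
  tab <- make_feature_table(X, cbind(y = y))
  r <- run_loocv(tab, model_spec("ridge", lambda = 1e-10))
  expect_lt(r$mse, 1e-6)
})

test_that("deterministic families are invariant to row permutation", {
  st <- make_sim_tables(seed = 9)
  tab <- st$table
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  tabp <- tab
  tabp$features <- tab$features[perm, ]
  tabp$targets <- tab$targets[perm, , drop = FALSE]
  tabp$meta <- tab$meta[perm, ]
  for (fam in c("ridge", "lasso", "pls")) {
    a <- run_loocv(tab, model_spec(fam, seed = 1))
    b <- run_loocv(tabp, model_spec(fam, seed = 1))
    expect_equal(a$mse, b$mse, tolerance = 1e-9,
                 label = paste(fam, "mse under permutation"))
  }
})

test_that("tree families are reproducible under a fixed seed", {
  st <- make_sim_tables(seed = 4, nm = 8, np = 3)
  tab <- st$table
  tab$targets <- tab$targets[, 1:2]
  for (fam in c("rf", "gbt")) {
    spec <- if (fam == "rf") model_spec(fam, seed = 7, n_trees = 25L)
            else model_spec(fam, seed = 7, n_rounds = 40L)
    a <- run_loocv(tab, spec)
    b <- run_loocv(tab, spec)
    expect_identical(a$predictions, b$predictions, label = fam)
  }
})

test_that("fold scalers are computed from training rows only (no leakage)", {
  st <- make_sim_tables(seed = 6, nm = 6, np = 3)
  tab <- st$table
  # inject a leaky feature: equal to the first target (only harmful if
  # scaling used the full data)
  tab$features <- cbind(tab$features, leak = tab$targets[, 1L])
  tab$col_modality <- c(tab$col_modality, "proteomics")
  r <- run_loocv(tab, model_spec("ridge"))
  for (i in seq_len(nrow(tab$features))) {
    sc <- r$fold_scalers[[i]]$features
    j <- ncol(tab$features)
    expect_equal(sc$center[j], mean(tab$features[-i, j]), tolerance = 1e-12)
    expect_equal(sc$scale[j], stats::sd(tab$features[-i, j]),
                 tolerance = 1e-12)
  }
})

test_that("ridge LOOCV recovers a noiseless linear world", {
  st <- make_sim_tables(seed = 2, nm = 10, np = 5, noise_sd_log2 = 0,
                        protein_noise_sd_log2 = 0)
  r <- suppressWarnings(run_loocv(st$table, model_spec("ridge",
                                                       lambda = 1e-8)))
  fc <- predicted_fold_changes(r$predictions, st$table$meta)
  truth <- true_protein_log2fc(st$sim$truth)
  expect_gte(pearson_concordance(fc, truth[names(fc)]), 0.99)
})

test_that("model ranking orders by MSE with alphabetical tiebreak", {
  st <- make_sim_tables(seed = 3, nm = 6, np = 3)
  tab <- st$table
  res <- lapply(c("ridge", "mean"), function(f)
    run_loocv(tab, model_spec(f)))
  rk <- rank_models(res)
  best <- res[[which.min(sapply(res, `[[`, "mse"))]]$family
  expect_identical(rk$family[1L], best)
  expect_true(all(diff(rk$mse) >= 0))
  # tie -> alphabetical
  res2 <- res
  res2[[1L]]$mse <- res2[[2L]]$mse
  rk2 <- rank_models(res2)
  expect_identical(rk2$family, sort(c(res2[[1L]]$family, res2[[2L]]$family)))
  expect_error(rank_models(res[1L]), "at least two")
  other <- make_sim_tables(seed = 8, nm = 7, np = 3)$table
  res3 <- list(res[[1L]], run_loocv(other, model_spec("mean")))
  expect_error(rank_models(res3), "different tables")
})
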