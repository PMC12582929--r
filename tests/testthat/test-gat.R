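test_that("graph construction follows the shared-pathway rule", {
  g <- tiny_graph()
  edge_ids <- cbind(g$nodes$id[g$edges$i], g$nodes$id[g$edges$j])
  expect_true(any(edge_ids[, 1] == "M1" & edge_ids[, 2] == "P1"))
  expect_false(any(edge_ids[, 1] == "M3" & edge_ids[, 2] == "P1"))
  expect_identical(eligible_proteins(g), c("P1", "P2"))  # P3 isolated

  # two shared pathways -> one edge with both provenance labels
  ann2 <- pathway_annotation(c("M1", "M1", "P1", "P1"),
                             c("Glycolysis", "PPP", "Glycolysis", "PPP"))
  g2 <- build_graph(ann2, "M1", "P1")
  expect_equal(nrow(g2$edges), 1L)
  expect_identical(g2$edges$provenance, "Glycolysis;PPP")

  expect_error(build_graph(ann2, c("M1", "X"), c("X", "P1")),
               "both lists: X")
  g0 <- build_graph(pathway_annotation(c("M1", "P1"), c("A", "B")),
                    "M1", "P1")
  expect_length(eligible_proteins(g0), 0L)
})

test_that("attention is a proper softmax over the neighborhood", {
  g <- tiny_graph()
  set.seed(1)
  X <- matrix(stats::rnorm(nrow(g$nodes) * 3), ncol = 3)
  heads <- phaseomics:::gat_params(d_in = 3, hidden = 8, heads = 2,
                                   seed = 2)$params$layer1
  out <- gat_layer_forward(g, X, heads, combine = "concat")
  for (A in out$attention) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    expect_true(all(A[!g$mask] == 0))
  }
  # isolated-in-practice node (P3) attends only to itself: h = z
  i_p3 <- which(g$nodes$id == "P3")
  z <- X %*% heads[[1L]]$W
  expect_equal(out$H[i_p3, 1:4], z[i_p3, ], tolerance = 1e-10)
  # identical features everywhere -> uniform attention over neighborhoods
  Xc <- matrix(1, nrow(g$nodes), 3)
  outc <- gat_layer_forward(g, Xc, heads)
  A <- outc$attention[[1L]]
  for (i in seq_len(nrow(A))) {
    nb <- which(g$mask[i, ])
    expect_equal(unname(A[i, nb]), rep(1 / length(nb), length(nb)),
                 tolerance = 1e-10)
  }
})

test_that("the step-decay schedule matches the stated learning rates", {
  sched <- training_schedule()
  expect_equal(schedule_lr(sched, 1), 0.001)
  expect_equal(schedule_lr(sched, 100), 0.001)
  expect_equal(schedule_lr(sched, 101), 0.0005)
  expect_equal(schedule_lr(sched, 250), 0.00025)
  expect_equal(schedule_lr(sched, 300), 0.001 * 0.5^floor(299 / 100))
})

test_that("training and inference are deterministic under a fixed seed", {
  cfg <- simulation_config(n_metabolites = 8, n_proteins = 4, n_pathways = 2,
                           phases = c("OD0.6", "OD2.0"), censor_rate = 0,
                           seed = 3)
  sim <- simulate_dataset(cfg)
  tab <- build_supervised_table(sim$metabolomics[[1L]], sim$metabolomics[[2L]],
                                sim$proteomics[[1L]], sim$proteomics[[2L]])
  g <- build_graph(sim$truth$pathway_assignment, sim$truth$metabolite_ids,
                   sim$truth$protein_ids)
  sched <- training_schedule(epochs = 15L, seed = 42L)
  m1 <- train_gat(g, tab, sched, hidden = 16L)
  m2 <- train_gat(g, tab, sched, hidden = 16L)
  expect_identical(m1$loss_trajectory, m2$loss_trajectory)
  p1 <- predict_protein_abundance(m1, g, tab, 1:2)
  p2 <- predict_protein_abundance(m1, g, tab, 1:2)
  expect_identical(p1$abundance, p2$abundance)
  expect_error(predict_protein_abundance(m1, g, tab, 1,
                                         proteins = "no_such"),
               "not eligible")
})

test_that("the network is equivariant to node permutation", {
  g <- tiny_graph()
  gp <- phaseomics:::gat_params(d_in = 3, hidden = 8, heads = 2,
                                dropout = 0, seed = 5)
  set.seed(9)
  X <- matrix(stats::rnorm(nrow(g$nodes) * 3), ncol = 3)
  base <- phaseomics:::gat_forward_sample(gp, X, g$mask, training = TRUE)
  perm <- c(4, 1, 6, 2, 5, 3)
  yp <- phaseomics:::gat_forward_sample(gp, X[perm, ],
                                        g$mask[perm, perm],
                                        training = TRUE)
  expect_equal(yp$y, base$y[perm], tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  g <- tiny_graph()   # 6 nodes
  gp <- phaseomics:::gat_params(d_in = 3, hidden = 8, heads = 2,
                                dropout = 0, seed = 8)
  set.seed(14)
  X <- matrix(stats::rnorm(nrow(g$nodes) * 3), ncol = 3)
  elig_idx <- which(g$nodes$id %in% c("P1", "P2"))
  target <- c(0.7, -0.4)
  loss_of <- function(flat) {
    gp2 <- gp
    gp2$params <- phaseomics:::set_params(gp$params, flat)
    fw <- phaseomics:::gat_forward_sample(gp2, X, g$mask, training = TRUE)
    mean((fw$y[elig_idx] - target)^2)
  }
  flat <- phaseomics:::flatten_params(gp$params)
  fw <- phaseomics:::gat_forward_sample(gp, X, g$mask, training = TRUE)
  dy <- numeric(nrow(g$nodes))
  dy[elig_idx] <- 2 * (fw$y[elig_idx] - target) / length(elig_idx)
  analytic <- phaseomics:::flatten_params(
    phaseomics:::gat_backward_sample(gp, dy, fw$cache, g$mask))
  set.seed(99)
  idx <- sample(length(flat), max(25L, ceiling(0.05 * length(flat))))
  h <- 1e-5
  for (k in idx) {
    up <- flat; up[k] <- up[k] + h
    dn <- flat; dn[k] <- dn[k] - h
    num <- (loss_of(up) - loss_of(dn)) / (2 * h)
    denom <- max(abs(num), abs(analytic[k]), 1e-8)
    expect_lt(abs(num - analytic[k]) / denom, 1e-4)
  }
})

test_that("the GAT fits a zero-noise single-link world to near-zero loss", {
  cfg <- simulation_config(n_metabolites = 6, n_proteins = 3, n_pathways = 2,
                           phases = c("OD0.6", "OD2.0"), noise_sd_log2 = 0,
                           protein_noise_sd_log2 = 0, censor_rate = 0,
                           protein_link_density = 1, seed = 6)
  sim <- simulate_dataset(cfg)
  tab <- build_supervised_table(sim$metabolomics[[1L]], sim$metabolomics[[2L]],
                                sim$proteomics[[1L]], sim$proteomics[[2L]])
  g <- build_graph(sim$truth$pathway_assignment, sim$truth$metabolite_ids,
                   sim$truth$protein_ids)
  m <- train_gat(g, tab, training_schedule(epochs = 300L, seed = 1L),
                 hidden = 16L, dropout = 0)
  n_elig <- length(m$eligible)
  # final summed loss relative to per-protein unit target variance
  expect_lt(tail(m$loss_trajectory, 1) / nrow(tab$features), 1e-2 * n_elig)
})
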