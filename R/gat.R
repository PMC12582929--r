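#' Build the metabolite-protein pathway graph
#'
#' Bipartite operationalization of "topological linkage": an undirected
#' edge joins metabolite m and protein p iff they share at least one
#' pathway label. Node order is deterministic (metabolites then proteins,
#' each lexicographic). Self-loops are added at attention time, never
#' stored. Optional metabolite-metabolite edges within a pathway sit
#' behind a flag and default off.
#'
#' @param ann a `PathwayAnnotation` covering both id sets.
#' @param metabolite_ids,protein_ids disjoint, non-empty id vectors.
#' @param met_met_edges also connect metabolites sharing a pathway.
#' @return an `OmicsGraph`: `nodes` (data.frame id/kind), `edges`
#'   (data.frame i/j/provenance), `mask` (N x N logical adjacency with
#'   self-loops), `degree` (without self-loops).
#' @export
build_graph <- function(ann, metabolite_ids, protein_ids,
                        met_met_edges = FALSE) {
  if (!length(metabolite_ids) || !length(protein_ids))
    stop("id lists must be non-empty", call. = FALSE)
  both <- intersect(metabolite_ids, protein_ids)
  if (length(both))
    stop("id present in both lists: ", both[1L], call. = FALSE)
  mets <- sort(unique(metabolite_ids))
  prots <- sort(unique(protein_ids))
  nodes <- data.frame(
    id = c(mets, prots),
    kind = rep(c("metabolite", "protein"), c(length(mets), length(prots))),
    stringsAsFactors = FALSE)
  n <- nrow(nodes)
  pw_of <- function(id) ann$pathway[ann$feature_id == id]
  mask <- diag(n) > 0
  edges <- list()
  add_edge <- function(i, j, prov) {
    key <- paste(min(i, j), max(i, j))
    if (is.null(edges[[key]]))
      edges[[key]] <<- list(i = min(i, j), j = max(i, j), prov = prov)
    else
      edges[[key]]$prov <<- union(edges[[key]]$prov, prov)
    mask[i, j] <<- TRUE; mask[j, i] <<- TRUE
  }
  met_pw <- lapply(mets, pw_of)
  prot_pw <- lapply(prots, pw_of)
  for (a in seq_along(mets)) {
    for (b in seq_along(prots)) {
      shared <- intersect(met_pw[[a]], prot_pw[[b]])
      if (length(shared)) add_edge(a, length(mets) + b, shared)
    }
  }
  if (met_met_edges && length(mets) > 1L) {
    for (a in seq_len(length(mets) - 1L)) {
      for (b in (a + 1L):length(mets)) {
        shared <- intersect(met_pw[[a]], met_pw[[b]])
        if (length(shared)) add_edge(a, b, shared)
      }
    }
  }
  edf <- if (length(edges)) {
    data.frame(i = vapply(edges, `[[`, numeric(1), "i"),
               j = vapply(edges, `[[`, numeric(1), "j"),
               provenance = vapply(edges, function(e)
                 paste(sort(e$prov), collapse = ";"), character(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(i = numeric(0), j = numeric(0),
               provenance = character(0), stringsAsFactors = FALSE)
  }
  degree <- rowSums(mask) - 1L
  structure(list(nodes = nodes, edges = edf, mask = mask, degree = degree),
            class = "OmicsGraph")
}

#' @export
print.OmicsGraph <- function(x, ...) {
  cat(sprintf("OmicsGraph: %d metabolites + %d proteins, %d edges\n",
              sum(x$nodes$kind == "metabolite"),
              sum(x$nodes$kind == "protein"), nrow(x$edges)))
  invisible(x)
}

#' Proteins eligible for prediction
#'
#' Only proteins connected to at least one metabolite can receive signal
#' through the graph, so predictions are restricted to proteins of
#' degree >= 1; isolated proteins are excluded from training targets and
#' predictions.
#'
#' @param g an `OmicsGraph`.
#' @return character vector of eligible protein ids.
#' @export
eligible_proteins <- function(g) {
  stopifnot(inherits(g, "OmicsGraph"))
  g$nodes$id[g$nodes$kind == "protein" & g$degree >= 1L]
}

# ---- GAT internals (pure matrix arithmetic, hand-written backward) -------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' GAT parameter initialization
#'
#' Two attention layers (4 heads each; layer 1 concatenates heads into the
#' 128-dim hidden state = 4 x 32, layer 2 averages heads into 32) with
#' batch normalization and an affine output head. Glorot-uniform
#' initialization from the seeded RNG stream.
#'
#' @param d_in input feature width per node (default 3: two abundance
#'   channels + kind indicator).
#' @param hidden total hidden width (must be divisible by `heads`).
#' @param heads attention heads per layer.
#' @param dropout dropout rate applied to node features after each layer's
#'   activation.
#' @param slope LeakyReLU negative slope inside the attention (the
#'   canonical 0.2).
#' @param seed integer seed.
#' @return a `GATParams` list.
#' @export
gat_params <- function(d_in = 3L, hidden = 128L, heads = 4L,
                       dropout = 0.3, slope = 0.2, seed = 1L) {
  if (hidden %% heads != 0L)
    stop("hidden width must be divisible by the head count", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0,1)",
                                        call. = FALSE)
  dh <- hidden %/% heads
  restore <- local_seed(seed)
  on.exit(restore())
  mk_head <- function(din, dout) list(W = glorot(din, dout),
                                      a_src = stats::runif(dout, -0.1, 0.1),
                                      a_dst = stats::runif(dout, -0.1, 0.1))
  p <- list(
    layer1 = lapply(seq_len(heads), function(h) mk_head(d_in, dh)),
    bn1 = list(gamma = rep(1, hidden), beta = rep(0, hidden)),
    layer2 = lapply(seq_len(heads), function(h) mk_head(hidden, dh)),
    bn2 = list(gamma = rep(1, dh), beta = rep(0, dh)),
    out = list(w = stats::runif(dh, -0.1, 0.1), b = 0)
  )
  structure(list(params = p, d_in = d_in, hidden = hidden, heads = heads,
                 per_head = dh, dropout = dropout, slope = slope,
                 seed = seed),
            class = "GATParams")
}

flatten_params <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, flatten_params), use.names = FALSE))
  as.numeric(p)
}

set_params <- function(skel, vec) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  out <- walk(skel)
  stopifnot(pos == length(vec))
  out
}

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  out <- p; out[] <- 0; out
}

attn_head_forward <- function(X, head, mask, slope) {
  Z <- X %*% head$W
  s <- drop(Z %*% head$a_src)
  t_ <- drop(Z %*% head$a_dst)
  n <- nrow(X)
  Epre <- outer(s, rep(1, n)) + outer(rep(1, n), t_)
  E <- ifelse(Epre > 0, Epre, slope * Epre)
  E[!mask] <- -Inf
  E <- E - apply(E, 1L, max)          # row-stable softmax
  A <- exp(E)
  A <- A / rowSums(A)
  list(H = A %*% Z, Z = Z, A = A, Epre = Epre)
}

attn_head_backward <- function(dH, cache, X, head, mask, slope) {
  Z <- cache$Z; A <- cache$A
  dA <- dH %*% t(Z)
  dZ <- t(A) %*% dH
  dE <- A * (dA - rowSums(A * dA))
  dEpre <- dE * ifelse(cache$Epre > 0, 1, slope)
  dEpre[!mask] <- 0
  ds <- rowSums(dEpre)
  dt <- colSums(dEpre)
  dZ <- dZ + outer(ds, head$a_src) + outer(dt, head$a_dst)
  list(dW = crossprod(X, dZ),
       da_src = drop(crossprod(Z, ds)),
       da_dst = drop(crossprod(Z, dt)),
       dX = dZ %*% t(head$W))
}

bn_forward <- function(X, gamma, beta, training, running, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2L, mu)^2)
  } else {
    mu <- running$mean; v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, invstd, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = Y, xhat = xhat, invstd = invstd, mu = mu, var = v)
}

bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dX <- sweep(t1 - t2, 2L, cache$invstd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x, y) ifelse(x > 0, 1, y + 1)

gat_forward_sample <- function(gp, X, mask, training = FALSE,
                               running = NULL, drop_masks = NULL) {
  p <- gp$params; slope <- gp$slope
  h1 <- lapply(p$layer1, function(h)
    attn_head_forward(X, h, mask, slope))
  H1 <- do.call(cbind, lapply(h1, `[[`, "H"))
  bn1 <- bn_forward(H1, p$bn1$gamma, p$bn1$beta, training, running$bn1)
  A1 <- elu(bn1$Y)
  D1 <- if (training && !is.null(drop_masks)) A1 * drop_masks$d1 else A1
  h2 <- lapply(p$layer2, function(h)
    attn_head_forward(D1, h, mask, slope))
  H2 <- Reduce(`+`, lapply(h2, `[[`, "H")) / gp$heads
  bn2 <- bn_forward(H2, p$bn2$gamma, p$bn2$beta, training, running$bn2)
  A2 <- elu(bn2$Y)
  D2 <- if (training && !is.null(drop_masks)) A2 * drop_masks$d2 else A2
  y <- drop(D2 %*% p$out$w) + p$out$b
  cache <- list(X = X, h1 = h1, H1 = H1, bn1 = bn1, A1 = A1, D1 = D1,
                h2 = h2, H2 = H2, bn2 = bn2, A2 = A2, D2 = D2,
                drop_masks = drop_masks)
  list(y = y, cache = cache,
       batch_stats = list(bn1 = list(mean = bn1$mu, var = bn1$var),
                          bn2 = list(mean = bn2$mu, var = bn2$var)))
}

gat_backward_sample <- function(gp, dy, cache, mask) {
  p <- gp$params; slope <- gp$slope
  g <- zeros_like(p)
  g$out$w <- drop(crossprod(cache$D2, dy))
  g$out$b <- sum(dy)
  dD2 <- outer(dy, p$out$w)
  dA2 <- if (!is.null(cache$drop_masks)) dD2 * cache$drop_masks$d2 else dD2
  dbn2y <- dA2 * elu_grad(cache$bn2$Y, cache$A2)
  b2 <- bn_backward(dbn2y, cache$bn2, p$bn2$gamma)
  g$bn2$gamma <- b2$dgamma; g$bn2$beta <- b2$dbeta
  dH2 <- b2$dX / gp$heads
  dD1 <- 0
  for (h in seq_len(gp$heads)) {
    bh <- attn_head_backward(dH2, cache$h2[[h]], cache$D1,
                             p$layer2[[h]], mask, slope)
    g$layer2[[h]]$W <- bh$dW
    g$layer2[[h]]$a_src <- bh$da_src
    g$layer2[[h]]$a_dst <- bh$da_dst
    dD1 <- dD1 + bh$dX
  }
  dA1 <- if (!is.null(cache$drop_masks)) dD1 * cache$drop_masks$d1 else dD1
  dbn1y <- dA1 * elu_grad(cache$bn1$Y, cache$A1)
  b1 <- bn_backward(dbn1y, cache$bn1, p$bn1$gamma)
  g$bn1$gamma <- b1$dgamma; g$bn1$beta <- b1$dbeta
  dh <- gp$per_head
  for (h in seq_len(gp$heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    bh <- attn_head_backward(b1$dX[, cols, drop = FALSE], cache$h1[[h]],
                             cache$X, p$layer1[[h]], mask, slope)
    g$layer1[[h]]$W <- bh$dW
    g$layer1[[h]]$a_src <- bh$da_src
    g$layer1[[h]]$a_dst <- bh$da_dst
  }
  g
}

#' Single GAT layer forward pass
#'
#' One multi-head attention layer on explicit inputs, exposed for
#' inspection and testing of the attention mechanics: per head,
#' `z_i = W x_i`, attention logits
#' `e_ij = LeakyReLU(a . [z_i || z_j])` over `N(i)` plus a self-loop,
#' row-softmax weights, and the attention-weighted sum. Heads are
#' concatenated (`combine = "concat"`, the hidden-layer convention) or
#' averaged (`combine = "mean"`, the output-layer convention).
#'
#' @param g an `OmicsGraph`.
#' @param X node feature matrix (nodes x d_in).
#' @param heads list of head parameter lists (`W`, `a_src`, `a_dst`).
#' @param combine `"concat"` or `"mean"`.
#' @param slope LeakyReLU negative slope.
#' @return list: `H` (combined output), `attention` (list of per-head
#'   row-stochastic N x N matrices).
#' @export
gat_layer_forward <- function(g, X, heads, combine = c("concat", "mean"),
                              slope = 0.2) {
  stopifnot(inherits(g, "OmicsGraph"), nrow(X) == nrow(g$nodes))
  combine <- match.arg(combine)
  outs <- lapply(heads, function(h)
    attn_head_forward(X, h, g$mask, slope))
  H <- if (combine == "concat") do.call(cbind, lapply(outs, `[[`, "H"))
       else Reduce(`+`, lapply(outs, `[[`, "H")) / length(outs)
  if (any(!is.finite(H)))
    stop("non-finite activations in GAT layer", call. = FALSE)
  list(H = H, attention = lapply(outs, `[[`, "A"))
}

#' Training schedule for the GAT
#'
#' Adam at learning rate 0.001, halved every 100 epochs (step decay),
#' squared-error loss on eligible protein nodes, 300 epochs, full-batch.
#'
#' @param learning_rate,step_size,gamma,epochs,seed schedule fields.
#' @return a `TrainingSchedule` list.
#' @export
training_schedule <- function(learning_rate = 0.001, step_size = 100L,
                              gamma = 0.5, epochs = 300L, seed = 1L) {
  stopifnot(epochs > 0, gamma > 0, gamma < 1, learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 step_size = as.integer(step_size), gamma = gamma,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "TrainingSchedule")
}

#' Learning rate at a given epoch under step decay
#'
#' @param sched a [training_schedule()].
#' @param epoch 1-based epoch index.
#' @return the learning rate in force during that epoch.
#' @export
schedule_lr <- function(sched, epoch) {
  sched$learning_rate * sched$gamma^((epoch - 1L) %/% sched$step_size)
}

# node feature layout: metabolites carry their two scaled abundance
# channels (phase t0, t1); proteins carry scaled t0 abundance and a kind
# indicator. Channels a node does not use are zero-padded.
build_node_features <- function(g, met0, met1, prot0) {
  n <- nrow(g$nodes)
  X <- matrix(0, n, 3L)
  is_met <- g$nodes$kind == "metabolite"
  ids <- g$nodes$id
  X[is_met, 1L] <- met0[ids[is_met]]
  X[is_met, 2L] <- met1[ids[is_met]]
  X[!is_met, 1L] <- prot0[ids[!is_met]]
  X[!is_met, 3L] <- 1
  if (anyNA(X)) stop("node feature missing for some graph node",
                     call. = FALSE)
  X
}

table_node_inputs <- function(g, table, rows, scalers) {
  ids <- colnames(table$features)
  lapply(rows, function(r) {
    x <- (table$features[r, ] - scalers$features$center) /
      scalers$features$scale
    names(x) <- ids
    met0 <- x[startsWith(ids, "met0_")]
    names(met0) <- sub("^met0_", "", names(met0))
    met1 <- x[startsWith(ids, "met1_")]
    names(met1) <- sub("^met1_", "", names(met1))
    prot0 <- x[startsWith(ids, "prot0_")]
    names(prot0) <- sub("^prot0_", "", names(prot0))
    build_node_features(g, met0, met1, prot0)
  })
}

fit_scalers <- function(table, rows) {
  X <- table$features[rows, , drop = FALSE]
  Y <- table$targets[rows, , drop = FALSE]
  sx <- scale_fold(X, X, table$col_modality)
  sy <- scale_fold(Y, Y, rep("proteomics", ncol(Y)))
  list(features = list(center = sx$center, scale = sx$scale),
       targets = list(center = sy$center, scale = sy$scale))
}

#' Train the pathway-graph attention network
#'
#' Full-batch training of the two-layer GAT on a cross-phase supervised
#' table: per training sample the graph carries that sample's scaled node
#' features, the output head is read at the eligible protein nodes, and
#' the squared-error loss against the scaled later-phase protein abundance
#' is summed over samples. Adam with step-decayed learning rate;
#' deterministic under a fixed schedule seed (initialization and dropout
#' draws come from one documented stream). Scaling statistics are fit on
#' the training rows only and stored in the model for inference.
#'
#' @param g an `OmicsGraph` whose node ids match the table's feature ids.
#' @param table a [build_supervised_table()] result.
#' @param sched a [training_schedule()].
#' @param rows training row indices (default: all rows).
#' @param hidden,heads,dropout architecture knobs (defaults 128/4/0.3).
#' @return a `TrainedGAT`: `gp` (parameters), `running` (batch-norm
#'   inference statistics), `loss_trajectory`, `eligible`, `scalers`,
#'   `sched`.
#' @export
train_gat <- function(g, table, sched = training_schedule(), rows = NULL,
                      hidden = 128L, heads = 4L, dropout = 0.3) {
  stopifnot(inherits(g, "OmicsGraph"), inherits(table, "FeatureTable"))
  if (is.null(rows)) rows <- seq_len(nrow(table$features))
  if (length(rows) < 3L) stop("need at least 3 training samples",
                              call. = FALSE)
  elig <- intersect(eligible_proteins(g), colnames(table$targets))
  if (!length(elig)) stop("no eligible proteins with targets", call. = FALSE)
  scalers <- fit_scalers(table, rows)
  Xs <- table_node_inputs(g, table, rows, scalers)
  Yt <- sweep(sweep(table$targets[rows, elig, drop = FALSE], 2L,
                    scalers$targets$center[match(elig, colnames(table$targets))]),
              2L, scalers$targets$scale[match(elig, colnames(table$targets))],
              "/")
  elig_idx <- match(elig, g$nodes$id)
  n_nodes <- nrow(g$nodes)

  gp <- gat_params(d_in = 3L, hidden = hidden, heads = heads,
                   dropout = dropout, seed = sched$seed)
  restore <- local_seed(sched$seed + 7L)   # dropout stream
  on.exit(restore())

  flat <- flatten_params(gp$params)
  m_adam <- v_adam <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  running <- list(bn1 = list(mean = rep(0, hidden), var = rep(1, hidden)),
                  bn2 = list(mean = rep(0, gp$per_head),
                             var = rep(1, gp$per_head)))
  momentum <- 0.1
  loss_traj <- numeric(sched$epochs)
  step <- 0L
  for (epoch in seq_len(sched$epochs)) {
    lr <- schedule_lr(sched, epoch)
    grad_flat <- numeric(length(flat))
    loss <- 0
    for (s in seq_along(rows)) {
      dmask <- if (gp$dropout > 0) {
        keep <- 1 - gp$dropout
        list(d1 = matrix(stats::rbinom(n_nodes * hidden, 1L, keep) / keep,
                         n_nodes, hidden),
             d2 = matrix(stats::rbinom(n_nodes * gp$per_head, 1L, keep) / keep,
                         n_nodes, gp$per_head))
      } else NULL
      fw <- gat_forward_sample(gp, Xs[[s]], g$mask, training = TRUE,
                               drop_masks = dmask)
      for (bn in c("bn1", "bn2")) {
        running[[bn]]$mean <- (1 - momentum) * running[[bn]]$mean +
          momentum * fw$batch_stats[[bn]]$mean
        running[[bn]]$var <- (1 - momentum) * running[[bn]]$var +
          momentum * fw$batch_stats[[bn]]$var
      }
      resid <- fw$y[elig_idx] - Yt[s, ]
      loss <- loss + mean(resid^2)
      dy <- numeric(n_nodes)
      dy[elig_idx] <- 2 * resid / length(elig_idx)
      gsamp <- gat_backward_sample(gp, dy, fw$cache, g$mask)
      grad_flat <- grad_flat + flatten_params(gsamp)
    }
    if (!is.finite(loss))
      stop("training diverged; last finite epoch ", epoch - 1L,
           call. = FALSE)
    loss_traj[epoch] <- loss
    step <- step + 1L
    m_adam <- b1 * m_adam + (1 - b1) * grad_flat
    v_adam <- b2 * v_adam + (1 - b2) * grad_flat^2
    mhat <- m_adam / (1 - b1^step)
    vhat <- v_adam / (1 - b2^step)
    flat <- flat - lr * mhat / (sqrt(vhat) + eps)
    gp$params <- set_params(gp$params, flat)
  }
  structure(list(gp = gp, running = running, loss_trajectory = loss_traj,
                 eligible = elig, eligible_idx = elig_idx,
                 scalers = scalers, sched = sched,
                 target_names = colnames(table$targets),
                 log2 = isTRUE(table$log2)),
            class = "TrainedGAT")
}

#' Predict protein abundance with a trained GAT
#'
#' Inference mode: dropout off, batch normalization uses the running
#' statistics accumulated during training. Returns predictions for the
#' eligible proteins only, on the standardized target scale and
#' inverse-transformed back to the abundance scale.
#'
#' @param model a `TrainedGAT`.
#' @param g the `OmicsGraph` used in training.
#' @param table the `FeatureTable` supplying input rows.
#' @param rows row indices to predict.
#' @param proteins protein ids to report (default: all eligible proteins;
#'   requesting an ineligible protein is an error).
#' @return list: `scaled` and `abundance`, each rows x protein matrices.
#' @export
predict_protein_abundance <- function(model, g, table, rows,
                                      proteins = NULL) {
  stopifnot(inherits(model, "TrainedGAT"))
  if (!is.null(proteins)) {
    bad <- setdiff(proteins, model$eligible)
    if (length(bad))
      stop("protein not eligible: ", bad[1L], call. = FALSE)
  }
  Xs <- table_node_inputs(g, table, rows, model$scalers)
  preds <- t(vapply(Xs, function(X) {
    fw <- gat_forward_sample(model$gp, X, g$mask, training = FALSE,
                             running = model$running)
    fw$y[model$eligible_idx]
  }, numeric(length(model$eligible))))
  colnames(preds) <- model$eligible
  rownames(preds) <- rownames(table$features)[rows]
  ti <- match(model$eligible, model$target_names)
  ab <- sweep(sweep(preds, 2L, model$scalers$targets$scale[ti], "*"),
              2L, model$scalers$targets$center[ti], "+")
  if (isTRUE(model$log2)) ab <- 2^ab
  if (!is.null(proteins)) {
    preds <- preds[, proteins, drop = FALSE]
    ab <- ab[, proteins, drop = FALSE]
  }
  list(scaled = preds, abundance = ab)
}

#' Leave-one-out cross-validation of the GAT
#'
#' Retrains the network once per held-out sample (scalers refit inside
#' each fold) and collects abundance-scale held-out predictions for the
#' eligible proteins.
#'
#' @param g an `OmicsGraph`.
#' @param table a [build_supervised_table()] result.
#' @param sched a [training_schedule()]; fold f trains with seed
#'   `sched$seed + f` so folds are independent but reproducible.
#' @param ... architecture knobs passed to [train_gat()].
#' @return a `CVResult`-like list: `predictions` (abundance scale),
#'   `mse` (scaled), `eligible`.
#' @export
gat_loocv <- function(g, table, sched = training_schedule(), ...) {
  n <- nrow(table$features)
  elig <- intersect(eligible_proteins(g), colnames(table$targets))
  pred <- matrix(NA_real_, n, length(elig),
                 dimnames = list(rownames(table$features), elig))
  sq <- 0; cnt <- 0L
  for (i in seq_len(n)) {
    fsched <- sched; fsched$seed <- sched$seed + i
    model <- train_gat(g, table, fsched, rows = setdiff(seq_len(n), i), ...)
    out <- predict_protein_abundance(model, g, table, i)
    pred[i, ] <- out$abundance[1L, elig]
    ti <- match(elig, colnames(table$targets))
    obs_scaled <- (table$targets[i, elig] -
                     model$scalers$targets$center[ti]) /
      model$scalers$targets$scale[ti]
    sq <- sq + sum((out$scaled[1L, elig] - obs_scaled)^2)
    cnt <- cnt + length(elig)
  }
  structure(list(family = "gat", predictions = pred, mse = sq / cnt,
                 eligible = elig,
                 table_signature = table_signature(table)),
            class = "CVResult")
}
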