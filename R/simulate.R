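# Seeded generator of two-strain multi-omics datasets with planted ground
# truth. All effects and noise live on the log2 scale so planted fold
# changes are exact; abundances are 2^log2 (log-normal).

local_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    restore <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    restore <- function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }
  }
  set.seed(seed)
  restore
}

#' Simulation configuration
#'
#' Stated world of the generator: a two-strain (WT vs MUT) design with four
#' biological replicates per strain per growth phase, log-normal abundances,
#' a planted subset of metabolites with a strain effect of fixed |log2 fold
#' change|, detection censoring (affected metabolites rendered undetectable
#' in the strain where they are lower), and proteins generated as noisy
#' weighted combinations of pathway-linked metabolites so that all strain
#' signal reaches the proteome through the metabolome.
#'
#' @param n_metabolites,n_proteins,n_pathways panel sizes.
#' @param replicates_per_group biological replicates per strain per phase
#'   (default 4, the usual design at this scale).
#' @param phases growth-phase labels (optical-density checkpoints).
#' @param frac_affected fraction of metabolites with a strain effect.
#' @param effect_log2fc planted |log2FC| of affected metabolites (1.0 is a
#'   2-fold strain effect, comfortably above the 0.58 significance gate).
#' @param noise_sd_log2 replicate noise sd on the log2 scale.
#' @param phase_sd_log2 sd of per-feature phase shifts (shared across
#'   strains); the default 2.0 makes growth phase the dominant source of
#'   global variance, as in real growth-course metabolomics.
#' @param protein_link_density expected metabolite links per protein.
#' @param within_pathway_prob probability a protein link stays inside its
#'   home pathway (0.9 leaves some model misspecification).
#' @param protein_noise_sd_log2 protein-level noise sd (log2).
#' @param censor_rate fraction of affected metabolites made undetectable in
#'   the strain where they are lower.
#' @param baseline_mean_log2,baseline_sd_log2 log2 baseline abundance
#'   distribution (defaults give raw abundances around 2^10).
#' @param seed integer seed; every draw flows from it in documented order.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_metabolites = 80, n_proteins = 40,
                              n_pathways = 6, replicates_per_group = 4,
                              phases = c("OD0.6", "OD2.0", "OD4.0"),
                              frac_affected = 0.3, effect_log2fc = 1.0,
                              noise_sd_log2 = 0.3, phase_sd_log2 = 2.0,
                              protein_link_density = 3,
                              within_pathway_prob = 0.9,
                              protein_noise_sd_log2 = 0.2,
                              censor_rate = 0.05,
                              baseline_mean_log2 = 10,
                              baseline_sd_log2 = 1.5,
                              seed = 1L) {
  cfg <- list(n_metabolites = as.integer(n_metabolites),
              n_proteins = as.integer(n_proteins),
              n_pathways = as.integer(n_pathways),
              replicates_per_group = as.integer(replicates_per_group),
              phases = as.character(phases),
              frac_affected = frac_affected,
              effect_log2fc = effect_log2fc,
              noise_sd_log2 = noise_sd_log2,
              phase_sd_log2 = phase_sd_log2,
              protein_link_density = protein_link_density,
              within_pathway_prob = within_pathway_prob,
              protein_noise_sd_log2 = protein_noise_sd_log2,
              censor_rate = censor_rate,
              baseline_mean_log2 = baseline_mean_log2,
              baseline_sd_log2 = baseline_sd_log2,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_metabolites > 0, n_proteins > 0, n_pathways > 0,
              replicates_per_group > 0, length(phases) >= 1,
              frac_affected >= 0, frac_affected <= 1,
              censor_rate >= 0, censor_rate <= 1,
              within_pathway_prob >= 0, within_pathway_prob <= 1,
              noise_sd_log2 >= 0, phase_sd_log2 >= 0,
              protein_noise_sd_log2 >= 0, protein_link_density > 0)
  })
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Draw the planted ground truth
#'
#' Deterministic given `cfg$seed`. Metabolites are assigned to pathways
#' round-robin; exactly `round(frac_affected * n_metabolites)` metabolites
#' receive a strain effect of `±effect_log2fc` (sign drawn at random,
#' constant across phases); each protein gets a home pathway and
#' `max(1, Poisson(link_density))` metabolite links, drawn within the home
#' pathway with probability `within_pathway_prob`; link weights are positive
#' and normalized to sum to 1 (a single-link protein therefore copies its
#' metabolite exactly at zero noise). A `censor_rate` fraction of affected
#' metabolites is marked undetectable in the strain where the effect makes
#' them lower.
#'
#' @param cfg a [simulation_config()].
#' @return a `SyntheticTruth` list: `affected_log2fc` (named vector, MUT vs
#'   WT), `effects_by_phase` (affected x phase matrix), `pathway_assignment`
#'   (`PathwayAnnotation` covering metabolites and proteins),
#'   `protein_links` (named list of weight vectors over metabolite ids),
#'   `censored_features` (named character: feature -> strain censored in),
#'   plus the id vectors.
#' @export
make_truth <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  restore <- local_seed(cfg$seed)
  on.exit(restore())

  met_ids <- sprintf("M%03d", seq_len(cfg$n_metabolites))
  prot_ids <- sprintf("P%03d", seq_len(cfg$n_proteins))
  pathways <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  met_pw <- pathways[((seq_len(cfg$n_metabolites) - 1L) %% cfg$n_pathways) + 1L]
  prot_pw <- pathways[((seq_len(cfg$n_proteins) - 1L) %% cfg$n_pathways) + 1L]

  # draw 1: affected set and signs
  n_aff <- round(cfg$frac_affected * cfg$n_metabolites)
  affected <- if (n_aff > 0) sort(sample(met_ids, n_aff)) else character(0)
  signs <- if (n_aff > 0) sample(c(-1, 1), n_aff, replace = TRUE) else numeric(0)
  affected_log2fc <- stats::setNames(signs * cfg$effect_log2fc, affected)
  effects_by_phase <- matrix(rep(affected_log2fc, length(cfg$phases)),
                             nrow = n_aff, ncol = length(cfg$phases),
                             dimnames = list(affected, cfg$phases))

  # draw 2: per-protein link counts, partners, weights
  protein_links <- vector("list", cfg$n_proteins)
  names(protein_links) <- prot_ids
  for (i in seq_len(cfg$n_proteins)) {
    k <- max(1L, stats::rpois(1L, cfg$protein_link_density))
    home <- met_ids[met_pw == prot_pw[i]]
    away <- met_ids[met_pw != prot_pw[i]]
    pick <- character(0)
    for (j in seq_len(k)) {
      use_home <- stats::runif(1) < cfg$within_pathway_prob
      pool <- if (use_home) setdiff(home, pick) else setdiff(away, pick)
      if (!length(pool)) pool <- setdiff(met_ids, pick)
      if (!length(pool)) break
      pick <- c(pick, pool[sample.int(length(pool), 1L)])
    }
    w <- stats::runif(length(pick), 0.5, 1.5)
    protein_links[[i]] <- stats::setNames(w / sum(w), pick)
  }

  # draw 3: censored subset of the affected metabolites
  n_cens <- round(cfg$censor_rate * n_aff)
  cens_feat <- if (n_cens > 0) sort(sample(affected, n_cens)) else character(0)
  # undetectable in the strain where the planted effect makes it lower:
  # effect < 0 (down in MUT) -> censored in MUT, else censored in WT
  cens_strain <- ifelse(affected_log2fc[cens_feat] < 0, "MUT", "WT")
  censored <- stats::setNames(as.character(cens_strain), cens_feat)

  ann <- pathway_annotation(c(met_ids, prot_ids), c(met_pw, prot_pw))
  structure(list(metabolite_ids = met_ids, protein_ids = prot_ids,
                 affected_log2fc = affected_log2fc,
                 effects_by_phase = effects_by_phase,
                 pathway_assignment = ann,
                 protein_links = protein_links,
                 censored_features = censored),
            class = "SyntheticTruth")
}

#' Simulate the multi-omics time course
#'
#' Per feature, a log2 baseline is drawn once and a per-phase shift (shared
#' across strains) is drawn once; each sample value is
#' `2^(baseline + phase_shift + strain_effect * 1[MUT] + N(0, noise_sd))`.
#' Protein log2 abundance is the truth-weighted sum of its linked
#' metabolites' log2 abundances in the same sample plus protein noise — all
#' strain signal reaches proteins through metabolites. Deterministic given
#' `cfg$seed` (a distinct sub-seed, `seed + 1`, drives this stage).
#'
#' @param truth a [make_truth()] result.
#' @param cfg the matching [simulation_config()].
#' @return list with elements `metabolomics` and `proteomics`, each a named
#'   list of `AbundanceMatrix` objects (one per phase, `scale="normalized"`).
#' @export
simulate_timecourse <- function(truth, cfg) {
  stopifnot(inherits(truth, "SyntheticTruth"), inherits(cfg, "SimulationConfig"))
  restore <- local_seed(cfg$seed + 1L)
  on.exit(restore())

  nm <- cfg$n_metabolites; np <- cfg$n_proteins
  reps <- cfg$replicates_per_group
  met_ids <- truth$metabolite_ids; prot_ids <- truth$protein_ids

  base_met <- stats::rnorm(nm, cfg$baseline_mean_log2, cfg$baseline_sd_log2)
  names(base_met) <- met_ids
  shift <- matrix(stats::rnorm(nm * length(cfg$phases), 0, cfg$phase_sd_log2),
                  nrow = nm, dimnames = list(met_ids, cfg$phases))

  eff <- stats::setNames(numeric(nm), met_ids)
  eff[names(truth$affected_log2fc)] <- truth$affected_log2fc

  # link weights as a proteins x metabolites matrix for the weighted sums
  W <- matrix(0, np, nm, dimnames = list(prot_ids, met_ids))
  for (p in prot_ids) W[p, names(truth$protein_links[[p]])] <-
    truth$protein_links[[p]]

  strains <- rep(c("WT", "MUT"), each = reps)
  repl <- rep(seq_len(reps), 2L)
  out_met <- out_prot <- stats::setNames(vector("list", length(cfg$phases)),
                                         cfg$phases)
  for (ph in cfg$phases) {
    sid <- paste0(strains, "_", ph, "_r", repl)
    meta <- data.frame(sample_id = sid, strain = strains, phase = ph,
                       replicate = repl, stringsAsFactors = FALSE)
    mu <- outer(base_met + shift[, ph], rep(1, 2L * reps)) +
      outer(eff, as.numeric(strains == "MUT"))
    log2_met <- mu + matrix(stats::rnorm(nm * 2L * reps, 0, cfg$noise_sd_log2),
                            nrow = nm)
    dimnames(log2_met) <- list(met_ids, sid)
    log2_prot <- W %*% log2_met +
      matrix(stats::rnorm(np * 2L * reps, 0, cfg$protein_noise_sd_log2),
             nrow = np)
    dimnames(log2_prot) <- list(prot_ids, sid)
    out_met[[ph]] <- abundance_matrix(2^log2_met, meta, "metabolomics",
                                      scale = "normalized")
    out_prot[[ph]] <- abundance_matrix(2^log2_prot, meta, "proteomics",
                                       scale = "normalized")
  }
  list(metabolomics = out_met, proteomics = out_prot)
}

#' Apply detection censoring
#'
#' For each censored feature of the truth, every sample of the designated
#' strain becomes missing — emulating metabolites consistently detected in
#' one strain and undetectable in the other.
#'
#' @param m an `AbundanceMatrix`.
#' @param truth a [make_truth()] result.
#' @return the censored `AbundanceMatrix`.
#' @export
apply_detection_censoring <- function(m, truth) {
  stopifnot(inherits(m, "AbundanceMatrix"), inherits(truth, "SyntheticTruth"))
  cens <- truth$censored_features
  if (!length(cens)) return(m)
  absent <- setdiff(names(cens), rownames(m$values))
  if (length(absent))
    stop("censored feature absent from matrix: ", absent[1L], call. = FALSE)
  for (f in names(cens)) {
    cols <- m$samples$strain == cens[[f]]
    m$values[f, cols] <- NA
  }
  m
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: draws truth, simulates the time course, and applies
#' detection censoring to the metabolomics matrices.
#'
#' @param cfg a [simulation_config()].
#' @return list with `truth`, `metabolomics`, `proteomics`.
#' @export
simulate_dataset <- function(cfg) {
  truth <- make_truth(cfg)
  sim <- simulate_timecourse(truth, cfg)
  sim$metabolomics <- lapply(sim$metabolomics, apply_detection_censoring,
                             truth = truth)
  c(list(truth = truth), sim)
}

#' Planted protein-level fold changes
#'
#' In the generative model all strain signal reaches proteins through
#' their linked metabolites, so the true protein log2 fold change is the
#' link-weighted sum of the planted metabolite effects.
#'
#' @param truth a [make_truth()] result.
#' @return named numeric vector, one log2FC (MUT vs WT) per protein.
#' @export
true_protein_log2fc <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  eff <- stats::setNames(numeric(length(truth$metabolite_ids)),
                         truth$metabolite_ids)
  eff[names(truth$affected_log2fc)] <- truth$affected_log2fc
  vapply(truth$protein_links, function(w) sum(w * eff[names(w)]),
         numeric(1))
}

#' Write a simulated dataset to disk
#'
#' Emits the standard wide abundance tables, one metadata table per phase
#' set, the pathway annotation table, and a truth JSON.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  all_meta <- list()
  for (mod in c("metabolomics", "proteomics")) {
    for (ph in names(sim[[mod]])) {
      m <- sim[[mod]][[ph]]
      f <- file.path(dir, sprintf("%s_%s.tsv", mod, gsub("[^A-Za-z0-9.]", "", ph)))
      write_abundance_table(m, f)
      paths[paste(mod, ph)] <- f
      all_meta[[paste(mod, ph)]] <- m$samples
    }
  }
  meta <- unique(do.call(rbind, all_meta))
  mf <- file.path(dir, "samples.tsv")
  utils::write.table(meta, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["metadata"] <- mf
  pf <- file.path(dir, "pathways.tsv")
  utils::write.table(as.data.frame(sim$truth$pathway_assignment), pf,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths["pathways"] <- pf
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(affected_log2fc = as.list(sim$truth$affected_log2fc),
         censored_features = as.list(sim$truth$censored_features),
         protein_links = lapply(sim$truth$protein_links, as.list)),
    tf, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- tf
  invisible(paths)
}
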