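# Desk-scale synthetic benchmark: the package's standard end-to-end
# experiment on generated data. Used by the test suite and the acceptance
# script so both measure exactly the same quantities.
#
# The benchmark runs at a reduced scale chosen once for single-CPU use:
# a 2 Mb genome (5 x 400 kb chromosomes), ~20k labeled training sites,
# a 201 bp DNA window and 10 neighbors per side, with proportionally
# narrowed layer widths. The full-size architecture defaults
# (dna_model_spec(), meth_model_spec(), encoding_spec()) are unchanged.

#' Benchmark architecture and encoding settings
#'
#' The reduced-scale model/encoding configuration used by the package's
#' synthetic benchmark: 201 bp window, 10 neighbors per side, 32+32
#' convolutional filters (kernels 11 and 3, pools 4 and 2), GRU widths
#' 16/32, joint width 64.
#'
#' @return List: encoding (without d_max), dna, meth, joint specs, and the
#'   train_config template.
#' @export
benchmark_specs <- function() {
  list(window_radius = 100L, k_neighbors = 10L,
       dna = dna_model_spec(n_filters1 = 48L, kernel1 = 11L, pool1 = 4L,
                            n_filters2 = 32L, kernel2 = 3L, pool2 = 2L,
                            fc_units = 32L, dropout = 0.25),
       meth = meth_model_spec(td_units = 8L, gru1_units = 16L, gru2_units = 32L,
                              dropout = 0.25),
       joint = joint_model_spec(fc_units = 64L),
       n_train = 14000L, n_val = 3000L, n_test = 4000L)
}

#' Simulation regimes of the benchmark
#'
#' "spatial": autocorrelated latent field only, no planted motifs (labels
#' depend on neighbors, not sequence). "motif": planted AT-rich hyper- and
#' CG-rich hypo-methylating consensus motifs only, no spatial field (labels
#' depend on sequence, not neighbors). "both": the default regime with both
#' signal sources. The motif effect radius equals the benchmark DNA window
#' half-width so the sequence model can in principle see every causal motif.
#'
#' @param regime One of "spatial", "motif", "both".
#' @param seed Simulation seed.
#' @return A [sim_config()].
#' @export
benchmark_sim_config <- function(regime = c("both", "spatial", "motif"), seed = 1L) {
  regime <- match.arg(regime)
  motifs <- list(
    hyper = list(consensus = "TATTTAAATAT", beta = 4, density_per_kb = 0.5),
    hypo = list(consensus = "GCGGCGCCGCG", beta = -4, density_per_kb = 0.5))
  sim_config(
    n_chroms = 5L, chrom_length = 400000L, gc_content = 0.4,
    planted_motifs = if (regime == "spatial") list() else motifs,
    spatial_rho = 0.95,
    spatial_sd = if (regime == "motif") 0 else 3,
    effect_radius = 100L,
    depth_lambda = 15, low_depth_fraction = 0.2, call_error = 0.1,
    seed = as.integer(seed))
}

benchmark_datasets <- function(sim, specs, seed) {
  labeled <- label_site(sim$report)
  dmax <- max_neighbor_gap(labeled)
  enc <- encoding_spec(specs$window_radius, specs$k_neighbors, dmax)
  spl <- split_sites(labeled, split_spec(paste0("chr", 1:3), "chr4", "chr5"))
  set.seed(seed)
  pick <- function(tab, n) tab[sort(sample.int(nrow(tab), min(n, nrow(tab))))]
  sub <- list(train = pick(spl$train, specs$n_train),
              val = pick(spl$val, specs$n_val),
              test = pick(spl$test, specs$n_test))
  ds <- lapply(names(sub), function(nm) {
    chroms <- unique(sub[[nm]]$chrom)
    build_dataset(sub[[nm]], sim$genome, enc,
                  neighbors = labeled[labeled$chrom %in% chroms])
  })
  names(ds) <- names(sub)
  c(ds, list(enc = enc, labeled = labeled))
}

train_benchmark_model <- function(kind, d, specs, cfg, regime = "both") {
  set.seed(cfg$seed)
  model <- switch(kind,
    dna = build_dna_model(specs$dna, d$enc),
    meth = build_meth_model(specs$meth, d$enc),
    joint = build_joint_model(specs$dna, specs$meth, specs$joint, d$enc))
  # epoch budget goes where there is signal to learn: the convolutional
  # branch converges slowly and gets its full budget only in the regimes
  # with planted sequence signal; the recurrent branch converges within a
  # few epochs under any regime and tolerates larger batches
  if (kind == "dna") {
    cfg$max_epochs <- switch(regime, spatial = 4L, motif = 20L, both = 5L)
    if (regime == "motif") cfg$patience <- 4L
  } else if (kind == "meth") {
    cfg$max_epochs <- 8L
    cfg$batch_size <- 256L
  } else {
    cfg$max_epochs <- 8L
  }
  train(model, d$train, d$val, cfg)
}

#' Run the full synthetic benchmark
#'
#' Simulates the three regimes, trains the DNA and methylation models in
#' each (plus the joint model in the "both" regime), evaluates held-out
#' chromosome-5 AUCs, imputes the sub-threshold (NA) sites of the "both"
#' regime and scores them against the hidden truth, and recovers the
#' planted motifs from the motif-regime DNA model.
#'
#' @param seed Integer seed driving simulation, subsampling and training.
#' @param verbose Print progress.
#' @return Nested list of metric panels, AUCs and motif-recovery scores.
#' @export
run_benchmark <- function(seed = 1L, verbose = FALSE) {
  specs <- benchmark_specs()
  cfg <- train_config(learning_rate = 1e-3, batch_size = 128L,
                      max_epochs = 16L, patience = 3L, lr_decay = 0.5,
                      seed = seed)
  res <- list(seed = seed)
  say <- function(...) if (verbose) message(...)

  for (regime in c("spatial", "motif", "both")) {
    say("regime: ", regime)
    sim <- run_simulation(benchmark_sim_config(regime, seed))
    d <- benchmark_datasets(sim, specs, seed)
    kinds <- if (regime == "both") c("dna", "meth", "joint") else c("dna", "meth")
    fit <- list()
    for (kind in kinds) {
      say("  training ", kind)
      fit[[kind]] <- train_benchmark_model(kind, d, specs, cfg, regime)
      prob <- predict(fit[[kind]], d$test)
      res[[regime]][[kind]] <- metrics(d$test$label, prob)
      say(sprintf("  %s test AUC %.3f", kind, res[[regime]][[kind]]$auc))
    }
    if (regime == "motif") {
      say("  extracting motifs")
      mot <- extract_motifs(fit$dna, d$test)
      cons <- benchmark_sim_config("motif", seed)$planted_motifs
      match_scores <- function(consensus) {
        vapply(mot$pwm, match_motif, 0, consensus = consensus)
      }
      hyper_m <- match_scores(cons$hyper$consensus)
      hypo_m <- match_scores(cons$hypo$consensus)
      res$motifs <- list(
        set = mot,
        hyper_match = max(hyper_m),
        hypo_match = max(hypo_m),
        hyper_effect = mot$table$effect[which.max(hyper_m)],
        hypo_effect = mot$table$effect[which.max(hypo_m)])
      say(sprintf("  hyper match %.3f (effect %.3f), hypo match %.3f (effect %.3f)",
                  res$motifs$hyper_match, res$motifs$hyper_effect,
                  res$motifs$hypo_match, res$motifs$hypo_effect))
    }
    if (regime == "both") {
      say("  imputing chr5 NA sites")
      test_sites <- d$labeled[d$labeled$chrom == "chr5"]
      tab <- impute_genome(fit$joint, test_sites, sim$genome["chr5"])
      truth <- sim$truth[sim$truth$chrom == "chr5"]
      key <- paste(tab$chrom, tab$pos, tab$strand)
      tkey <- paste(truth$chrom, truth$pos, truth$strand)
      na_idx <- which(is.na(tab$observed_state) & !is.na(tab$pred_prob))
      ts <- truth$true_state[match(key[na_idx], tkey)]
      res$impute <- list(
        auc = auc_score(ts, tab$pred_prob[na_idx]),
        n_rows_in = nrow(test_sites),
        n_rows_out = nrow(tab),
        n_na = sum(is.na(tab$observed_state)),
        n_imputed = sum(is.na(tab$observed_state) & !is.na(tab$imputed_state)),
        n_flagged = sum(tab$flag != ""),
        n_flagged_na = sum(tab$flag != "" & is.na(tab$observed_state)),
        observed_changed = {
          key_in <- paste(test_sites$chrom, test_sites$pos, test_sites$strand)
          key_out <- paste(tab$chrom, tab$pos, tab$strand)
          sum(tab$observed_state[match(key_in, key_out)] != test_sites$label,
              na.rm = TRUE)
        })
      say(sprintf("  imputation AUC vs hidden truth %.3f (n=%d)",
                  res$impute$auc, length(na_idx)))
    }
  }
  res
}
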