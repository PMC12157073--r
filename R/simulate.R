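# Synthetic genome + methylome generator. Emulates the statistical structure
# the predictive models exploit: three cytosine contexts, ~1:9
# methylated:unmethylated imbalance, a spatially autocorrelated latent
# methylation field (AR(1) over consecutive cytosines), sequence-motif-driven
# hyper/hypo-methylation, and variable read depth producing sub-threshold
# (NA) sites. Ground truth at every site, including NA sites, is retained so
# imputation can be scored.

#' Simulation configuration
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bases).
#' @param gc_content Background GC fraction.
#' @param planted_motifs List of motifs, each `list(consensus =, beta =,
#'   density_per_kb =)`: the consensus is stamped at Poisson-distributed
#'   non-overlapping positions, and `beta` shifts the latent methylation
#'   logit of every cytosine within `effect_radius` of a stamp.
#' @param beta0 Baseline logit; NULL (default) calibrates it with
#'   [calibrate_beta0()] so the marginal methylation rate is `target_rate`.
#' @param target_rate Marginal methylated fraction used for calibration
#'   (default 0.1, the canonical 1:9 imbalance).
#' @param spatial_rho AR(1) autocorrelation of the latent field over
#'   consecutive cytosines.
#' @param spatial_sd Stationary standard deviation of the latent field.
#' @param effect_radius Reach of a planted motif (bases; matches the DNA
#'   window half-width used by the sequence model).
#' @param depth_lambda Mean of the Poisson read-depth distribution.
#' @param low_depth_fraction Share of sites forced below 4 reads (depth
#'   resampled uniformly from 0..3).
#' @param call_error Per-read probability of a wrong methylation call.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_chroms = 5L, chrom_length = 400000L, gc_content = 0.4,
                       planted_motifs = list(
                         hyper = list(consensus = "TATTTAAATAT", beta = 4, density_per_kb = 0.5),
                         hypo = list(consensus = "GCGGCGCCGCG", beta = -4, density_per_kb = 0.5)),
                       beta0 = NULL, target_rate = 0.1,
                       spatial_rho = 0.95, spatial_sd = 3,
                       effect_radius = 500L, depth_lambda = 15,
                       low_depth_fraction = 0.2, call_error = 0.1, seed = 1L) {
  stopifnot(gc_content > 0, gc_content < 1,
            spatial_rho > 0, spatial_rho < 1,
            low_depth_fraction >= 0, low_depth_fraction < 1,
            chrom_length > 2L * 501L)
  structure(list(n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
                 gc_content = gc_content, planted_motifs = planted_motifs,
                 beta0 = beta0, target_rate = target_rate,
                 spatial_rho = spatial_rho, spatial_sd = spatial_sd,
                 effect_radius = as.integer(effect_radius),
                 depth_lambda = depth_lambda,
                 low_depth_fraction = low_depth_fraction,
                 call_error = call_error, seed = as.integer(seed)),
            class = "sim_config")
}

# probability that at least one stamp of motif m overlaps a +/- R window
motif_window_prob <- function(motif, effect_radius) {
  len <- 2 * effect_radius + nchar(motif$consensus)
  1 - exp(-motif$density_per_kb / 1000 * len)
}

#' Calibrate the baseline logit for a target methylation rate
#'
#' Solves E[logistic(beta0 + B + u)] = target for beta0, where u is the
#' stationary N(0, spatial_sd^2) latent field (integrated on a fine grid)
#' and B sums the planted-motif effects, each present with its window
#' probability (all combinations enumerated). Deterministic.
#'
#' @param config A [sim_config()].
#' @return The calibrated beta0.
#' @export
calibrate_beta0 <- function(config) {
  u <- seq(-8, 8, length.out = 4001) * config$spatial_sd
  wu <- stats::dnorm(u, 0, max(config$spatial_sd, 1e-12))
  wu <- wu / sum(wu)
  if (config$spatial_sd <= 0) { u <- 0; wu <- 1 }
  motifs <- config$planted_motifs
  m <- length(motifs)
  combos <- if (m > 0L) expand.grid(rep(list(0:1), m)) else data.frame(row.names = 1)
  pm <- vapply(motifs, motif_window_prob, 0, effect_radius = config$effect_radius)
  betas <- vapply(motifs, function(x) x$beta, 0)
  rate_at <- function(b0) {
    tot <- 0
    for (i in seq_len(nrow(combos))) {
      ind <- as.numeric(combos[i, ])
      w <- prod(ifelse(ind == 1, pm, 1 - pm))
      if (m == 0L) w <- 1
      tot <- tot + w * sum(wu * stats::plogis(b0 + sum(betas * ind) + u))
    }
    tot
  }
  stats::uniroot(function(b0) rate_at(b0) - config$target_rate,
                 c(-30, 10), tol = 1e-8)$root
}

#' Simulate a genome with planted motifs
#'
#' I.i.d. background bases at the configured GC content; each motif's
#' consensus is stamped at Poisson-distributed, mutually non-overlapping
#' positions and every stamp is logged.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (a `genome_set`) and `motif_log` (`data.table`
#'   with chrom, start, end, motif).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  probs <- c(A = (1 - config$gc_content) / 2, T = (1 - config$gc_content) / 2,
             G = config$gc_content / 2, C = config$gc_content / 2)
  seqs <- character(config$n_chroms)
  logs <- list()
  for (i in seq_len(config$n_chroms)) {
    ch <- sprintf("chr%d", i)
    bases <- sample(names(probs), config$chrom_length, replace = TRUE, prob = probs)
    occupied <- rep(FALSE, config$chrom_length)
    for (mi in seq_along(config$planted_motifs)) {
      motif <- config$planted_motifs[[mi]]
      w <- nchar(motif$consensus)
      if (w > config$chrom_length) stop("motif longer than chromosome")
      n_stamp <- stats::rpois(1, motif$density_per_kb * config$chrom_length / 1000)
      if (n_stamp == 0L) next
      starts <- sort(sample.int(config$chrom_length - w + 1L, min(n_stamp, config$chrom_length %/% w)))
      for (s in starts) {
        span <- s:(s + w - 1L)
        if (any(occupied[span])) next
        bases[span] <- seq_chars(motif$consensus)
        occupied[span] <- TRUE
        logs[[length(logs) + 1L]] <- data.table::data.table(
          chrom = ch, start = s, end = s + w - 1L,
          motif = names(config$planted_motifs)[mi] %||% sprintf("motif%d", mi))
      }
    }
    seqs[i] <- paste(bases, collapse = "")
  }
  names(seqs) <- sprintf("chr%d", seq_len(config$n_chroms))
  log_dt <- if (length(logs)) data.table::rbindlist(logs) else
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), motif = character())
  list(genome = structure(seqs, class = "genome_set"), motif_log = log_dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a methylome over a genome
#'
#' For every cytosine (both strands), the latent logit is
#' `beta0 + sum_m beta_m * [stamp of m within effect_radius] + u`, with `u`
#' an AR(1) field over consecutive cytosines. The true state is Bernoulli of
#' the logistic, read depth is Poisson (a configured fraction forced below
#' 4 reads), and methylated read counts are Binomial with the per-read call
#' error applied.
#'
#' @param genome A `genome_set` (from [simulate_genome()]).
#' @param motif_log Stamp log from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List: `report` (cytosine-report `data.table`: chrom, pos, strand,
#'   n_meth, n_unmeth, context) and `truth` (chrom, pos, strand, context,
#'   true_state, p_meth, depth).
#' @export
simulate_methylome <- function(genome, motif_log, config) {
  set.seed(config$seed + 1L)
  beta0 <- config$beta0 %||% calibrate_beta0(config)
  sites <- genome_cytosines(genome)
  n <- nrow(sites)
  motif_term <- numeric(n)
  for (mi in seq_along(config$planted_motifs)) {
    motif <- config$planted_motifs[[mi]]
    nm <- names(config$planted_motifs)[mi] %||% sprintf("motif%d", mi)
    w <- nchar(motif$consensus)
    for (ch in unique(sites$chrom)) {
      idx <- which(sites$chrom == ch)
      S <- sort(motif_log$start[motif_log$chrom == ch & motif_log$motif == nm])
      if (!length(S)) next
      p <- sites$pos[idx]
      lo <- p - config$effect_radius - w + 1L
      hi <- p + config$effect_radius
      cnt <- findInterval(hi, S) - findInterval(lo - 1L, S)
      motif_term[idx] <- motif_term[idx] + motif$beta * (cnt > 0L)
    }
  }
  u <- numeric(n)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)   # sites are sorted by (chrom, pos)
    m <- length(idx)
    innov <- stats::rnorm(m, 0, config$spatial_sd * sqrt(1 - config$spatial_rho^2))
    innov[1] <- stats::rnorm(1, 0, config$spatial_sd)
    u[idx] <- as.numeric(stats::filter(innov, config$spatial_rho, method = "recursive"))
  }
  p_meth <- stats::plogis(beta0 + motif_term + u)
  s <- stats::rbinom(n, 1L, p_meth)
  depth <- stats::rpois(n, config$depth_lambda)
  low <- stats::runif(n) < config$low_depth_fraction
  depth[low] <- sample(0:3, sum(low), replace = TRUE)
  p_read <- ifelse(s == 1L, 1 - config$call_error, config$call_error)
  n_meth <- stats::rbinom(n, depth, p_read)
  report <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    n_meth = n_meth, n_unmeth = depth - n_meth, context = sites$context)
  truth <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    context = sites$context, true_state = s, p_meth = p_meth, depth = depth)
  list(report = report, truth = truth, beta0 = beta0)
}

#' Run a full simulation
#'
#' Convenience wrapper: genome, stamp log, report and truth in one call.
#'
#' @param config A [sim_config()].
#' @return List: genome, motif_log, report, truth, beta0.
#' @export
run_simulation <- function(config = sim_config()) {
  g <- simulate_genome(config)
  m <- simulate_methylome(g$genome, g$motif_log, config)
  c(g, m)
}

#' Export a simulation as plain-text fixture files
#'
#' Writes `genome.fa`, `report.tsv` (readable by [read_cytosine_report()])
#' and `truth.tsv` to a directory. Byte-identical for identical seeds.
#'
#' @param sim Output of [run_simulation()].
#' @param out_dir Target directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "genome.fa")
  con <- file(fa, "w")
  for (ch in names(sim$genome)) {
    writeLines(paste0(">", ch), con)
    s <- sim$genome[[ch]]
    writeLines(substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69, nchar(s))), con)
  }
  close(con)
  rp <- file.path(out_dir, "report.tsv")
  data.table::fwrite(sim$report, rp, sep = "\t", col.names = FALSE, quote = FALSE)
  tr <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(sim$truth, tr, sep = "\t", quote = FALSE)
  invisible(c(genome = fa, report = rp, truth = tr))
}
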