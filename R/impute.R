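# Genome-wide imputation: fill NA methylation states from a trained model.

#' Impute missing methylation states genome-wide
#'
#' Every NA-labeled cytosine receives a predicted probability and a
#' binarized state (strictly > 0.5 means methylated). Neighbor features for
#' NA targets are built from observed-labeled sites only -- one prediction
#' pass, never from previously imputed values. Processing streams one
#' chromosome at a time. Observed labels are never altered unless
#' `overwrite = TRUE`, in which case observed sites are also predicted and
#' the model's call replaces the observed state (use with care: there is no
#' principled criterion for declaring an observed state wrong).
#'
#' @param model A trained `methyl_model` (carries its encoding and d_max).
#' @param records Labeled site table from [label_site()] (must include the
#'   NA-labeled sites and a `context` column).
#' @param genome The matching `genome_set`.
#' @param overwrite Also predict observed sites and replace their states.
#' @param predict_observed Also predict observed sites (probabilities only;
#'   their final state stays the observed label).
#' @return A `data.table` (the methylome table): chrom, pos, strand, context,
#'   depth, observed_state, pred_prob, imputed_state. Sites with
#'   indeterminate context are flagged in the `flag` column and not
#'   predicted.
#' @export
impute_genome <- function(model, records, genome, overwrite = FALSE,
                          predict_observed = overwrite) {
  stopifnot(inherits(model, "methyl_model"))
  if (!model$trained) warning("imputing with an untrained model")
  missing_chrom <- setdiff(unique(records$chrom), names(genome))
  if (length(missing_chrom)) {
    stop("chromosome(s) in records but absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  }
  out <- data.table::data.table(
    chrom = records$chrom, pos = records$pos, strand = records$strand,
    context = if ("context" %in% names(records)) records$context else NA_character_,
    depth = if ("depth" %in% names(records)) records$depth
            else records$n_meth + records$n_unmeth,
    observed_state = records$label,
    pred_prob = NA_real_,
    imputed_state = NA_integer_,
    flag = "")
  data.table::setorder(out, chrom, pos, strand)
  indet <- !is.na(out$context) & out$context == "indeterminate"
  out$flag[indet] <- "indeterminate_context"
  for (ch in unique(out$chrom)) {
    in_ch <- out$chrom == ch
    targets <- in_ch & !indet & (is.na(out$observed_state) | predict_observed)
    if (!any(targets)) next
    universe <- out[in_ch & !is.na(out$observed_state),
                    list(chrom, pos, label = observed_state)]
    ds <- build_dataset(
      out[targets, list(chrom, pos, strand, label = observed_state)],
      genome, model$encoding, neighbors = universe, allow_na = TRUE)
    # build_dataset re-sorts identically to `out`, so order is preserved
    out$pred_prob[which(targets)] <- predict(model, ds)
  }
  na_obs <- is.na(out$observed_state)
  out$imputed_state <- out$observed_state
  fill <- na_obs & !is.na(out$pred_prob)
  out$imputed_state[fill] <- binarize_prob(out$pred_prob[fill])
  if (overwrite) {
    repl <- !is.na(out$pred_prob)
    out$imputed_state[repl] <- binarize_prob(out$pred_prob[repl])
  }
  out[]
}

#' Per-interval observed/imputed track
#'
#' Extracts the observed and imputed state tracks for a genomic interval,
#' ready for plotting or bedGraph export.
#'
#' @param table Methylome table from [impute_genome()].
#' @param chrom Chromosome id.
#' @param start,end 1-based inclusive interval bounds.
#' @return `data.table` with pos, strand, context, observed_state,
#'   pred_prob, imputed_state for sites in the interval.
#' @export
region_report <- function(table, chrom, start, end) {
  if (end < start) {
    return(table[0, list(pos, strand, context, observed_state, pred_prob, imputed_state)])
  }
  sel <- table$chrom == chrom & table$pos >= start & table$pos <= end
  table[sel, list(pos, strand, context, observed_state, pred_prob, imputed_state)]
}
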