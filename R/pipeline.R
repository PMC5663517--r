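# End-to-end orchestration: featurize -> train -> hills -> motifs -> score,
# and the simulation benchmark harness comparing the hierarchical model with
# the naive multi-class baseline.

#' Run the full pipeline on a labeled dataset
#'
#' @param dataset a [labeled_dataset()].
#' @param outdir output directory for [write_outputs()]; `NULL` skips
#'   writing.
#' @param config a [train_config()].
#' @param hill_threshold hill score threshold (default 0.1).
#' @param kmer_frac motif k-mer membership threshold (default 0.7).
#' @param seed random seed for motif discovery.
#' @return list with `model` (an `md_model`), `motifs` (a
#'   `motif_score_table`) and `files` (paths written, if any).
#' @export
run_pipeline <- function(dataset, outdir = NULL, config = train_config(),
                         hill_threshold = 0.1, kmer_frac = 0.7,
                         seed = config$seed) {
  fm <- feature_matrix(dataset$sequences)
  model <- train_model(dataset, fm, config)
  motifs <- discover_motifs(model, dataset, hill_threshold = hill_threshold,
                            kmer_frac = kmer_frac, seed = seed)
  files <- if (!is.null(outdir))
    write_outputs(model, motifs, outdir, sites = attr(dataset, "sites"))
  list(model = model, motifs = motifs, files = files)
}

# drop near-identical discovered motifs (greedy by LLR) and motifs flagged
# low-complexity, so assignment counts are not inflated by re-discoveries.
# The threshold is stricter than the truth-matching threshold: distinct
# motifs can correlate moderately by chance over 6 columns.
dedupe_motifs <- function(motifs, threshold = 0.85) {
  motifs <- Filter(function(m) !isTRUE(m$low_complexity), motifs)
  if (length(motifs) <= 1L) return(motifs)
  ord <- order(-vapply(motifs, function(m)
    if (is.finite(m$llr)) m$llr else -Inf, numeric(1)))
  kept <- list()
  for (i in ord) {
    dup <- any(vapply(kept, function(km)
      pwm_correlation(motifs[[i]]$matrix, km$matrix) >= threshold,
      logical(1)))
    if (!dup) kept[[motifs[[i]]$name]] <- motifs[[i]]
  }
  kept[order(match(names(kept), names(motifs)))]
}

#' Simulation benchmark of motif-label deconvolution
#'
#' Generates one synthetic dataset at the requested label overlap, trains
#' both the hierarchical model and the naive multi-class baseline, discovers
#' motifs from the hierarchical model's hills, dedupes them, matches them
#' against the planted PWMs, and scores motif-label assignments for both
#' methods on the same discovered motif set (the methods differ in the label
#' weight vectors that drive assignment).
#'
#' @param overlap requested label co-occurrence rate.
#' @param n_sites dataset size (default 2000).
#' @param seed random seed for generation, training folds and motif
#'   discovery.
#' @param config a [train_config()]; its seed is overridden by `seed`.
#' @param label_sets passed to [sim_config()].
#' @param insertion_freq motif insertion frequency (default 0.7).
#' @param assign_thresh assignment score threshold (default 0, see
#'   [score_assignments()]).
#' @param fit_baseline also fit and evaluate the MCC baseline (default TRUE;
#'   skipping it saves time when only the hierarchical model is of
#'   interest).
#' @return list with elements `hier` and `mcc` (each a [score_assignments()]
#'   result augmented with `all_correct_exclusive`: every planted motif
#'   recovered and assigned exactly its true label), plus `mapping`,
#'   `motifs`, and `sim_stats` from [sim_realized_stats()].
#' @export
evaluate_simulation <- function(overlap, n_sites = 2000L, seed = 1L,
                                config = train_config(),
                                label_sets = list(c("A", "B"),
                                                  c("X", "Y")),
                                insertion_freq = 0.7, assign_thresh = 0,
                                fit_baseline = TRUE) {
  config$seed <- seed
  sim <- simulate_dataset(sim_config(n_sites = n_sites,
                                     label_sets = label_sets,
                                     overlap = overlap,
                                     insertion_freq = insertion_freq,
                                     seed = seed))
  ds <- sim$dataset
  fm <- feature_matrix(ds$sequences)
  model <- train_model(ds, fm, config)
  mcc <- if (fit_baseline) fit_mcc_baseline(ds, fm)

  disc <- discover_motifs(model, ds, seed = seed)
  motifs <- dedupe_motifs(disc$motifs)
  truth <- sim$config$motif_assignment
  truth_pwms <- truth[!duplicated(vapply(truth, function(m) m$name,
                                         character(1)))]
  names(truth_pwms) <- vapply(truth_pwms, function(m) m$name, character(1))
  truth_labels <- stats::setNames(
    names(truth),
    vapply(truth, function(m) m$name, character(1)))

  mapping <- match_motifs(motifs, truth_pwms)

  eval_one <- function(tbl) {
    res <- score_assignments(tbl, mapping, truth_labels, assign_thresh)
    ok <- vapply(names(truth_labels), function(tm) {
      dm <- mapping$discovered[mapping$truth == tm]
      length(dm) > 0L &&
        setequal(unique(unlist(res$assignments[dm])), truth_labels[[tm]])
    }, logical(1))
    res$all_correct_exclusive <- all(ok)
    res$per_motif_ok <- ok
    res
  }
  tbl_h <- score_table(motifs, model)
  list(hier = eval_one(tbl_h),
       mcc = if (fit_baseline) eval_one(score_table(motifs, mcc)),
       mapping = mapping, motifs = motifs,
       sim_stats = sim_realized_stats(sim), model = model)
}
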