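# Evaluation against simulation ground truth: PWM matching, motif-label
# assignment error rates, and cross-validated classification performance.

# best mean per-column Pearson correlation between two PWMs over all gapless
# offsets (>= min_cols aligned columns) and both orientations
pwm_correlation <- function(a, b, min_cols = 6L) {
  best <- -Inf
  for (mb in list(b, pwm_revcomp(b))) {
    wa <- nrow(a); wb <- nrow(mb)
    for (off in (-(wb - min_cols)):(wa - min_cols)) {
      ia <- max(1L, 1L + off):min(wa, wb + off)
      if (length(ia) < min_cols) next
      ib <- ia - off
      cors <- vapply(seq_along(ia), function(j) {
        ca <- a[ia[j], ]; cb <- mb[ib[j], ]
        if (stats::sd(ca) == 0 || stats::sd(cb) == 0) return(0)
        stats::cor(ca, cb)
      }, numeric(1))
      best <- max(best, mean(cors))
    }
  }
  best
}

#' Match discovered motifs to ground-truth motifs
#'
#' Best gapless alignment over all offsets and both orientations; a pair
#' matches when the mean per-column Pearson correlation is at least
#' `threshold` over at least `min_cols` aligned columns. Pairs are assigned
#' one-to-one greedily by decreasing correlation.
#'
#' @param discovered list of [pwm()].
#' @param truth list of [pwm()] (ground truth).
#' @param threshold mean column-correlation threshold (default 0.75).
#' @param min_cols minimum aligned columns (default 6).
#' @return data.frame with columns `discovered`, `truth`, `correlation`; one
#'   row per matched pair.
#' @export
match_motifs <- function(discovered, truth, threshold = 0.75,
                         min_cols = 6L) {
  out <- data.frame(discovered = character(0), truth = character(0),
                    correlation = numeric(0), stringsAsFactors = FALSE)
  if (length(discovered) == 0L || length(truth) == 0L) return(out)
  cm <- matrix(NA_real_, nrow = length(discovered), ncol = length(truth),
               dimnames = list(names(discovered), names(truth)))
  for (i in seq_along(discovered)) for (j in seq_along(truth))
    cm[i, j] <- pwm_correlation(discovered[[i]]$matrix, truth[[j]]$matrix,
                                min_cols)
  while (TRUE) {
    best <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    if (!is.finite(cm[best[1L], best[2L]]) ||
        cm[best[1L], best[2L]] < threshold) break
    out <- rbind(out, data.frame(discovered = rownames(cm)[best[1L]],
                                 truth = colnames(cm)[best[2L]],
                                 correlation = cm[best[1L], best[2L]],
                                 stringsAsFactors = FALSE))
    cm[best[1L], ] <- NA
    cm[, best[2L]] <- NA
    if (all(is.na(cm))) break
  }
  out
}

#' Evaluate motif-label assignments against ground truth
#'
#' A motif is assigned to every label whose score exceeds `assign_thresh`
#' and — when the score table carries subclass models — whose every spanned
#' subclass also scores the motif above `assign_thresh`: a label-specific
#' feature must be consistently enriched across all subclasses the label
#' spans, which is what makes the assignment robust to label co-occurrence
#' (a confounded motif scores negatively in at least one spanned subclass).
#' For each ground-truth motif recovered by the matcher, its true label
#' yields a TP if assigned (else FN) and every wrong label assigned counts
#' as an FP; unrecovered truth motifs count as FN. Discovered motifs that
#' match no planted motif are not adjudicated: they have no defined true
#' label. Rates are computed over the truth motif x label grid.
#'
#' @param tbl a `motif_score_table` (label columns are used).
#' @param mapping match table from [match_motifs()].
#' @param truth_labels named character vector: truth motif name -> true
#'   label.
#' @param assign_thresh assignment score threshold (default 0: a positive
#'   score, consistent across spanned subclasses, assigns the motif).
#' @return list with counts `TP`, `FP`, `FN`, rates `TPR`, `FPR`,
#'   `precision`, `recall`, `F1`, and the per-motif `assignments`.
#' @export
score_assignments <- function(tbl, mapping, truth_labels,
                              assign_thresh = 0) {
  labels <- tbl$labels
  n_truth <- length(truth_labels)
  S <- tbl$scores[, labels, drop = FALSE]
  ok <- S > assign_thresh
  if (!is.null(tbl$spanned)) {
    for (p in labels) {
      sub_ok <- tbl$scores[, tbl$spanned[[p]], drop = FALSE] > assign_thresh
      ok[, p] <- ok[, p] & apply(sub_ok, 1L, all)
    }
  }
  assigned <- lapply(seq_len(nrow(S)), function(i) labels[ok[i, ]])
  names(assigned) <- rownames(S)

  TP <- 0L; FP <- 0L; FN <- 0L
  for (tm in names(truth_labels)) {
    dm <- mapping$discovered[mapping$truth == tm]
    if (length(dm) == 0L) { FN <- FN + 1L; next }
    got <- unique(unlist(assigned[dm]))
    if (truth_labels[[tm]] %in% got) TP <- TP + 1L else FN <- FN + 1L
    FP <- FP + length(setdiff(got, truth_labels[[tm]]))
  }
  N_neg <- n_truth * (length(labels) - 1L)
  precision <- if (TP + FP > 0L) TP / (TP + FP) else 1
  recall <- if (TP + FN > 0L) TP / (TP + FN) else 0
  F1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  list(TP = TP, FP = FP, FN = FN,
       TPR = recall, FPR = if (N_neg > 0L) FP / N_neg else 0,
       precision = precision, recall = recall, F1 = F1,
       assignments = assigned)
}

#' Cross-validated subclass auROC
#'
#' K-fold cross-validation (folds stratified by subclass): the model is
#' trained on the remaining folds and held-out subclass posteriors give a
#' one-vs-rest auROC per subclass, averaged over folds. Subclasses with
#' fewer members than folds are excluded with a warning.
#'
#' @param dataset a [labeled_dataset()].
#' @param config a [train_config()].
#' @param folds number of folds (default 3).
#' @param space a [kmer_space()].
#' @return named numeric vector of per-subclass auROC values.
#' @export
crossval_auroc <- function(dataset, config = train_config(), folds = 3L,
                           space = kmer_space()) {
  small <- dataset$subclasses[dataset$subclass_sizes < folds]
  if (length(small))
    warning("excluding subclasses with fewer members than folds: ",
            paste(small, collapse = ", "))
  set.seed(config$seed)
  fold_of <- make_stratified_folds(dataset$subclass_of, folds)
  auc_mat <- matrix(NA_real_, nrow = folds,
                    ncol = length(dataset$subclasses),
                    dimnames = list(NULL, dataset$subclasses))
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    sub <- labeled_dataset(dataset$sequences[tr], dataset$label_sets[tr])
    fm <- feature_matrix(sub$sequences, space)
    fit <- train_model(sub, fm, config)
    X_te <- featurize(fm, dataset$sequences[te])
    p <- subclass_posteriors(X_te, fit$weights)
    key_te <- subclass_key(dataset$label_sets[te])
    for (sc in colnames(p)) {
      is_pos <- key_te == sc
      if (sum(is_pos) == 0L || sum(!is_pos) == 0L) next
      auc_mat[f, sc] <- auroc(p[, sc], is_pos)
    }
  }
  aucs <- colMeans(auc_mat, na.rm = TRUE)
  aucs[dataset$subclass_sizes >= folds & is.finite(aucs)]
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) auROC of a score against a binary truth.
#'
#' @param score numeric scores.
#' @param positive logical vector, `TRUE` for positives.
#' @return scalar auROC in `[0, 1]`.
#' @export
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  r <- rank(score)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  stopifnot(n_pos > 0L, n_neg > 0L)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Realized statistics of a simulated dataset
#'
#' Reports the realized per-label insertion frequency (fraction of
#' label-bearing sequences that received an instance of the label's motif)
#' and, for paired label sets, the realized co-occurrence rate.
#'
#' @param sim result of [simulate_dataset()].
#' @return list with `insertion_freq` (named by label) and `overlap`.
#' @export
sim_realized_stats <- function(sim) {
  ds <- sim$dataset
  ins <- sim$truth$insertions
  labels <- unlist(sim$config$label_sets, use.names = FALSE)
  insf <- vapply(labels, function(lab) {
    carriers <- which(vapply(ds$label_sets, function(l) lab %in% l,
                             logical(1)))
    if (length(carriers) == 0L) return(NA_real_)
    with_ins <- unique(ins$seq_index[ins$label == lab])
    length(intersect(carriers, with_ins)) / length(carriers)
  }, numeric(1))
  overlap <- NA_real_
  set1 <- sim$config$label_sets[[1]]
  if (length(sim$config$label_sets) > 1L) {
    set2 <- sim$config$label_sets[[2]]
    k <- min(length(set1), length(set2))
    hits <- 0L; tot <- 0L
    for (i in seq_len(k)) {
      carriers <- vapply(ds$label_sets, function(l) set1[i] %in% l,
                         logical(1))
      both <- vapply(ds$label_sets,
                     function(l) set1[i] %in% l && set2[i] %in% l,
                     logical(1))
      hits <- hits + sum(both); tot <- tot + sum(carriers)
    }
    overlap <- hits / tot
  }
  list(insertion_freq = insf, overlap = overlap)
}

#' Trinucleotide frequency spectrum
#'
#' @param seqs character vector of sequences.
#' @return named numeric vector of the 64 trinucleotide frequencies.
#' @export
trinucleotide_spectrum <- function(seqs) {
  counts <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(seqs)))
  counts / sum(counts)
}
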