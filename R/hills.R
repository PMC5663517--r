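# Hill extraction: scan trained k-mer models across sequences and call
# short (10-15 bp) high-scoring subregions that concentrate the
# discriminative signal.

HILL_MIN <- 10L
HILL_MAX <- 15L

# per-position k-mer model weight tracks for equal-length sequences.
# Returns a list over k of (sequences x (L-k+1)) matrices of weights; windows
# containing non-ACGT bases score 0.
position_weights <- function(code, w, space) {
  out <- list()
  for (k in space$k_values) {
    idx <- kmer_code_windows(code, k)
    cols <- space$code_lookup[[as.character(k)]][idx + 1L]
    pw <- w[cols]
    pw[is.na(pw)] <- 0
    dim(pw) <- dim(idx)
    out[[as.character(k)]] <- pw
  }
  out
}

#' Scan a k-mer model across sequences
#'
#' For every 15 bp window the score is the sum, over all k-mer occurrences
#' starting inside the window, of the model's weight for that (canonical)
#' k-mer. Occurrences are weighted by raw counts, not standardized counts:
#' per-window standardization is undefined and raw weighting preserves
#' locality.
#'
#' @param seqs character vector of equal-length sequences.
#' @param w numeric weight vector of length `space$K` (a row of a label or
#'   subclass model).
#' @param space a [kmer_space()].
#' @param window scan window width in bp (default 15, the maximum hill size).
#' @return matrix (sequences x (L - window + 1)) of window scores; zero
#'   columns if sequences are shorter than `window`.
#' @export
scan_model <- function(seqs, w, space, window = HILL_MAX) {
  code <- seq_code_matrix(seqs)
  L <- ncol(code)
  n_win <- L - window + 1L
  if (n_win < 1L)
    return(matrix(numeric(0), nrow = length(seqs), ncol = 0L))
  pw <- position_weights(code, w, space)
  track <- matrix(0, nrow = length(seqs), ncol = n_win)
  for (k in space$k_values) {
    mat <- pw[[as.character(k)]]
    # sum of position weights for k-mer starts s .. s + window - k
    cs <- cbind(0, t(apply(mat, 1L, cumsum)))
    span <- window - k + 1L
    track <- track + (cs[, (span + 1L):(span + n_win), drop = FALSE] -
                        cs[, 1L:n_win, drop = FALSE])
  }
  track
}

# segment one score track into maximal super-threshold runs; each run yields
# one candidate hill centred on its maximal window.
segment_track <- function(track_row, threshold, window = HILL_MAX) {
  above <- track_row > threshold
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  res <- lapply(runs, function(i) {
    win <- starts[i]:ends[i]
    best <- win[which.max(track_row[win])]
    c(start = best - 1L, end = best - 1L + window,
      score = max(track_row[win]))
  })
  do.call(rbind, res)
}

#' Call hills from trained model score tracks
#'
#' Maximal runs of 15 bp windows scoring above `threshold` are merged; each
#' run is reported as one hill spanning the run's maximal window. Overlapping
#' candidates from adjacent runs are resolved greedily by score. Per-label
#' hills are called only on sequences bearing that label.
#'
#' @param seqs character vector of equal-length sequences.
#' @param w model weight vector (length `space$K`).
#' @param space a [kmer_space()].
#' @param threshold window score threshold defining a hill (default 0.1).
#' @param seq_ids optional sequence identifiers.
#' @param model_name name recorded in the `source_model` column.
#' @return data.frame with columns `seq_index`, `seq_id`, `start`, `end`
#'   (0-based half-open within the sequence), `score`, `source_model`, `dna`.
#' @export
call_hills <- function(seqs, w, space, threshold = 0.1, seq_ids = NULL,
                       model_name = "model") {
  empty <- data.frame(seq_index = integer(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), source_model = character(0),
                      dna = character(0), stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  if (is.null(seq_ids)) seq_ids <- sprintf("seq%d", seq_along(seqs))
  track <- scan_model(seqs, w, space)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (ncol(track) == 0L) break
    seg <- segment_track(track[i, ], threshold)
    if (is.null(seg)) next
    if (nrow(seg) > 1L) {
      # greedy non-overlap resolution: keep higher-scoring hills
      ord <- order(-seg[, "score"])
      keep <- logical(nrow(seg))
      for (j in ord) {
        ks <- seg[keep, , drop = FALSE]
        overlaps <- nrow(ks) > 0L &&
          any(pmax(ks[, "start"], seg[j, "start"]) <
                pmin(ks[, "end"], seg[j, "end"]))
        keep[j] <- !overlaps
      }
      seg <- seg[keep, , drop = FALSE]
      seg <- seg[order(seg[, "start"]), , drop = FALSE]
    }
    out[[i]] <- data.frame(seq_index = i, seq_id = seq_ids[i],
                           start = as.integer(seg[, "start"]),
                           end = as.integer(seg[, "end"]),
                           score = seg[, "score"],
                           source_model = model_name,
                           stringsAsFactors = FALSE)
  }
  hills <- do.call(rbind, out)
  if (is.null(hills)) return(empty)
  hills$dna <- substr(seqs[hills$seq_index], hills$start + 1L, hills$end)
  rownames(hills) <- NULL
  hills
}

#' Call per-label hills for a trained model
#'
#' @param model an `md_model` from [train_model()].
#' @param dataset the [labeled_dataset()] to scan (typically the training
#'   data).
#' @param threshold hill score threshold (default 0.1).
#' @return named list of hill data.frames, one per label; each label's model
#'   is scanned only over sequences carrying that label.
#' @export
label_hills <- function(model, dataset, threshold = 0.1) {
  out <- list()
  for (p in model$labels) {
    idx <- which(vapply(dataset$label_sets, function(l) p %in% l,
                        logical(1)))
    if (length(idx) == 0L) {
      out[[p]] <- call_hills(character(0), model$weights$W_lab[p, ],
                             model$space, threshold)
      next
    }
    h <- call_hills(dataset$sequences[idx], model$weights$W_lab[p, ],
                    model$space, threshold, seq_ids = dataset$ids[idx],
                    model_name = p)
    h$seq_index <- idx[h$seq_index]
    out[[p]] <- h
  }
  out
}
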