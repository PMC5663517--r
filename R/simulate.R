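# Synthetic labeled datasets: Markov background sequences, two overlapping
# label sets with a controlled co-occurrence rate, and PWM-sampled motif
# instances planted at label-bearing sites.

soft_pwm <- function(consensus, strong = 0.85, mids = integer(0),
                     mid_p = 0.6) {
  cd <- match(strsplit(consensus, "")[[1]], DNA_BASES)
  w <- length(cd)
  mat <- matrix((1 - strong) / 3, nrow = w, ncol = 4L)
  mat[cbind(seq_len(w), cd)] <- strong
  for (j in mids) {
    mat[j, ] <- (1 - mid_p) / 3
    mat[j, cd[j]] <- mid_p
  }
  mat / rowSums(mat)
}

#' Bundled synthetic motif PWMs
#'
#' Five distinct PWMs of widths 7-10 styled on well-known TF binding motif
#' families (homeodomain, E-box, forkhead, GATA and AP-1 consensus patterns).
#' They are constructed by the package for simulations, not taken from a
#' motif database. Widths of at least 7 keep the motifs identifiable by the
#' PWM matcher (which requires 6 aligned columns) even when a discovered
#' motif is registered one column off.
#'
#' @return named list of [pwm()] objects.
#' @export
bundled_motifs <- function() {
  list(
    HOMEO = pwm(soft_pwm("CTAATTA", mids = c(1L, 7L)), name = "HOMEO"),
    EBOX  = pwm(soft_pwm("GCAGCTGC", mids = c(1L, 8L)), name = "EBOX"),
    FKHD  = pwm(soft_pwm("TGTTTACA", mids = 8L), name = "FKHD"),
    GATA  = pwm(soft_pwm("AGATAAGA", mids = c(1L, 7L, 8L)), name = "GATA"),
    AP1   = pwm(soft_pwm("ATGACTCATC", mids = c(1L, 2L, 9L, 10L)),
                name = "AP1")
  )
}

#' Sample an instance from a PWM
#'
#' Each base is drawn column-wise from the PWM's probability density.
#'
#' @param x a [pwm()].
#' @return a character string of width `nrow(x$matrix)`.
#' @export
sample_pwm_instance <- function(x) {
  paste(apply(x$matrix, 1L, function(p) sample(DNA_BASES, 1L, prob = p)),
        collapse = "")
}

#' Simulation configuration
#'
#' @param n_sites number of sequences (default 6000).
#' @param seq_len sequence length in bp (default 150).
#' @param label_sets list of two character vectors: the two overlapping label
#'   sets. The i-th label of set 1 is paired with the i-th label of set 2
#'   (labels of set 1 beyond the length of set 2 are unpaired and draw their
#'   set-2 partner uniformly).
#' @param overlap pairwise co-occurrence rate in `[0, 1]`: the probability
#'   that a sequence carrying a set-1 label also carries its paired set-2
#'   label (otherwise a uniformly chosen other set-2 label).
#' @param insertion_freq probability that a label carried by a sequence
#'   plants a motif instance there (default 0.7).
#' @param motif_assignment named list label -> [pwm()]; defaults to the
#'   [bundled_motifs()] assigned to labels in order.
#' @param background a `markov_model` (default
#'   [default_markov_background()]).
#' @param seed random seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites = 6000L, seq_len = 150L,
                       label_sets = list(c("A", "B"), c("X", "Y")),
                       overlap = 0.7, insertion_freq = 0.7,
                       motif_assignment = NULL,
                       background = default_markov_background(),
                       seed = 1L) {
  stopifnot(overlap >= 0, overlap <= 1,
            insertion_freq >= 0, insertion_freq <= 1,
            length(label_sets) %in% 1:2)
  labels <- unlist(label_sets, use.names = FALSE)
  if (is.null(motif_assignment)) {
    bank <- bundled_motifs()
    stopifnot(length(labels) <= length(bank))
    motif_assignment <- stats::setNames(bank[seq_along(labels)], labels)
  }
  stopifnot(all(labels %in% names(motif_assignment)))
  widths <- vapply(motif_assignment, function(m) nrow(m$matrix), integer(1))
  if (any(widths > seq_len)) stop("motif wider than seq_len")
  structure(list(n_sites = as.integer(n_sites),
                 seq_len = as.integer(seq_len), label_sets = label_sets,
                 overlap = overlap, insertion_freq = insertion_freq,
                 motif_assignment = motif_assignment,
                 background = background, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic labeled dataset
#'
#' Sequences are drawn from the background Markov model; each sequence gets
#' one label from each label set, with the set-2 label equal to the set-1
#' label's partner with probability `overlap`. For every label on a
#' sequence, with probability `insertion_freq` an instance of the label's
#' motif is sampled column-wise from its PWM and written over the background
#' at a uniform-random offset; multiple insertions on one sequence are placed
#' without overlap (the offset is resampled up to 10 times, then the
#' insertion is skipped and recorded).
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [labeled_dataset()]), `truth` (list:
#'   `motif_of_label`, `insertions` data.frame with columns seq_index, label,
#'   motif, start, width, and `skipped` count) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_sites
  L <- config$seq_len
  seqs <- sample_background(config$background, n, L)

  set1 <- config$label_sets[[1]]
  set2 <- if (length(config$label_sets) > 1L) config$label_sets[[2]]
  else character(0)
  l1 <- sample(set1, n, replace = TRUE)
  label_sets <- as.list(l1)
  if (length(set2) > 0L) {
    partner <- stats::setNames(rep(NA_character_, length(set1)), set1)
    k <- min(length(set1), length(set2))
    partner[seq_len(k)] <- set2[seq_len(k)]
    l2 <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      p <- partner[[l1[i]]]
      if (is.na(p)) {
        l2[i] <- sample(set2, 1L)
      } else if (stats::runif(1) < config$overlap) {
        l2[i] <- p
      } else if (length(set2) > 1L) {
        l2[i] <- sample(setdiff(set2, p), 1L)
      }  # else: no alternative set-2 label; the site keeps only l1
    }
    label_sets <- mapply(function(a, b) if (is.na(b)) a else c(a, b),
                         l1, l2, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }

  ins <- list()
  skipped <- 0L
  for (i in seq_len(n)) {
    occupied <- matrix(integer(0), ncol = 2L)
    for (lab in label_sets[[i]]) {
      if (stats::runif(1) >= config$insertion_freq) next
      m <- config$motif_assignment[[lab]]
      w <- nrow(m$matrix)
      placed <- FALSE
      for (try in 1:10) {
        start <- sample.int(L - w + 1L, 1L) - 1L
        clash <- nrow(occupied) > 0L &&
          any(pmax(occupied[, 1L], start) < pmin(occupied[, 2L], start + w))
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed) { skipped <- skipped + 1L; next }
      occupied <- rbind(occupied, c(start, start + w))
      inst <- sample_pwm_instance(m)
      substr(seqs[i], start + 1L, start + w) <- inst
      ins[[length(ins) + 1L]] <- data.frame(seq_index = i, label = lab,
                                            motif = m$name, start = start,
                                            width = w,
                                            stringsAsFactors = FALSE)
    }
  }
  insertions <- if (length(ins)) do.call(rbind, ins)
  else data.frame(seq_index = integer(0), label = character(0),
                  motif = character(0), start = integer(0),
                  width = integer(0), stringsAsFactors = FALSE)

  dataset <- labeled_dataset(seqs, label_sets)
  motif_of_label <- vapply(config$motif_assignment, function(m) m$name,
                           character(1))
  list(dataset = dataset,
       truth = list(motif_of_label = motif_of_label,
                    insertions = insertions, skipped = skipped),
       config = config)
}

#' The five-label benchmark fixture
#'
#' 9,000 sequences of 150 bp carrying labels from two overlapping sets
#' ({A, B, C} and {X, Y}) with a strong A-X and B-Y pairing (co-occurrence
#' 0.85; C draws its set-2 label uniformly), one distinct bundled motif per
#' label, and motif instances planted at 70% of label-bearing sites.
#'
#' @param seed random seed.
#' @param n_sites number of sequences (default 9000).
#' @return as [simulate_dataset()].
#' @export
fig_fixture_5label <- function(seed = 1L, n_sites = 9000L) {
  bank <- bundled_motifs()
  cfg <- sim_config(n_sites = n_sites, seq_len = 150L,
                    label_sets = list(c("A", "B", "C"), c("X", "Y")),
                    overlap = 0.85, insertion_freq = 0.7,
                    motif_assignment = list(A = bank$HOMEO, B = bank$EBOX,
                                            C = bank$FKHD, X = bank$GATA,
                                            Y = bank$AP1),
                    seed = seed)
  simulate_dataset(cfg)
}
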