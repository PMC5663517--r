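# Motif derivation from hills: K-means clustering with silhouette-selected K,
# a ZOOPS-EM position weight matrix finder, and scoring of motifs against
# label/subclass k-mer models.

#' Position weight matrix
#'
#' @param mat numeric matrix, width x 4 (columns A,C,G,T), rows summing to 1.
#' @param name motif name.
#' @param source_cluster optional provenance string.
#' @param llr log-likelihood ratio of the EM fit vs background, if known.
#' @param low_complexity flag set when the fit does not beat a shuffled-
#'   sequence null.
#' @return object of class `pwm`.
#' @export
pwm <- function(mat, name = "motif", source_cluster = NA_character_,
                llr = NA_real_, low_complexity = FALSE) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4L, all(abs(rowSums(mat) - 1) < 1e-6))
  colnames(mat) <- DNA_BASES
  structure(list(matrix = mat, name = name, source_cluster = source_cluster,
                 llr = llr, low_complexity = low_complexity),
            class = "pwm")
}

#' Consensus string of a PWM
#' @param x a [pwm()].
#' @return character consensus (most probable base per column).
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 1L, which.max)], collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$name, ":", pwm_consensus(x),
      if (isTRUE(x$low_complexity)) "(low complexity)" else "", "\n")
  invisible(x)
}

pwm_revcomp <- function(mat) {
  mat[rev(seq_len(nrow(mat))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Cluster hills by k-mer content
#'
#' Hills are embedded as raw canonical k-mer count vectors, restricted to
#' k-mers present in at least 5% of the hills. K is chosen from 2..6 by the
#' highest median silhouette index over 30 bootstrap samples (of size
#' min(500, n), drawn with replacement); clusters smaller than 10% of the
#' largest cluster are then merged into their nearest centroid. Fewer than 20
#' hills (or degenerate identical hills) yield a single cluster.
#'
#' @param hills hill data.frame from [call_hills()].
#' @param space a [kmer_space()].
#' @param seed random seed for bootstraps and K-means starts.
#' @param k_range candidate cluster numbers.
#' @param n_boot number of bootstrap samples for the silhouette index.
#' @return integer vector of cluster assignments (1-based), with attribute
#'   `"K"` (selected K after merging).
#' @export
cluster_hills <- function(hills, space, seed = 1L, k_range = 2:6,
                          n_boot = 30L) {
  n <- nrow(hills)
  single <- structure(rep(1L, n), K = 1L)
  if (n < 20L) return(single)
  feats <- count_kmers(hills$dna, space)
  keep <- colMeans(feats > 0) >= 0.05
  feats <- feats[, keep, drop = FALSE]
  if (ncol(feats) == 0L || nrow(unique(feats)) < 2L) return(single)

  set.seed(seed)
  k_range <- k_range[k_range < n]
  sil <- matrix(NA_real_, nrow = n_boot, ncol = length(k_range))
  bs_size <- min(500L, n)
  sil_size <- min(250L, bs_size)
  for (bt in seq_len(n_boot)) {
    idx <- sample.int(n, bs_size, replace = TRUE)
    bs <- feats[idx, , drop = FALSE]
    # silhouette is evaluated on a subsample of each bootstrap; the median
    # over the 30 bootstraps is what drives the choice of K
    sub <- sample.int(bs_size, sil_size)
    d <- stats::dist(bs[sub, , drop = FALSE])
    for (j in seq_along(k_range)) {
      K <- k_range[j]
      if (nrow(unique(bs)) <= K) next
      km <- tryCatch(stats::kmeans(bs, centers = K, nstart = 1L,
                                   iter.max = 25L),
                     error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster[sub])) < 2L) next
      sil[bt, j] <- mean(cluster::silhouette(km$cluster[sub],
                                             d)[, "sil_width"])
    }
  }
  med <- apply(sil, 2L, stats::median, na.rm = TRUE)
  if (all(!is.finite(med))) return(single)
  K <- k_range[which.max(med)]

  km <- tryCatch(stats::kmeans(feats, centers = K, nstart = 5L,
                               iter.max = 50L),
                 error = function(e) NULL)
  if (is.null(km)) return(single)
  assign <- km$cluster
  centers <- km$centers

  # merge clusters below 10% of the largest into their nearest centroid
  repeat {
    sizes <- tabulate(assign, nbins = nrow(centers))
    live <- which(sizes > 0)
    small <- live[sizes[live] < 0.10 * max(sizes)]
    if (length(small) == 0L || length(live) <= 1L) break
    victim <- small[which.min(sizes[small])]
    others <- setdiff(live, victim)
    d2 <- colSums((t(centers[others, , drop = FALSE]) -
                     centers[victim, ])^2)
    target <- others[which.min(d2)]
    assign[assign == victim] <- target
    members <- assign == target
    centers[target, ] <- colMeans(feats[members, , drop = FALSE])
  }
  assign <- match(assign, sort(unique(assign)))
  structure(assign, K = length(unique(assign)))
}

# ---- ZOOPS EM motif finder -------------------------------------------------

# group coded sequences by length into matrices for vectorized EM
group_codes <- function(codes) {
  lens <- lengths(codes)
  lapply(split(seq_along(codes), lens), function(idx) {
    do.call(rbind, codes[idx])
  })
}

# window log-ratio scores for one group: list(fwd, rev), each n x n_off;
# vectorized over offsets with shifted matrix slices
group_scores <- function(gm, logratio) {
  w <- nrow(logratio)
  L <- ncol(gm)
  n_off <- L - w + 1L
  if (n_off < 1L) return(NULL)
  lr_rc <- logratio[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
  fwd <- rev <- matrix(0, nrow = nrow(gm), ncol = n_off)
  for (j in seq_len(w)) {
    sl <- gm[, j:(j + n_off - 1L), drop = FALSE]
    pf <- logratio[j, ][sl]; dim(pf) <- dim(sl)
    pr <- lr_rc[j, ][sl]; dim(pr) <- dim(sl)
    fwd <- fwd + pf
    rev <- rev + pr
  }
  list(fwd = fwd, rev = rev, n_off = n_off)
}

zoops_em_once <- function(groups, width, bg, seed_window, max_iter = 25L,
                          tol = 3e-3) {
  # init PWM from the seed window with heavy smoothing
  mat <- matrix(rep(bg, each = width), nrow = width)
  for (j in seq_len(width))
    mat[j, seed_window[j]] <- mat[j, seed_window[j]] + 1.5
  mat <- mat / rowSums(mat)
  gamma <- 0.5
  ll_old <- -Inf
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    logratio <- log(mat) - rep(log(bg), each = width)
    counts <- matrix(0.25, nrow = width, ncol = 4L)  # pseudocounts
    tot_site <- 0
    n_scored <- 0L
    ll <- 0
    for (gm in groups) {
      gs <- group_scores(gm, logratio)
      if (is.null(gs)) next
      n <- nrow(gm)
      n_scored <- n_scored + n
      pri <- gamma / (2L * gs$n_off)
      ef <- exp(gs$fwd); er <- exp(gs$rev)
      mix <- (1 - gamma) + pri * (rowSums(ef) + rowSums(er))
      ll <- ll + sum(log(mix))
      rf <- pri * ef / mix
      rr <- pri * er / mix
      tot_site <- tot_site + sum(rf) + sum(rr)
      for (j in seq_len(width)) {
        sl <- gm[, j:(j + gs$n_off - 1L), drop = FALSE]
        cf <- rowsum(as.vector(rf), group = as.vector(sl))
        counts[j, as.integer(rownames(cf))] <-
          counts[j, as.integer(rownames(cf))] + cf
        cr <- rowsum(as.vector(rr), group = 5L - as.vector(sl))
        counts[width - j + 1L, as.integer(rownames(cr))] <-
          counts[width - j + 1L, as.integer(rownames(cr))] + cr
      }
    }
    if (n_scored == 0L) stop("no sequence long enough for this width")
    mat <- counts / rowSums(counts)
    gamma <- min(max(tot_site / n_scored, 1e-3), 1 - 1e-3)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mat = mat, gamma = gamma, llr = ll, n_scored = n_scored,
       width = width)
}

#' Discover a PWM in a set of short sequences
#'
#' Internal ZOOPS (zero-or-one occurrence per sequence) EM over both strands:
#' each sequence contains at most one motif instance at a uniform-random
#' offset. Widths 6-12 are tried with several random seed restarts each and
#' the fit with the best log-likelihood ratio against the background model is
#' kept. The fit is flagged low-complexity when its LLR does not clearly
#' exceed an EM fit on base-shuffled copies of the same sequences. On EM
#' failure the fallback is the centre-aligned consensus frequency matrix.
#'
#' @param seqs character vector of sequences (typically 10-15 bp hills).
#' @param widths candidate motif widths.
#' @param nstarts random restarts per width.
#' @param seed random seed.
#' @param name motif name.
#' @param max_seqs cap on sequences used by EM (subsampled, seeded).
#' @return a [pwm()] with `llr` and `low_complexity` filled in.
#' @export
discover_pwm <- function(seqs, widths = 6:12, nstarts = 5L, seed = 1L,
                         name = "motif", max_seqs = 100L) {
  stopifnot(length(seqs) >= 2L)
  set.seed(seed)
  if (length(seqs) > max_seqs) seqs <- sample(seqs, max_seqs)
  codes <- lapply(strsplit(toupper(seqs), "", fixed = TRUE),
                  function(ch) {
                    cd <- match(ch, DNA_BASES)
                    cd[!is.na(cd)]
                  })
  codes <- codes[lengths(codes) >= min(widths)]
  if (length(codes) < 2L) return(consensus_pwm(seqs, name))
  base_tab <- tabulate(unlist(codes), nbins = 4L) + 1
  bg <- base_tab / sum(base_tab)
  widths <- widths[widths <= max(lengths(codes))]

  # widths are compared on a BIC-penalized LLR (3 free parameters per PWM
  # column), since the raw LLR always favours the widest motif
  run_em <- function(cds, n_restarts) {
    best <- NULL
    best_score <- -Inf
    groups <- group_codes(cds)
    for (w in widths) {
      usable <- cds[lengths(cds) >= w]
      if (length(usable) < 2L) next
      for (r in seq_len(n_restarts)) {
        sq <- usable[[sample.int(length(usable), 1L)]]
        o <- sample.int(length(sq) - w + 1L, 1L)
        fit <- tryCatch(zoops_em_once(groups, w, bg, sq[o:(o + w - 1L)]),
                        error = function(e) NULL)
        if (is.null(fit)) next
        score <- fit$llr - 1.5 * w * log(fit$n_scored)
        if (score > best_score) { best <- fit; best_score <- score }
      }
    }
    best
  }

  best <- run_em(codes, nstarts)
  if (is.null(best)) return(consensus_pwm(seqs, name))
  best$mat <- trim_pwm_edges(best$mat)

  # low-complexity check against a base-shuffled null; skipped when the fit
  # is far above anything a shuffled fit can reach (> 1.5 nats/sequence)
  if (best$llr / best$n_scored > 1.5) {
    lowc <- FALSE
  } else {
    shuffled <- lapply(codes, function(cd) sample(cd))
    null_fit <- run_em(shuffled, 2L)
    null_llr <- if (is.null(null_fit)) 0 else max(null_fit$llr, 0)
    lowc <- best$llr < max(2 * null_llr, 0.05 * length(codes))
  }

  pwm(best$mat, name = name, llr = best$llr, low_complexity = lowc)
}

# drop uninformative flanking columns (< min_ic bits), keeping >= min_w
trim_pwm_edges <- function(mat, min_ic = 0.25, min_w = 6L) {
  ic <- 2 + rowSums(mat * log2(pmax(mat, 1e-9)))
  lo <- 1L; hi <- nrow(mat)
  while (hi - lo + 1L > min_w && ic[lo] < min_ic) lo <- lo + 1L
  while (hi - lo + 1L > min_w && ic[hi] < min_ic) hi <- hi - 1L
  mat[lo:hi, , drop = FALSE]
}

#' Discover a PWM with an external MEME binary (optional engine)
#'
#' Writes the sequences to a temporary FASTA, runs
#' `meme -dna -mod zoops -nmotifs <nmotifs>`, and parses the motif with the
#' best E-value from MEME's minimal-format output. The internal EM engine
#' ([discover_pwm()]) is the default throughout the package; this adapter is
#' for users who prefer MEME's model and have it installed.
#'
#' @param seqs character vector of sequences.
#' @param meme_path path to the MEME executable.
#' @param nmotifs motifs to ask MEME for (the first is returned).
#' @param name motif name.
#' @return a [pwm()].
#' @export
discover_pwm_meme <- function(seqs, meme_path = Sys.which("meme"),
                              nmotifs = 3L, name = "motif") {
  if (!nzchar(meme_path) || !file.exists(meme_path))
    stop("MEME executable not found; use discover_pwm() or supply meme_path")
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fa)
  outdir <- tempfile("meme")
  cmd_args <- c(fa, "-dna", "-mod", "zoops", "-nmotifs", nmotifs,
                "-oc", outdir, "-text")
  out <- system2(meme_path, cmd_args, stdout = TRUE, stderr = FALSE)
  txt <- tempfile(fileext = ".txt")
  writeLines(out, txt)
  motifs <- read_meme(txt)
  if (length(motifs) == 0L) stop("MEME returned no motifs")
  m <- motifs[[1L]]
  m$name <- name
  m$source_cluster <- paste("meme:", paste(cmd_args, collapse = " "))
  m
}

# centre-aligned base frequency matrix fallback
consensus_pwm <- function(seqs, name = "motif") {
  w <- min(nchar(seqs))
  trimmed <- vapply(seqs, function(s) {
    off <- (nchar(s) - w) %/% 2L
    substr(s, off + 1L, off + w)
  }, character(1))
  ch <- matrix(unlist(strsplit(trimmed, "", fixed = TRUE)),
               nrow = length(trimmed), byrow = TRUE)
  counts <- vapply(DNA_BASES, function(bs) colSums(ch == bs),
                   numeric(w))
  counts <- counts + 0.25
  pwm(counts / rowSums(counts), name = name, llr = NA_real_)
}

# ---- scoring motifs against k-mer models ----------------------------------

#' Canonical k-mers belonging to a motif
#'
#' A k-mer belongs to a motif when its best gapless alignment against the PWM
#' (log-odds versus a uniform background, either orientation, any offset with
#' the k-mer fully inside the motif) reaches at least `frac` of the maximum
#' log-odds achievable at that offset.
#'
#' @param x a [pwm()].
#' @param space a [kmer_space()].
#' @param frac membership threshold as a fraction of the per-offset maximum
#'   (default 0.7).
#' @return integer vector of canonical k-mer column ids.
#' @export
motif_kmers <- function(x, space, frac = 0.7) {
  LR <- log(pmax(x$matrix, 1e-6) / 0.25)
  w <- nrow(LR)
  member <- logical(space$K)
  for (k in space$k_values) {
    if (w < k) next
    kmers <- all_kmers(k)
    cd <- seq_code_matrix(kmers) + 1L
    cols <- space$lookup[kmers]
    for (mat in list(LR, log(pmax(pwm_revcomp(x$matrix), 1e-6) / 0.25))) {
      for (o in 0:(w - k)) {
        mx <- sum(apply(mat[(o + 1):(o + k), , drop = FALSE], 1L, max))
        if (mx <= 0) next
        sc <- rep(0, nrow(cd))
        for (j in seq_len(k)) sc <- sc + mat[o + j, ][cd[, j]]
        member[cols[sc >= frac * mx]] <- TRUE
      }
    }
  }
  which(member)
}

#' Score a motif against a k-mer weight vector
#'
#' The motif's score under a label or subclass model is the sum of the
#' model's weights over the canonical k-mers belonging to the motif. Positive
#' scores mean the motif is discriminatively enriched for that model;
#' non-positive scores indicate depletion, not necessarily absence.
#'
#' @param x a [pwm()].
#' @param w numeric weight vector of length `space$K`.
#' @param space a [kmer_space()].
#' @param frac membership threshold passed to [motif_kmers()].
#' @param members optional precomputed membership set (column ids).
#' @return scalar score.
#' @export
score_motif <- function(x, w, space, frac = 0.7, members = NULL) {
  if (is.null(members)) members <- motif_kmers(x, space, frac)
  if (length(members) == 0L) {
    warning("motif ", x$name, " has an empty k-mer membership set")
    return(0)
  }
  sum(w[members])
}

#' Discover and score motifs for every label of a trained model
#'
#' Runs the full interpretation pipeline: per-label hill calling, hill
#' clustering, per-cluster PWM discovery, and scoring of every discovered
#' motif against every label and subclass k-mer model.
#'
#' @param model an `md_model` from [train_model()].
#' @param dataset the [labeled_dataset()] scanned for hills.
#' @param hill_threshold hill score threshold (default 0.1).
#' @param kmer_frac motif k-mer membership threshold (default 0.7).
#' @param min_cluster minimum cluster size for PWM discovery (default 10).
#' @param seed random seed.
#' @return object of class `motif_score_table`: list with `motifs` (list of
#'   [pwm()]), `scores` (motif x (labels, subclasses) matrix), `hills`
#'   (per-label hill data.frames).
#' @export
discover_motifs <- function(model, dataset, hill_threshold = 0.1,
                            kmer_frac = 0.7, min_cluster = 10L, seed = 1L) {
  hills <- label_hills(model, dataset, hill_threshold)
  motifs <- list()
  for (p in names(hills)) {
    h <- hills[[p]]
    if (nrow(h) < 2L) next
    cl <- cluster_hills(h, model$space, seed = seed)
    for (cid in sort(unique(cl))) {
      seqs <- h$dna[cl == cid]
      if (length(seqs) < min_cluster) next
      nm <- sprintf("%s_c%d", p, cid)
      m <- discover_pwm(seqs, seed = seed + length(motifs), name = nm)
      m$source_cluster <- sprintf("label=%s;cluster=%d;hills=%d",
                                  p, cid, length(seqs))
      motifs[[nm]] <- m
    }
  }
  score_table(motifs, model, kmer_frac = kmer_frac, hills = hills)
}

#' Score a set of motifs against all label and subclass models
#'
#' @param motifs list of [pwm()].
#' @param model an `md_model` (or a list with `W_lab` rows per label, e.g.
#'   an `mcc_model`, in which case only label columns are produced).
#' @param kmer_frac membership threshold.
#' @param hills optional hill list carried through for reporting.
#' @return a `motif_score_table`.
#' @export
score_table <- function(motifs, model, kmer_frac = 0.7, hills = NULL) {
  space <- model$space
  if (inherits(model, "md_model")) {
    W <- rbind(model$weights$W_lab,
               model$weights$W_sub[, -1L, drop = FALSE])
    labels <- model$labels
    spanned <- lapply(model$structure$C, function(idx)
      model$structure$subclasses[idx])
  } else {
    W <- model$W_lab
    labels <- model$labels
    spanned <- NULL
  }
  scores <- matrix(NA_real_, nrow = length(motifs), ncol = nrow(W),
                   dimnames = list(names(motifs), rownames(W)))
  n_members <- stats::setNames(integer(length(motifs)), names(motifs))
  for (i in seq_along(motifs)) {
    members <- motif_kmers(motifs[[i]], space, kmer_frac)
    n_members[i] <- length(members)
    for (r in seq_len(nrow(W)))
      scores[i, r] <- if (length(members)) sum(W[r, members]) else 0
  }
  structure(list(motifs = motifs, scores = scores, labels = labels,
                 n_members = n_members, spanned = spanned,
                 hills = hills), class = "motif_score_table")
}

#' @export
print.motif_score_table <- function(x, ...) {
  cat("motif_score_table:", length(x$motifs), "motifs\n")
  if (length(x$motifs)) {
    df <- data.frame(consensus = vapply(x$motifs, pwm_consensus,
                                        character(1)),
                     round(x$scores[, x$labels, drop = FALSE], 3))
    print(df)
  }
  invisible(x)
}
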