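# shared fixtures and cached heavy runs

rand_seqs <- function(n, L, seed = 1, probs = rep(0.25, 4)) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
          collapse = ""), character(1))
}

# naive substring k-mer counting oracle
oracle_count <- function(seq, space) {
  out <- stats::setNames(numeric(space$K), space$columns)
  for (k in space$k_values) {
    L <- nchar(seq)
    if (L < k) next
    for (s in 1:(L - k + 1)) {
      km <- substr(seq, s, s + k - 1)
      if (grepl("[^ACGT]", km)) next
      out[canonical_kmer(km)] <- out[canonical_kmer(km)] + 1
    }
  }
  out
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# a small two-subclass dataset with one planted k-mer word per subclass
planted_two_class <- function(n_per = 100, L = 60, seed = 42,
                              words = c("ACGTACGA", "GGCATCCG")) {
  seqs <- rand_seqs(2 * n_per, L, seed = seed)
  labs <- vector("list", 2 * n_per)
  set.seed(seed + 1)
  for (i in seq_len(2 * n_per)) {
    g <- if (i <= n_per) 1L else 2L
    off <- sample.int(L - nchar(words[g]) + 1L, 1L)
    substr(seqs[i], off, off + nchar(words[g]) - 1L) <- words[g]
    labs[[i]] <- c("L1", "L2")[g]
  }
  labeled_dataset(seqs, labs)
}

# cached heavy simulation sweep shared across acceptance tests
.sweep_cache <- new.env(parent = emptyenv())

sweep_runs <- function(overlaps = c(0.5, 0.7, 0.9), seeds = 1:10) {
  key <- paste(c(overlaps, seeds), collapse = "_")
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  res <- list()
  for (ov in overlaps) for (sd in seeds) {
    res[[sprintf("ov%.2f_s%d", ov, sd)]] <-
      suppressWarnings(evaluate_simulation(
        ov, n_sites = 2000L, seed = sd,
        fit_baseline = (ov == 0.9)))
  }
  .sweep_cache[[key]] <- res
  res
}
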