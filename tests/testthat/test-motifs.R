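sp <- kmer_space()

test_that("EM recovers a planted word as the PWM consensus", {
  set.seed(7)
  flank <- function() paste(sample(c("A", "C", "G", "T"), 7,
                                   replace = TRUE), collapse = "")
  seqs <- replicate(50, paste0(flank(), "TAATTA", flank()))
  m <- discover_pwm(seqs, seed = 3)
  expect_s3_class(m, "pwm")
  expect_false(m$low_complexity)
  expect_true(grepl("TAATTA", pwm_consensus(m)) ||
                grepl("TAATTA", revcomp_str(pwm_consensus(m))))
})

test_that("uniform-random clusters are flagged low-complexity", {
  seqs <- rand_seqs(40, 15, seed = 9)
  m <- discover_pwm(seqs, seed = 3)
  expect_true(m$low_complexity)
})

test_that("hill clustering separates two planted motifs", {
  set.seed(4)
  mk <- function(word, n) vapply(seq_len(n), function(i) {
    s <- rand_seqs(1, 15, seed = sample.int(1e6, 1))
    off <- sample.int(15 - nchar(word) + 1, 1)
    substr(s, off, off + nchar(word) - 1) <- word
    s
  }, character(1))
  dna <- c(mk("TTAATTAA", 60), mk("GGCCGGCC", 60))
  hills <- data.frame(seq_index = seq_along(dna),
                      seq_id = as.character(seq_along(dna)),
                      start = 0L, end = 15L, score = 1,
                      source_model = "t", dna = dna,
                      stringsAsFactors = FALSE)
  cl <- cluster_hills(hills, sp, seed = 1)
  expect_equal(attr(cl, "K"), 2L)
  truth <- rep(1:2, each = 60)
  tab <- table(cl, truth)
  purity <- sum(apply(tab, 1, max)) / length(truth)
  expect_gte(purity, 0.9)
})

test_that("rare k-mers are excluded from clustering features and small
           clusters are merged", {
  # fewer than 20 hills -> a single cluster, no K-means at all
  few <- data.frame(dna = rand_seqs(10, 15, seed = 5))
  expect_equal(attr(cluster_hills(few, sp, seed = 1), "K"), 1L)
  # the 5% presence rule: a k-mer present in 4% of hills is not a feature.
  # Checked through the embedding used by cluster_hills.
  dna <- c(rand_seqs(96, 15, seed = 8), rep("GGGGGGGGGGGGGGG", 4))
  feats <- count_kmers(dna, sp)
  keep <- colMeans(feats > 0) >= 0.05
  expect_false(keep[[canonical_kmer("GGGGG")]])  # in exactly 4% of hills
  # merge rule: a cluster below 10% of the largest is absorbed
  set.seed(2)
  big <- vapply(1:100, function(i) {
    s <- rand_seqs(1, 15, seed = 1000 + i)
    substr(s, 4, 11) <- "TTAATTAA"; s
  }, character(1))
  small <- vapply(1:9, function(i) {
    s <- rand_seqs(1, 15, seed = 2000 + i)
    substr(s, 4, 11) <- "GGCCGGCC"; s
  }, character(1))
  hills2 <- data.frame(dna = c(big, small))
  cl2 <- cluster_hills(hills2, sp, seed = 1)
  sizes <- table(cl2)
  expect_true(all(sizes >= 0.10 * max(sizes)))
})

test_that("motif k-mer membership drives additive scoring", {
  m <- bundled_motifs()$GATA
  members <- motif_kmers(m, sp)
  expect_gt(length(members), 0)
  # perfect-consensus k-mers belong to the motif
  expect_true(kmer_column("AGATA", sp) %in% members ||
                kmer_column(canonical_kmer("AGATA"), sp) %in% members)
  w <- numeric(sp$K)
  expect_equal(score_motif(m, w, sp), 0)  # all-zero weights
  set.seed(1)
  w <- rnorm(sp$K)
  s_all <- score_motif(m, w, sp)
  # additivity over a partition of the membership set
  half <- members[seq_len(length(members) %/% 2)]
  rest <- setdiff(members, half)
  expect_equal(s_all, sum(w[half]) + sum(w[rest]))
  # empty membership: a uniform PWM has no k-mers at 70% of max log-odds
  flat <- pwm(matrix(0.25, nrow = 8, ncol = 4), name = "flat")
  expect_warning(s0 <- score_motif(flat, w, sp), "empty")
  expect_equal(s0, 0)
})

test_that("MEME round trip preserves PWMs", {
  path <- tempfile(fileext = ".meme")
  mot <- bundled_motifs()[1:3]
  write_meme(mot, path)
  back <- read_meme(path)
  expect_equal(names(back), names(mot))
  for (nm in names(mot))
    expect_equal(back[[nm]]$matrix, mot[[nm]]$matrix, tolerance = 1e-5)
  # an empty motif set still writes a valid parseable header
  empty_path <- tempfile(fileext = ".meme")
  write_meme(list(), empty_path)
  expect_match(readLines(empty_path)[1], "MEME version")
  expect_length(read_meme(empty_path), 0)
})
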