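test_that("generation is deterministic under a fixed seed", {
  a <- simulate_dataset(sim_config(n_sites = 200, seed = 11))
  b <- simulate_dataset(sim_config(n_sites = 200, seed = 11))
  expect_identical(a$dataset$sequences, b$dataset$sequences)
  expect_identical(a$dataset$label_sets, b$dataset$label_sets)
  expect_identical(a$truth$insertions, b$truth$insertions)
  c <- simulate_dataset(sim_config(n_sites = 200, seed = 12))
  expect_false(identical(a$dataset$sequences, c$dataset$sequences))
})

test_that("realized insertion frequency is 0.7 within 0.02", {
  sim <- simulate_dataset(sim_config(n_sites = 4000, seed = 1))
  st <- sim_realized_stats(sim)
  expect_true(all(abs(st$insertion_freq - 0.7) <= 0.02))
})

test_that("realized overlap tracks the requested rate across the grid", {
  for (ov in c(0.5, 0.7, 0.9, 0.99)) {
    sim <- simulate_dataset(sim_config(n_sites = 2000, overlap = ov,
                                       seed = 3))
    st <- sim_realized_stats(sim)
    expect_lt(abs(st$overlap - ov), 0.02)
  }
})

test_that("a single paired label at overlap 0.99 co-occurs in >=97% of sites", {
  bank <- bundled_motifs()
  cfg <- sim_config(n_sites = 2000, label_sets = list("A", "X"),
                    overlap = 0.99,
                    motif_assignment = list(A = bank$HOMEO, X = bank$GATA),
                    seed = 5)
  sim <- simulate_dataset(cfg)
  a_sites <- vapply(sim$dataset$label_sets, function(l) "A" %in% l,
                    logical(1))
  both <- vapply(sim$dataset$label_sets,
                 function(l) all(c("A", "X") %in% l), logical(1))
  expect_gte(sum(both) / sum(a_sites), 0.97)
})

test_that("zero insertion frequency reproduces the pure background", {
  cfg0 <- sim_config(n_sites = 150, insertion_freq = 0, seed = 7)
  sim0 <- simulate_dataset(cfg0)
  set.seed(7)
  bg <- sample_background(cfg0$background, 150, 150)
  expect_identical(sim0$dataset$sequences, bg)
  expect_equal(nrow(sim0$truth$insertions), 0L)
})

test_that("fitted Markov models reproduce training composition", {
  # training on all-A sequence emits almost exclusively A (add-one
  # smoothing leaves a small escape probability per transition)
  m_a <- fit_markov_background(strrep("A", 4000), order = 2)
  set.seed(1)
  draws <- sample_background(m_a, 20, 100)
  frac_a <- mean(strsplit(paste(draws, collapse = ""), "")[[1]] == "A")
  expect_gte(frac_a, 0.98)
  # order 0 reduces to i.i.d. base sampling with matching base frequencies
  m0 <- fit_markov_background(rand_seqs(5, 400, seed = 2,
                                        probs = c(.4, .1, .1, .4)),
                              order = 0)
  expect_equal(nrow(m0$trans), 1L)
  set.seed(1)
  draw <- sample_background(m0, 50, 200)
  freq <- table(strsplit(paste(draw, collapse = ""), "")[[1]]) /
    (50 * 200)
  expect_lt(abs(freq[["A"]] - m0$trans[1, "A"]), 0.02)
  # 2nd-order: regenerated trinucleotide spectrum matches training closely
  train <- sample_background(default_markov_background(), 2000, 300)
  m2 <- fit_markov_background(train, order = 2)
  regen <- sample_background(m2, 2000, 300)
  expect_lt(max(abs(trinucleotide_spectrum(train) -
                      trinucleotide_spectrum(regen))), 0.005)
})

test_that("the five-label benchmark fixture matches its design", {
  sim <- fig_fixture_5label(seed = 2, n_sites = 9000)
  ds <- sim$dataset
  expect_equal(ds$M, 9000L)
  expect_true(all(lengths(ds$label_sets) >= 1))
  expect_setequal(ds$labels, c("A", "B", "C", "X", "Y"))
  st <- sim_realized_stats(sim)
  expect_true(all(abs(st$insertion_freq - 0.7) <= 0.02))
  # distinct motif per label
  expect_equal(length(unique(sim$truth$motif_of_label)), 5L)
})

test_that("insertions never overlap on a sequence", {
  sim <- simulate_dataset(sim_config(n_sites = 1500, overlap = 0.9,
                                     seed = 4))
  ins <- sim$truth$insertions
  for (i in unique(ins$seq_index)) {
    xi <- ins[ins$seq_index == i, ]
    if (nrow(xi) < 2) next
    xi <- xi[order(xi$start), ]
    expect_true(all(xi$start[-1] >= xi$start[-nrow(xi)] +
                      xi$width[-nrow(xi)]))
  }
  # inserted instances are reflected in the emitted sequences
  for (r in sample(nrow(ins), 20)) {
    seq_i <- sim$dataset$sequences[ins$seq_index[r]]
    inst <- substr(seq_i, ins$start[r] + 1, ins$start[r] + ins$width[r])
    expect_equal(nchar(inst), ins$width[r])
  }
})
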