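sp <- kmer_space()

write_toy_genome <- function(path) {
  set.seed(77)
  chr1 <- rand_seqs(1, 4000, seed = 77)
  chr2 <- rand_seqs(1, 2500, seed = 78)
  writeLines(c(">chr1 test assembly", chr1, ">chr2", chr2), path)
  list(chr1 = chr1, chr2 = chr2)
}

test_that("window extraction matches a substring oracle on a toy genome", {
  gpath <- tempfile(fileext = ".fa")
  gen <- write_toy_genome(gpath)
  set.seed(5)
  n <- 100
  chroms <- sample(c("chr1", "chr2"), n, replace = TRUE)
  mids <- ifelse(chroms == "chr1", sample(200:3800, n, TRUE),
                 sample(200:2300, n, TRUE))
  tab <- data.frame(chrom = chroms, start = mids,
                    labels = sample(c("a", "b", "a;b"), n, TRUE))
  spath <- tempfile(fileext = ".tsv")
  write.table(tab, spath, sep = "\t", row.names = FALSE, quote = FALSE)
  ds <- load_sites(spath, gpath, window = 150)
  expect_equal(ds$M, n)
  for (i in sample(n, 25)) {
    expected <- substr(gen[[chroms[i]]], mids[i] - 75 + 1, mids[i] + 75)
    expect_equal(ds$sequences[i], expected)
  }
  expect_equal(unique(nchar(ds$sequences)), 150L)
})

test_that("site loading computes subclasses and balancing weights", {
  gpath <- tempfile(fileext = ".fa")
  write_toy_genome(gpath)
  tab <- data.frame(chrom = "chr1", start = seq(300, 3600, length.out = 30),
                    labels = c(rep("big", 20), rep("small", 10)))
  spath <- tempfile(fileext = ".tsv")
  write.table(tab, spath, sep = "\t", row.names = FALSE, quote = FALSE)
  ds <- load_sites(spath, gpath)
  expect_equal(sort(unique(ds$b)), c(1, 2))
})

test_that("out-of-bounds windows are dropped and errors are informative", {
  gpath <- tempfile(fileext = ".fa")
  write_toy_genome(gpath)
  tab <- data.frame(chrom = c("chr1", "chr1"), start = c(10, 1000),
                    labels = c("x", "x"))
  spath <- tempfile(fileext = ".tsv")
  write.table(tab, spath, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_message(ds <- load_sites(spath, gpath), "dropped 1")
  expect_equal(ds$M, 1L)
  # missing chromosome names the culprit
  tab2 <- data.frame(chrom = "chrZ", start = 500, labels = "x")
  write.table(tab2, spath, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_sites(spath, gpath), "chrZ")
  # empty label field reports the line number
  tab3 <- data.frame(chrom = c("chr1", "chr1"), start = c(500, 600),
                     labels = c("x", ""))
  write.table(tab3, spath, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_sites(spath, gpath), "line 3")
})

test_that("labeled FASTA input carries labels after the pipe", {
  fpath <- tempfile(fileext = ".fa")
  writeLines(c(">s1|early;proximal", strrep("ACGT", 10),
               ">s2|late", strrep("TTAA", 10)), fpath)
  ds <- load_labeled_fasta(fpath)
  expect_equal(ds$M, 2L)
  expect_equal(ds$label_sets[[1]], c("early", "proximal"))
  expect_equal(ds$ids, c("s1", "s2"))
})

test_that("written outputs round-trip and have the documented shapes", {
  ds <- planted_two_class(n_per = 25, L = 40, seed = 19)
  fm <- feature_matrix(ds$sequences, sp)
  m <- suppressWarnings(
    train_model(ds, fm, train_config(sweeps = 1, max_admm_iters = 5)))
  outdir <- tempfile()
  tbl <- suppressWarnings(discover_motifs(m, ds, hill_threshold = 0.05,
                                          seed = 1))
  files <- write_outputs(m, tbl, outdir)
  expect_true(all(file.exists(files)))
  # label weight TSV: 648 k-mer rows, one column per label
  W <- read_weight_table(file.path(outdir, "label_weights.tsv"))
  expect_equal(ncol(W), 648L)
  expect_equal(nrow(W), length(m$labels))
  expect_equal(unname(W), unname(m$weights$W_lab), tolerance = 1e-9)
  Ws <- read_weight_table(file.path(outdir, "subclass_weights.tsv"))
  expect_equal(unname(Ws), unname(m$weights$W_sub), tolerance = 1e-9)
  # run log is valid JSON with the config
  log <- jsonlite::read_json(file.path(outdir, "run_log.json"))
  expect_equal(log$config$alpha, 1.9)
  # training log: one row per sweep with objective and residuals
  tl <- read.delim(file.path(outdir, "training_log.tsv"))
  expect_equal(nrow(tl), length(m$objective))
  expect_named(tl, c("sweep", "objective", "admm_iters",
                     "primal_residual", "dual_residual"))
})

test_that("scores clamp to the +/-0.4 plotting saturation", {
  expect_equal(saturate_scores(0.55), 0.4)
  expect_equal(saturate_scores(-1.2), -0.4)
  expect_equal(saturate_scores(c(0.1, -0.39)), c(0.1, -0.39))
})

test_that("hills export as BED in sequence and genome coordinates", {
  h <- data.frame(seq_index = c(1L, 2L), seq_id = c("s1", "s2"),
                  start = c(5L, 20L), end = c(20L, 35L),
                  score = c(0.5, 0.3), source_model = "A",
                  dna = c("x", "y"), stringsAsFactors = FALSE)
  bpath <- tempfile(fileext = ".bed")
  write_hills_bed(h, bpath)
  bed <- read.delim(bpath, header = FALSE)
  expect_equal(bed$V2, c(5L, 20L))
  sites <- data.frame(chrom = c("chr1", "chr2"), start = c(100L, 1000L),
                      end = c(250L, 1150L))
  write_hills_bed(h, bpath, sites = sites)
  bed2 <- read.delim(bpath, header = FALSE)
  expect_equal(bed2$V1, c("chr1", "chr2"))
  expect_equal(bed2$V2, c(105L, 1020L))
})
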