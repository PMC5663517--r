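# Canonical k-mer feature space and standardized count matrices.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character k-mers
#'
#' @param x character vector of DNA strings over A/C/G/T.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Canonical form of a k-mer
#'
#' A k-mer and its reverse complement are collapsed onto a single
#' representative: the lexicographically smaller of the pair. This makes all
#' downstream features strand-symmetric.
#'
#' @param kmer character vector of k-mers over A/C/G/T.
#' @return character vector of canonical k-mers.
#' @export
#' @examples
#' canonical_kmer(c("AAAA", "TTTT", "ACGT"))
canonical_kmer <- function(kmer) {
  pmin(kmer, revcomp_chr(kmer))
}

all_kmers <- function(k) {
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' Build the canonical k-mer feature space
#'
#' Enumerates all k-mers for each requested k, collapses reverse-complement
#' pairs onto one column, and records lookup tables used for counting and
#' model scanning. With the default `k_values = c(4, 5)` the space has
#' 136 + 512 = 648 columns.
#'
#' @param k_values integer vector of k-mer lengths (default `c(4, 5)`).
#' @return an object of class `kmer_space` with elements `k_values`,
#'   `columns` (canonical k-mer names, in column order), `K` (total number of
#'   features), `lookup` (named integer vector mapping every k-mer to its
#'   column) and `code_lookup` (per-k integer vectors mapping the base-4
#'   encoding of a k-mer to its column, used by the fast scanner).
#' @export
kmer_space <- function(k_values = c(4L, 5L)) {
  stopifnot(all(k_values >= 1L))
  k_values <- as.integer(sort(unique(k_values)))
  columns <- character(0)
  lookup <- integer(0)
  code_lookup <- list()
  for (k in k_values) {
    kmers <- all_kmers(k)
    canon <- canonical_kmer(kmers)
    cols_k <- sort(unique(canon))
    ids <- length(columns) + match(canon, cols_k)
    names(ids) <- kmers
    columns <- c(columns, cols_k)
    lookup <- c(lookup, ids)
    code_lookup[[as.character(k)]] <- unname(ids)
  }
  structure(list(k_values = k_values, columns = columns,
                 K = length(columns), lookup = lookup,
                 code_lookup = code_lookup),
            class = "kmer_space")
}

#' @export
print.kmer_space <- function(x, ...) {
  cat("kmer_space: k =", paste(x$k_values, collapse = ","),
      "| features:", x$K, "\n")
  invisible(x)
}

#' Column index of a k-mer in a feature space
#'
#' @param kmer character vector of k-mers.
#' @param space a [kmer_space()].
#' @return integer column ids; `NA` for k-mers containing non-ACGT characters
#'   or of a length not in the space.
#' @export
kmer_column <- function(kmer, space) {
  unname(space$lookup[kmer])
}

#' Encode equal-length sequences as a base code matrix
#'
#' @param seqs character vector of equal-length DNA strings.
#' @return integer matrix (sequences x positions) with A,C,G,T -> 0..3 and
#'   any other character -> NA.
#' @keywords internal
seq_code_matrix <- function(seqs) {
  lens <- nchar(seqs)
  stopifnot(length(unique(lens)) == 1L)
  L <- lens[1]
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
               nrow = length(seqs), ncol = L, byrow = TRUE)
  code <- match(ch, DNA_BASES) - 1L
  dim(code) <- dim(ch)
  code
}

# base-4 rolling encoding of every k-mer start; NA where the window holds a
# non-ACGT base. Returns (sequences x (L-k+1)) matrix of codes in 0..4^k-1.
kmer_code_windows <- function(code, k) {
  L <- ncol(code)
  n_win <- L - k + 1L
  if (n_win < 1L) return(matrix(integer(0), nrow = nrow(code), ncol = 0L))
  idx <- matrix(0, nrow = nrow(code), ncol = n_win)
  for (j in seq_len(k)) {
    idx <- idx + code[, j:(j + n_win - 1L), drop = FALSE] * 4^(k - j)
  }
  idx
}

#' Count canonical k-mers in a set of sequences
#'
#' Each occurrence, read left to right, increments its canonical column once;
#' windows containing N (or any non-ACGT character) are skipped.
#'
#' @param seqs character vector of DNA sequences (not necessarily equal
#'   length).
#' @param space a [kmer_space()].
#' @return integer matrix (sequences x `space$K`) of raw counts, with
#'   canonical k-mers as column names.
#' @export
count_kmers <- function(seqs, space) {
  sset <- Biostrings::DNAStringSet(seqs)
  out <- matrix(0L, nrow = length(seqs), ncol = space$K,
                dimnames = list(NULL, space$columns))
  for (k in space$k_values) {
    raw <- Biostrings::oligonucleotideFrequency(sset, width = k)
    grp <- space$lookup[colnames(raw)]
    collapsed <- t(rowsum(t(raw), group = grp))
    out[, as.integer(colnames(collapsed))] <-
      out[, as.integer(colnames(collapsed)), drop = FALSE] + collapsed
  }
  out
}

#' Build a standardized feature matrix
#'
#' Counts canonical k-mers and z-scores each column over the training set.
#' Columns that are constant in training are recorded with sd 1 so they map
#' to all-zero features. The centering/scaling parameters are retained so
#' held-out or user sequences can be featurized on the training scale.
#'
#' @param seqs character vector of DNA sequences.
#' @param space a [kmer_space()].
#' @return object of class `feature_matrix`: list with `X` (standardized
#'   M x K matrix), `col_means`, `col_sds`, `space`.
#' @export
feature_matrix <- function(seqs, space = kmer_space()) {
  counts <- count_kmers(seqs, space)
  mu <- colMeans(counts)
  sds <- apply(counts, 2L, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  X <- sweep(sweep(counts, 2L, mu, "-"), 2L, sds, "/")
  structure(list(X = X, col_means = mu, col_sds = sds, space = space),
            class = "feature_matrix")
}

#' Featurize new sequences with frozen standardization parameters
#'
#' @param fm a [feature_matrix()] fitted on training sequences.
#' @param seqs character vector of new sequences.
#' @return standardized numeric matrix on the training scale.
#' @export
featurize <- function(fm, seqs) {
  stopifnot(inherits(fm, "feature_matrix"))
  counts <- count_kmers(seqs, fm$space)
  sweep(sweep(counts, 2L, fm$col_means, "-"), 2L, fm$col_sds, "/")
}
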