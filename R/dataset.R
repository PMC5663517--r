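# Labeled sequence datasets and the label/subclass bookkeeping used by the
# hierarchical classifier.

subclass_key <- function(labels) {
  vapply(labels, function(l) paste(sort(unique(l)), collapse = ";"),
         character(1))
}

#' Construct a labeled dataset
#'
#' Sites annotated with one or more labels are grouped into subclasses, the
#' distinct observed label combinations. Subclasses are the classes of the
#' underlying multinomial model; per-site balancing weights are
#' `|n_max| / |n|`, the size of the largest subclass over the size of the
#' site's own subclass, so that small subclasses are up-weighted.
#'
#' @param sequences character vector of equal-length DNA sequences.
#' @param label_sets list of character vectors, one non-empty set of labels
#'   per sequence.
#' @param ids optional sequence identifiers.
#' @return object of class `labeled_dataset` with elements `sequences`,
#'   `label_sets`, `ids`, `labels` (sorted unique labels), `subclasses`
#'   (distinct label combinations, ";"-joined sorted labels), `subclass_of`
#'   (integer index per sequence), `y` (M x |T| binary membership matrix),
#'   `b` (balancing weights) and `M`.
#' @export
labeled_dataset <- function(sequences, label_sets, ids = NULL) {
  M <- length(sequences)
  stopifnot(M >= 1L, length(label_sets) == M)
  if (any(lengths(label_sets) == 0L))
    stop("every sequence needs at least one label")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("sequences must all have the same length")
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(M))

  keys <- subclass_key(label_sets)
  subclasses <- sort(unique(keys))
  subclass_of <- match(keys, subclasses)
  sizes <- tabulate(subclass_of, nbins = length(subclasses))
  b <- max(sizes) / sizes[subclass_of]
  y <- matrix(0L, nrow = M, ncol = length(subclasses),
              dimnames = list(NULL, subclasses))
  y[cbind(seq_len(M), subclass_of)] <- 1L

  structure(list(sequences = sequences, label_sets = label_sets, ids = ids,
                 labels = sort(unique(unlist(label_sets))),
                 subclasses = subclasses, subclass_of = subclass_of,
                 subclass_sizes = sizes, y = y, b = b, M = M),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", x$M, "sequences of", nchar(x$sequences[1]), "bp\n")
  cat("  labels:    ", paste(x$labels, collapse = ", "), "\n")
  cat("  subclasses:", paste(sprintf("%s (%d)", x$subclasses,
                                     x$subclass_sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Label/subclass spanning structure
#'
#' For each subclass n, `Pi[[n]]` is the set of labels spanning it; for each
#' label p, `C[[p]]` is the set of subclasses it spans. The two views are
#' transposes of one another.
#'
#' @param dataset a [labeled_dataset()], or a character vector of subclass
#'   keys (";"-joined labels).
#' @return object of class `label_structure` with `labels`, `subclasses`,
#'   `Pi` (list over subclasses of label indices) and `C` (list over labels
#'   of subclass indices).
#' @export
label_structure <- function(dataset) {
  subclasses <- if (inherits(dataset, "labeled_dataset"))
    dataset$subclasses else as.character(dataset)
  Pi_names <- strsplit(subclasses, ";", fixed = TRUE)
  labels <- sort(unique(unlist(Pi_names)))
  Pi <- lapply(Pi_names, function(p) match(p, labels))
  C <- lapply(seq_along(labels), function(p)
    which(vapply(Pi, function(s) p %in% s, logical(1))))
  names(Pi) <- subclasses
  names(C) <- labels
  if (any(lengths(C) == 0L)) stop("label spanning no subclass")
  structure(list(labels = labels, subclasses = subclasses, Pi = Pi, C = C),
            class = "label_structure")
}
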