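# Multinomial model over subclasses with fused-L1 ties to label models.
#
# The trained model holds one weight vector per subclass (k-mer weights plus
# an intercept) and one weight vector per label (k-mer weights only). The
# training objective is a balanced multinomial negative log-likelihood over
# subclasses plus an L1 penalty on the difference between each subclass
# vector and every label vector spanning it:
#
#   - sum_i sum_n b_i y_in log softmax_n(w_n . x_i)
#     + lambda sum_n sum_{p in Pi(n)} || w_n - w_p ||_1
#
# Intercepts are excluded from the penalty: labels are scored on k-mer
# content only.

#' Construct a weight set
#'
#' @param W_sub numeric matrix, one row per subclass, columns =
#'   `(Intercept, k-mer features)`.
#' @param W_lab numeric matrix, one row per label, columns = k-mer features.
#' @param structure the [label_structure()] the weights refer to.
#' @param space the [kmer_space()] of the features.
#' @return object of class `weight_set`.
#' @export
weight_set <- function(W_sub, W_lab, structure, space) {
  stopifnot(nrow(W_sub) == length(structure$subclasses),
            nrow(W_lab) == length(structure$labels),
            ncol(W_sub) == space$K + 1L, ncol(W_lab) == space$K)
  rownames(W_sub) <- structure$subclasses
  rownames(W_lab) <- structure$labels
  colnames(W_sub) <- c("(Intercept)", space$columns)
  colnames(W_lab) <- space$columns
  structure(list(W_sub = W_sub, W_lab = W_lab, structure = structure,
                 space = space), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight_set:", nrow(x$W_sub), "subclass and", nrow(x$W_lab),
      "label k-mer models over", x$space$K, "features\n")
  invisible(x)
}

#' Subclass posterior probabilities
#'
#' Softmax over subclass linear scores, computed with max-subtraction for
#' overflow safety.
#'
#' @param X standardized feature matrix (rows = sequences), without an
#'   intercept column.
#' @param W_sub subclass weight matrix (rows = subclasses, first column the
#'   intercept), or a [weight_set()].
#' @return matrix (sequences x subclasses) of posteriors; rows sum to 1.
#' @export
subclass_posteriors <- function(X, W_sub) {
  if (inherits(W_sub, "weight_set")) W_sub <- W_sub$W_sub
  scores <- X %*% t(W_sub[, -1L, drop = FALSE])
  scores <- sweep(scores, 2L, W_sub[, 1L], "+")
  scores <- scores - apply(scores, 1L, max)
  e <- exp(scores)
  p <- e / rowSums(e)
  colnames(p) <- rownames(W_sub)
  p
}

# balanced multinomial negative log-likelihood
weighted_nll <- function(X, y, b, W_sub) {
  p <- subclass_posteriors(X, W_sub)
  cls <- max.col(y, ties.method = "first")
  -sum(b * log(pmax(p[cbind(seq_len(nrow(X)), cls)], 1e-300)))
}

fused_penalty <- function(W_sub, W_lab, structure) {
  tot <- 0
  for (n in seq_along(structure$Pi)) {
    wn <- W_sub[n, -1L]
    for (p in structure$Pi[[n]]) tot <- tot + sum(abs(wn - W_lab[p, ]))
  }
  tot
}

#' Training objective
#'
#' Balanced multinomial negative log-likelihood plus the fused L1 penalty
#' tying each subclass model to the label models spanning it. At all-zero
#' weights this equals `sum(b) * log(|T|)`.
#'
#' @param ws a [weight_set()].
#' @param X standardized feature matrix.
#' @param y binary subclass membership matrix.
#' @param b per-sequence balancing weights.
#' @param lambda fusion penalty coefficient (>= 0).
#' @return scalar objective value.
#' @export
model_objective <- function(ws, X, y, b, lambda) {
  weighted_nll(X, y, b, ws$W_sub) +
    lambda * fused_penalty(ws$W_sub, ws$W_lab, ws$structure)
}
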