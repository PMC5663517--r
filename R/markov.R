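# Markov background models for synthetic regulatory sequence.

markov_contexts <- function(order) {
  if (order == 0L) return("")
  apply(do.call(expand.grid,
                c(rep(list(DNA_BASES), order), KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE))[, rev(seq_len(order)),
                                             drop = FALSE],
        1L, paste, collapse = "")
}

new_markov_model <- function(trans, init, order) {
  stopifnot(nrow(trans) == 4^order, ncol(trans) == 4L,
            length(init) == 4^order,
            all(abs(rowSums(trans) - 1) < 1e-9))
  rownames(trans) <- markov_contexts(order)
  colnames(trans) <- DNA_BASES
  structure(list(order = as.integer(order), trans = trans,
                 init = init / sum(init)), class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("markov_model of order", x$order, "\n")
  invisible(x)
}

#' Fit a Markov background model
#'
#' Maximum-likelihood transition probabilities of the given order with
#' add-one smoothing; the initial context distribution is the observed
#' context frequency.
#'
#' @param seqs character vector of training sequences (A/C/G/T; other
#'   characters break the chain at that point).
#' @param order Markov order (>= 0); default 2.
#' @return object of class `markov_model` with `order`, `trans`
#'   (4^order x 4 transition matrix) and `init` (context distribution).
#' @export
fit_markov_background <- function(seqs, order = 2L) {
  stopifnot(order >= 0L)
  n_ctx <- 4L^order
  counts <- matrix(1, nrow = n_ctx, ncol = 4L)  # add-one smoothing
  ctx_counts <- rep(1, n_ctx)
  for (s in seqs) {
    cd <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES) - 1L
    L <- length(cd)
    if (L <= order) next
    if (order == 0L) {
      ok <- !is.na(cd)
      counts[1L, ] <- counts[1L, ] + tabulate(cd[ok] + 1L, nbins = 4L)
      ctx_counts[1L] <- ctx_counts[1L] + sum(ok)
      next
    }
    ctx <- 0L
    for (j in seq_len(order)) ctx <- ctx * 4L + cd[j:(L - order + j - 1L)]
    nxt <- cd[(order + 1L):L]
    ok <- !is.na(ctx) & !is.na(nxt)
    if (!any(ok)) next
    tab <- table(factor(ctx[ok] + 1L, levels = seq_len(n_ctx)),
                 factor(nxt[ok] + 1L, levels = 1:4))
    counts <- counts + unclass(tab)
    ctx_counts <- ctx_counts + tabulate(ctx[ok] + 1L, nbins = n_ctx)
  }
  new_markov_model(counts / rowSums(counts), ctx_counts, order)
}

#' Default vertebrate-like background model
#'
#' A synthetic 2nd-order model constructed in closed form to emulate typical
#' vertebrate genome composition: ~41% GC, strong CpG dinucleotide depletion,
#' and enrichment of poly-A/poly-T tracts. It is a stand-in built by the
#' package, not a model fit to a real genome; users analysing real data can
#' fit their own with [fit_markov_background()].
#'
#' @return a `markov_model` of order 2.
#' @export
default_markov_background <- function() {
  base_p <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)
  trans <- matrix(0, nrow = 16L, ncol = 4L)
  for (b1 in 0:3) for (b2 in 0:3) {
    row <- base_p
    if (DNA_BASES[b2 + 1L] == "C") row["G"] <- row["G"] * 0.22  # CpG
    for (nb in DNA_BASES) {
      if (DNA_BASES[b2 + 1L] == nb && nb %in% c("A", "T")) {
        row[nb] <- row[nb] * 1.25
        if (DNA_BASES[b1 + 1L] == nb) row[nb] <- row[nb] * 1.5  # tracts
      }
    }
    trans[b1 * 4L + b2 + 1L, ] <- row / sum(row)
  }
  # stationary distribution over contexts: power iteration on the pair chain
  init <- rep(1 / 16, 16L)
  for (it in 1:200) {
    nxt <- rep(0, 16L)
    for (ctx in 1:16) {
      b2 <- (ctx - 1L) %% 4L
      for (nb in 0:3)
        nxt[b2 * 4L + nb + 1L] <- nxt[b2 * 4L + nb + 1L] +
          init[ctx] * trans[ctx, nb + 1L]
    }
    if (max(abs(nxt - init)) < 1e-12) { init <- nxt; break }
    init <- nxt
  }
  new_markov_model(trans, init, 2L)
}

#' Sample sequences from a Markov background model
#'
#' Generation is vectorized across sequences: at each position every
#' sequence's next base is drawn from its current context's transition row.
#'
#' @param model a `markov_model`.
#' @param n number of sequences.
#' @param len sequence length.
#' @return character vector of `n` sequences of length `len`.
#' @export
sample_background <- function(model, n, len) {
  o <- model$order
  stopifnot(len >= max(o, 1L))
  cum <- t(apply(model$trans, 1L, cumsum))[, 1:3, drop = FALSE]
  code <- matrix(0L, nrow = n, ncol = len)
  if (o == 0L) {
    ctx <- rep(1L, n)
    start <- 1L
  } else {
    ctx <- sample.int(4L^o, n, replace = TRUE, prob = model$init)
    c0 <- ctx - 1L
    for (j in o:1) { code[, j] <- c0 %% 4L; c0 <- c0 %/% 4L }
    start <- o + 1L
  }
  if (start <= len) for (t in start:len) {
    u <- stats::runif(n)
    nb <- 1L + (u > cum[ctx, 1L]) + (u > cum[ctx, 2L]) + (u > cum[ctx, 3L])
    code[, t] <- nb - 1L
    ctx <- if (o == 0L) ctx else ((ctx - 1L) %% 4L^(o - 1L)) * 4L + nb
  }
  do.call(paste0, lapply(seq_len(len),
                         function(j) DNA_BASES[code[, j] + 1L]))
}
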