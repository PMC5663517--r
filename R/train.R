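# Training: relaxed ADMM for the fused-L1 multinomial model, the closed-form
# median update for label weights, and lambda selection by cross-validation.

#' Training configuration
#'
#' @param lambda fusion penalty coefficient, expressed per unit of total
#'   sequence weight (the absolute coefficient in the objective is
#'   `lambda * sum(b)`); `NULL` selects it by 3-fold cross-validation over
#'   `lambda_grid`.
#' @param rho ADMM penalty parameter, on the same per-unit-weight scale.
#' @param alpha over-relaxation parameter in (0, 2]; default 1.9.
#' @param eps_abs,eps_rel absolute and relative stopping tolerances.
#' @param max_admm_iters cap on ADMM iterations per label-update sweep.
#' @param sweeps number of outer label-update sweeps (the sweep loop also
#'   stops early when label weights change by less than `sweep_tol` in
#'   max-norm).
#' @param sweep_tol early-stopping tolerance for the outer sweeps.
#' @param lbfgs_maxit L-BFGS iterations per w-step (warm-started).
#' @param threads number of workers for the distributed w-step: the M
#'   training examples are split across workers, each evaluates its share of
#'   the likelihood and gradient, and the pooled sums drive the joint
#'   quasi-Newton step (the z/u updates act as pooling steps). The pooled
#'   path is numerically equivalent to `threads = 1`.
#' @param snap_frac post-fit fusion polish: subclass weight coordinates
#'   within `snap_frac` of the soft-thresholding threshold (2*lambda/rho) of
#'   their label weight are snapped onto it exactly, recovering the fusion
#'   pattern of the exact optimum that finite ADMM iterations only approach.
#'   0 disables polishing.
#' @param lambda_grid grid used when `lambda` is `NULL`.
#' @param seed seed for stochastic elements (CV folds).
#' @return a `train_config` list.
#' @export
train_config <- function(lambda = 0.005, rho = 1.0, alpha = 1.9,
                         eps_abs = 1e-5, eps_rel = 1e-2,
                         max_admm_iters = 500L, sweeps = 5L,
                         sweep_tol = 1e-4, lbfgs_maxit = 30L, threads = 1L,
                         lambda_grid = c(0.01, 0.05, 0.1, 0.5, 1),
                         snap_frac = 0.15, seed = 1L) {
  stopifnot(is.null(lambda) || lambda >= 0, rho > 0,
            alpha > 0, alpha <= 2, eps_abs > 0, eps_rel >= 0)
  structure(list(lambda = lambda, rho = rho, alpha = alpha,
                 eps_abs = eps_abs, eps_rel = eps_rel,
                 max_admm_iters = as.integer(max_admm_iters),
                 sweeps = as.integer(sweeps), sweep_tol = sweep_tol,
                 lbfgs_maxit = as.integer(lbfgs_maxit),
                 threads = as.integer(threads),
                 lambda_grid = lambda_grid, snap_frac = snap_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Soft-thresholding (shrinkage) operator
#'
#' Element-wise: values with magnitude at most `k` are zeroed, larger values
#' are shrunk toward zero by `k`.
#'
#' @param a numeric vector or matrix.
#' @param k non-negative threshold.
#' @return object of the same shape as `a`.
#' @export
#' @examples
#' shrinkage(c(1.2, -0.2, -1.0), 0.5)  # 0.7, 0, -0.5
shrinkage <- function(a, k) {
  stopifnot(k >= 0)
  sign(a) * pmax(abs(a) - k, 0)
}

#' Median update for label weight vectors
#'
#' Each coordinate of a label's weight vector is the median of that
#' coordinate over the subclasses the label spans (for an even number of
#' subclasses, the mean of the two middle values). A label spanning a single
#' subclass copies that subclass's k-mer weights exactly.
#'
#' @param W_sub subclass weight matrix (first column intercept).
#' @param structure a [label_structure()].
#' @return matrix (labels x k-mer features) of label weights.
#' @export
update_label_weights <- function(W_sub, structure) {
  Wk <- W_sub[, -1L, drop = FALSE]
  out <- matrix(0, nrow = length(structure$labels), ncol = ncol(Wk),
                dimnames = list(structure$labels, colnames(Wk)))
  for (p in seq_along(structure$C)) {
    rows <- structure$C[[p]]
    out[p, ] <- if (length(rows) == 1L) Wk[rows, ]
    else apply(Wk[rows, , drop = FALSE], 2L, stats::median)
  }
  out
}

# NLL and gradient of the w-step subproblem on a row subset.
# par: vec of W_sub (|T| x (K+1)); A = Z + W_lab[pair_p,] - U is the prox
# target so the quadratic term is (rho/2) sum_np ||w_n - A_np||^2.
# chunks: list of row-index vectors; the likelihood and its gradient are
# evaluated per chunk and pooled by summation, so the multi-worker path is
# an exact data-parallel evaluation of the same w-step. The proximal target
# A changes across ADMM iterations and is updated through `set_A`, so the
# (possibly large) data shares are materialized only once.
make_wstep_fns <- function(X1, cls, b, pair_n, A, rho, nT,
                           chunks = list(seq_along(cls))) {
  K1 <- ncol(X1)
  whole <- length(chunks) == 1L &&
    identical(chunks[[1]], seq_along(cls))
  shares <- if (whole) {
    list(list(X = X1, b = b, ii = cbind(seq_along(cls), cls)))
  } else {
    lapply(chunks, function(rows) list(
      X = X1[rows, , drop = FALSE], b = b[rows],
      ii = cbind(seq_along(rows), cls[rows])))
  }
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  cache$A <- A
  compute <- function(par) {
    if (identical(cache$par, par)) return()
    W <- matrix(par, nrow = nT)
    nll <- 0
    G <- matrix(0, nrow = nT, ncol = K1)
    for (sh in shares) {
      S <- sh$X %*% t(W)
      S <- S - do.call(pmax, as.data.frame(S))
      E <- exp(S)
      rs <- rowSums(E)
      nll <- nll - sum(sh$b * (S[sh$ii] - log(rs)))
      R <- E / rs
      R[sh$ii] <- R[sh$ii] - 1
      G <- G + crossprod(R * sh$b, sh$X)
    }
    D <- W[pair_n, -1L, drop = FALSE] - cache$A
    cache$fval <- nll + 0.5 * rho * sum(D * D)
    dsum <- rowsum(D, group = pair_n)
    G[as.integer(rownames(dsum)), -1L] <-
      G[as.integer(rownames(dsum)), -1L, drop = FALSE] + rho * dsum
    cache$grad <- as.vector(G)
    cache$par <- par
  }
  list(fn = function(par) { compute(par); cache$fval },
       gr = function(par) { compute(par); cache$grad },
       set_A = function(A_new) { cache$A <- A_new; cache$par <- NULL })
}

# one ADMM solve of the w_n subproblem at fixed label weights.
# Returns updated W_sub plus Z/U state and residual traces.
admm_inner <- function(X1, cls, b, structure, W_sub, W_lab, lam_abs, rho_abs,
                       config) {
  nT <- length(structure$subclasses)
  K <- ncol(W_lab)
  pair_n <- rep(seq_along(structure$Pi), lengths(structure$Pi))
  pair_p <- unlist(structure$Pi, use.names = FALSE)
  Wp_mat <- W_lab[pair_p, , drop = FALSE]
  Z <- W_sub[pair_n, -1L, drop = FALSE] - Wp_mat
  U <- matrix(0, nrow = length(pair_n), ncol = K)
  thr <- if (rho_abs > 0) 2 * lam_abs / rho_abs else 0
  kdim <- K
  primal <- dual <- numeric(0)

  chunks <- if (config$threads > 1L)
    split(seq_along(cls), rep_len(seq_len(config$threads), length(cls)))
  else list(seq_along(cls))

  par <- as.vector(W_sub)
  fns <- make_wstep_fns(X1, cls, b, pair_n,
                        matrix(0, length(pair_n), K), rho_abs, nT,
                        chunks = chunks)
  for (t in seq_len(config$max_admm_iters)) {
    fns$set_A(Z + Wp_mat - U)
    # the first w-step does the heavy lifting; later ones are warm-started
    # corrections and need far fewer quasi-Newton iterations
    maxit_t <- if (t == 1L) config$lbfgs_maxit
    else max(8L, config$lbfgs_maxit %/% 4L)
    opt <- stats::optim(par, fns$fn, fns$gr, method = "L-BFGS-B",
                        control = list(maxit = maxit_t))
    par <- opt$par
    W <- matrix(par, nrow = nT)
    Wn_pairs <- W[pair_n, -1L, drop = FALSE]

    Z_old <- Z
    # over-relaxation: w_n is blended toward its consensus value z + w_p
    W_hat <- config$alpha * Wn_pairs +
      (1 - config$alpha) * (Z_old + Wp_mat)
    Z <- shrinkage(W_hat - Wp_mat + U, thr)
    U <- U + W_hat - Z - Wp_mat

    # residual norms use the user-scale rho so tolerances are in weight units
    r_norm <- sqrt(sum((Wn_pairs - Z - Wp_mat)^2))
    s_norm <- sqrt(sum((config$rho * (Z - Z_old))^2))
    primal <- c(primal, r_norm)
    dual <- c(dual, s_norm)
    eps_pri <- config$eps_abs * kdim +
      config$eps_rel * max(sqrt(sum(Wn_pairs^2)), sqrt(sum(Z^2)),
                           sqrt(sum(Wp_mat^2)))
    eps_dual <- config$eps_abs * kdim +
      config$eps_rel * sqrt(sum((config$rho * U)^2))
    if (r_norm < eps_pri && s_norm < eps_dual) break
  }
  converged <- r_norm < eps_pri && s_norm < eps_dual
  if (!converged)
    warning("ADMM did not reach stopping tolerances in ",
            config$max_admm_iters, " iterations; returning last iterate")
  list(W_sub = W, iters = length(primal), primal = primal, dual = dual,
       converged = converged)
}

#' Fit the multi-label k-mer model
#'
#' Alternates (i) an ADMM solve for the subclass weight vectors at fixed
#' label weights and (ii) the closed-form coordinate-wise median update for
#' the label weights, until the label weights stabilise or `config$sweeps`
#' sweeps have run. The ADMM w-step is solved by warm-started L-BFGS; the
#' z-step is soft-thresholding at 2*lambda/rho of the over-relaxed iterate;
#' stopping follows the dual- and primal-residual criteria with the feature
#' count K as the absolute scale factor.
#'
#' @param dataset a [labeled_dataset()].
#' @param features a [feature_matrix()] built from `dataset$sequences`.
#' @param config a [train_config()]. If `config$lambda` is `NULL` it is
#'   first selected by [select_lambda()].
#' @return object of class `md_model`: a [weight_set()] plus the feature
#'   standardization parameters, the config used, and training diagnostics
#'   (objective per sweep, ADMM iteration counts, residual traces).
#' @export
train_model <- function(dataset, features, config = train_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(features, "feature_matrix"))
  structure_ <- label_structure(dataset)
  if (is.null(config$lambda))
    config$lambda <- select_lambda(dataset, features, config)

  X <- features$X
  X1 <- cbind(1, X)
  cls <- dataset$subclass_of
  b <- dataset$b
  nT <- length(structure_$subclasses)
  K <- features$space$K
  # the w-step optimizes the NLL per unit of total sequence weight, so
  # lambda and rho are on an O(1) scale independent of dataset size; the
  # reported objective is the equivalent unnormalized form
  scale_b <- sum(b)
  b_norm <- b / scale_b

  W_sub <- matrix(0, nrow = nT, ncol = K + 1L)
  W_lab <- matrix(0, nrow = length(structure_$labels), ncol = K,
                  dimnames = list(structure_$labels, features$space$columns))
  obj_trace <- numeric(0)
  admm_iters <- integer(0)
  residuals <- list()

  for (s in seq_len(config$sweeps)) {
    W_sub_prev <- W_sub
    W_lab_prev <- W_lab
    inner <- admm_inner(X1, cls, b_norm, structure_, W_sub, W_lab,
                        config$lambda, config$rho, config)
    W_sub <- inner$W_sub
    # identifiability: the softmax and the fused penalty are both invariant
    # to adding one vector to every subclass weight vector; fix the gauge by
    # sum-to-zero contrasts so weights are deviations from a pooled model
    W_sub <- sweep(W_sub, 2L, colMeans(W_sub))
    admm_iters <- c(admm_iters, inner$iters)
    residuals[[s]] <- list(primal = inner$primal, dual = inner$dual)
    W_lab_new <- update_label_weights(W_sub, structure_)
    delta <- max(abs(W_lab_new - W_lab))
    W_lab <- W_lab_new
    ws <- weight_set(W_sub, W_lab, structure_, features$space)
    obj_new <- model_objective(ws, X, dataset$y, b,
                               config$lambda * scale_b)
    if (s > 1L && obj_new > obj_trace[s - 1L]) {
      # the inexact inner solve stopped improving; keep the better iterate
      W_sub <- W_sub_prev
      W_lab <- W_lab_prev
      admm_iters <- admm_iters[-s]
      residuals[[s]] <- NULL
      break
    }
    obj_trace <- c(obj_trace, obj_new)
    if (delta < config$sweep_tol) break
  }

  # fusion polish: snap near-fused coordinates onto their label consensus,
  # then refresh the label medians
  snap_tol <- config$snap_frac * 2 * config$lambda / config$rho
  if (snap_tol > 0) {
    for (rep in 1:4) {
      for (n in seq_along(structure_$Pi)) {
        wn <- W_sub[n, -1L]
        for (p in structure_$Pi[[n]]) {
          d <- wn - W_lab[p, ]
          wn[abs(d) <= snap_tol] <- W_lab[p, abs(d) <= snap_tol]
        }
        W_sub[n, -1L] <- wn
      }
      W_sub <- sweep(W_sub, 2L, colMeans(W_sub))
      W_lab <- update_label_weights(W_sub, structure_)
    }
  }

  ws <- weight_set(W_sub, W_lab, structure_, features$space)
  structure(list(weights = ws, structure = structure_, space = features$space,
                 col_means = features$col_means, col_sds = features$col_sds,
                 config = config, objective = obj_trace,
                 admm_iters = admm_iters, residuals = residuals,
                 labels = structure_$labels,
                 subclasses = structure_$subclasses),
            class = "md_model")
}

#' @export
print.md_model <- function(x, ...) {
  cat("md_model:", length(x$subclasses), "subclasses /", length(x$labels),
      "labels; lambda =", x$config$lambda, "\n")
  cat("  objective per sweep:", paste(signif(x$objective, 6), collapse = " "),
      "\n")
  invisible(x)
}

#' Select the fusion penalty by cross-validation
#'
#' 3-fold cross-validation (folds stratified by subclass) over a small
#' lambda grid, maximizing mean held-out per-sequence subclass
#' log-likelihood.
#'
#' @inheritParams train_model
#' @param folds number of folds.
#' @return the selected lambda.
#' @export
select_lambda <- function(dataset, features, config = train_config(),
                          folds = 3L) {
  set.seed(config$seed)
  fold_of <- make_stratified_folds(dataset$subclass_of, folds)
  grid <- config$lambda_grid
  ll <- matrix(NA_real_, nrow = folds, ncol = length(grid))
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    sub_data <- labeled_dataset(dataset$sequences[tr],
                                dataset$label_sets[tr])
    sub_fm <- feature_matrix(sub_data$sequences, features$space)
    X_te <- featurize(sub_fm, dataset$sequences[te])
    for (g in seq_along(grid)) {
      cfg <- config; cfg$lambda <- grid[g]
      fit <- train_model(sub_data, sub_fm, cfg)
      p <- subclass_posteriors(X_te, fit$weights)
      key <- subclass_key(dataset$label_sets[te])
      col <- match(key, fit$subclasses)
      ok <- !is.na(col)
      ll[f, g] <- mean(log(pmax(p[cbind(which(ok), col[ok])], 1e-300)))
    }
  }
  grid[which.max(colMeans(ll))]
}

make_stratified_folds <- function(strata, folds) {
  fold_of <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Naive multi-class baseline
#'
#' Treats each label as a mutually exclusive class: every sequence is
#' duplicated once per label it carries, and a standard L1-regularized
#' multinomial logistic regression is fit on the duplicated design (via
#' glmnet). Used only for benchmark comparisons against the hierarchical
#' model.
#'
#' @inheritParams train_model
#' @param lambda glmnet penalty; a single small value keeps the baseline fast
#'   and mildly sparse.
#' @return object of class `mcc_model` with `W_lab` (labels x K k-mer weight
#'   matrix) and `intercepts`.
#' @export
fit_mcc_baseline <- function(dataset, features, lambda = 1e-3) {
  rows <- rep(seq_len(dataset$M), lengths(dataset$label_sets))
  y <- factor(unlist(dataset$label_sets, use.names = FALSE),
              levels = sort(unique(unlist(dataset$label_sets))))
  X <- features$X[rows, , drop = FALSE]
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  co <- glmnet::coef.glmnet(fit, s = lambda)
  W <- t(vapply(co, function(m) as.numeric(m)[-1L],
                numeric(ncol(features$X))))
  rownames(W) <- names(co)
  colnames(W) <- features$space$columns
  structure(list(W_lab = W,
                 intercepts = vapply(co, function(m) as.numeric(m)[1L],
                                     numeric(1)),
                 labels = names(co), space = features$space),
            class = "mcc_model")
}
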