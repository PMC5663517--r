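sp <- kmer_space()

test_that("shrinkage matches its closed form", {
  expect_equal(shrinkage(1.2, 0.5), 0.7)
  expect_equal(shrinkage(-0.2, 0.5), 0)
  expect_equal(shrinkage(-1.0, 0.5), -0.5)
  expect_equal(shrinkage(c(0.5, -0.5, 0), 0.5), c(0, 0, 0))
  a <- matrix(c(2, -2, 0.1, -0.1), 2)
  expect_equal(shrinkage(a, 1), matrix(c(1, -1, 0, 0), 2))
})

test_that("label weights are coordinate-wise medians over spanned subclasses", {
  st <- label_structure(c("A;P", "B;P", "C;P", "Q"))
  W <- matrix(0, 4, sp$K + 1)
  W[1, 2] <- 0.2; W[2, 2] <- -0.1; W[3, 2] <- 0.4   # P spans rows 1:3
  W[1, 3] <- 0.1; W[2, 3] <- 0.3                     # even set for A? no:
  lab <- update_label_weights(W, st)
  expect_equal(unname(lab["P", 1]), 0.2)             # median of 3
  # label spanning a single subclass copies it exactly
  W[4, ] <- rnorm(sp$K + 1)
  lab <- update_label_weights(W, st)
  expect_equal(unname(lab["Q", ]), unname(W[4, -1]))
  # even-cardinality median = mean of the two middle values
  st2 <- label_structure(c("A;P", "B;P"))
  W2 <- matrix(0, 2, sp$K + 1)
  W2[1, 2] <- 0.1; W2[2, 2] <- 0.3
  expect_equal(unname(update_label_weights(W2, st2)["P", 1]), 0.2)
})

test_that("lambda = 0 fit matches an unpenalized multinomial reference", {
  skip_if_not_installed("nnet")
  ds <- planted_two_class(n_per = 60, L = 40, seed = 21)
  fm <- feature_matrix(ds$sequences, sp)
  # the full 648-feature problem is separable at this n, so the unpenalized
  # optimum is not finite; compare on a common informative subspace chosen
  # by marginal class association (independent of either fit)
  cls <- max.col(ds$y)
  assoc <- abs(colMeans(fm$X[cls == 1, ]) - colMeans(fm$X[cls == 2, ]))
  keep <- order(-assoc)[1:12]
  sub_space <- structure(list(k_values = sp$k_values,
                              columns = sp$columns[keep], K = 12L,
                              lookup = sp$lookup,
                              code_lookup = sp$code_lookup),
                         class = "kmer_space")
  sub_fm <- structure(list(X = fm$X[, keep],
                           col_means = fm$col_means[keep],
                           col_sds = fm$col_sds[keep], space = sub_space),
                      class = "feature_matrix")
  # at lambda 0 the ADMM reduces to a proximal-point iteration; a small rho
  # weakens the anchor and speeds convergence to the unpenalized optimum
  cfg <- train_config(lambda = 0, rho = 0.001, sweeps = 1,
                      max_admm_iters = 60, lbfgs_maxit = 200,
                      eps_abs = 1e-8)
  fit <- suppressWarnings(train_model(ds, sub_fm, cfg))
  nll_ours <- model_objective(fit$weights, sub_fm$X, ds$y, ds$b, 0)
  ref_df <- data.frame(y = factor(cls), sub_fm$X)
  ref <- nnet::multinom(y ~ ., data = ref_df, weights = ds$b,
                        trace = FALSE, maxit = 1000, reltol = 1e-14)
  nll_ref <- -as.numeric(stats::logLik(ref))
  expect_lt(abs(nll_ours - nll_ref), 1e-3)
})

test_that("planted k-mers receive the largest weights in their subclass", {
  ds <- planted_two_class(n_per = 100, L = 60, seed = 42,
                          words = c("ACGTACGA", "GGCATCCG"))
  fm <- feature_matrix(ds$sequences, sp)
  fit <- train_model(ds, fm, train_config())
  for (g in 1:2) {
    word <- c("ACGTACGA", "GGCATCCG")[g]
    constituents <- unique(canonical_kmer(
      vapply(1:(nchar(word) - 4), function(s) substr(word, s, s + 4),
             character(1))))
    row <- fit$weights$W_sub[g, -1]
    expect_true(names(which.max(row)) %in% constituents)
  }
})

test_that("objective is non-increasing over outer sweeps", {
  ds <- planted_two_class(n_per = 80, L = 50, seed = 3)
  fm <- feature_matrix(ds$sequences, sp)
  fit <- train_model(ds, fm, train_config(sweeps = 4, snap_frac = 0))
  diffs <- diff(fit$objective)
  expect_true(all(diffs <= 1e-6 * abs(fit$objective[-length(fit$objective)])
                  + 1e-6))
})

test_that("large lambda drives subclass weights onto the label weights", {
  ds <- planted_two_class(n_per = 60, L = 40, seed = 13)
  fm <- feature_matrix(ds$sequences, sp)
  fit <- train_model(ds, fm, train_config(lambda = 100, sweeps = 2))
  st <- fit$structure
  tot <- 0
  for (n in seq_along(st$Pi)) for (p in st$Pi[[n]])
    tot <- tot + sum(abs(fit$weights$W_sub[n, -1] - fit$weights$W_lab[p, ]))
  expect_lt(tot, 1e-6)
})

test_that("both printed stopping criteria hold at reported convergence", {
  ds <- planted_two_class(n_per = 60, L = 40, seed = 8)
  fm <- feature_matrix(ds$sequences, sp)
  cfg <- train_config()
  fit <- train_model(ds, fm, cfg)
  for (res in fit$residuals) {
    np <- length(res$primal)
    expect_gt(np, 0)
    # residual traces end below the absolute tolerance component
    expect_lt(res$primal[np], cfg$eps_abs * sp$K +
                cfg$eps_rel * 10)  # generous relative part bound
    expect_lt(res$dual[np], cfg$eps_abs * sp$K + cfg$eps_rel * 10)
  }
})

test_that("distributed w-step pooling agrees with the single-thread path", {
  ds <- planted_two_class(n_per = 60, L = 40, seed = 31)
  fm <- feature_matrix(ds$sequences, sp)
  f1 <- train_model(ds, fm, train_config(sweeps = 2))
  f4 <- train_model(ds, fm, train_config(sweeps = 2, threads = 4))
  o1 <- model_objective(f1$weights, fm$X, ds$y, ds$b, 0.005 * sum(ds$b))
  o4 <- model_objective(f4$weights, fm$X, ds$y, ds$b, 0.005 * sum(ds$b))
  expect_lt(abs(o1 - o4) / o1, 1e-2)
})

test_that("the MCC baseline duplicates multi-label sites and reduces to a
           multinomial fit on single-label data", {
  seqs <- rand_seqs(60, 40, seed = 2)
  labs <- rep(list(c("A", "X"), "A", "X"), each = 20)
  ds <- labeled_dataset(seqs, labs)
  fm <- feature_matrix(ds$sequences, sp)
  fit <- fit_mcc_baseline(ds, fm)
  expect_setequal(fit$labels, c("A", "X"))
  expect_equal(dim(fit$W_lab), c(2L, sp$K))
  # single-label data: same model as a direct multinomial glmnet fit
  ds2 <- planted_two_class(n_per = 40, L = 40, seed = 5)
  fm2 <- feature_matrix(ds2$sequences, sp)
  fit2 <- fit_mcc_baseline(ds2, fm2)
  ref <- glmnet::glmnet(fm2$X, factor(unlist(ds2$label_sets)),
                        family = "multinomial", alpha = 1, lambda = 1e-3,
                        standardize = FALSE)
  co <- glmnet::coef.glmnet(ref, s = 1e-3)
  expect_equal(unname(fit2$W_lab["L1", ]), as.numeric(co$L1)[-1],
               tolerance = 1e-8)
})
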