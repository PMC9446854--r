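# Full-chain behavior: residual bookkeeping, determinism, exact model
# reductions, shrinkage under a null trait, and prediction.

small_instance <- function(n = 200, p = 50, seed = 31, h2 = 0.5) {
  g <- simulate_genotypes(n, p, n_chrom = 2, ld_rho = 0.4,
                          maf_range = c(0.1, 0.5), seed = seed)
  f <- allele_frequencies(g)
  X <- center_scale(g, f)
  set.seed(seed + 1)
  qtl <- sample(p, 3)
  beta <- numeric(p); beta[qtl] <- c(0.8, -0.6, 0.5)
  gvar <- var(drop(X$X %*% beta))
  y <- drop(X$X %*% beta) + rnorm(n, sd = sqrt(gvar * (1 - h2) / h2))
  list(X = X, y = y, qtl = qtl, g = g, f = f)
}

test_that("the maintained residual never drifts from y - mu - X beta", {
  d <- small_instance()
  ann <- annotation_set(cbind(a = rep(c(1L, 0L), length.out = 50),
                              b = rep(c(1L, 1L, 0L), length.out = 50)))
  for (model in c("bayesr", "bayesrcpi", "bayesrcplus")) {
    fit <- bayes_fit(d$X, d$y, model,
                     annotations = if (model == "bayesr") NULL else ann,
                     config = sampler_config(1500, 500, 2, seed = 41))
    expect_lt(fit$max_residual_dev, 1e-8)
  }
})

test_that("identical seeds give bit-identical summaries", {
  d <- small_instance()
  cfg <- sampler_config(1200, 400, 2, seed = 77, update_order = "permuted")
  f1 <- bayes_fit(d$X, d$y, "bayesr", config = cfg)
  f2 <- bayes_fit(d$X, d$y, "bayesr", config = cfg)
  expect_identical(f1$beta_hat, f2$beta_hat)
  expect_identical(f1$trace, f2$trace)
  f3 <- bayes_fit(d$X, d$y, "bayesr",
                  config = sampler_config(1200, 400, 2, seed = 78))
  expect_false(identical(f1$beta_hat, f3$beta_hat))
})

test_that("single-category and disjoint annotations reduce to the base models", {
  d <- small_instance()
  cfg <- sampler_config(1500, 500, 2, seed = 55)
  # BayesRC with only the "other" category is BayesR
  ann1 <- annotation_set(matrix(1L, 50, 1, dimnames = list(NULL, "other")))
  fr <- bayes_fit(d$X, d$y, "bayesr", config = cfg)
  frc <- bayes_fit(d$X, d$y, "bayesrc", annotations = ann1, config = cfg)
  expect_equal(fr$beta_hat, frc$beta_hat)
  expect_equal(fr$sigma_g2_hat, frc$sigma_g2_hat)
  # disjoint annotations: RCpi and RC+ take the same update path as RC
  A <- matrix(0L, 50, 2, dimnames = list(NULL, c("a", "b")))
  A[1:25, 1] <- 1L; A[26:50, 2] <- 1L
  ann2 <- annotation_set(A)
  frc2 <- bayes_fit(d$X, d$y, "bayesrc", annotations = ann2, config = cfg)
  fpi <- bayes_fit(d$X, d$y, "bayesrcpi", annotations = ann2, config = cfg)
  fplus <- bayes_fit(d$X, d$y, "bayesrcplus", annotations = ann2, config = cfg)
  expect_equal(frc2$beta_hat, fpi$beta_hat)
  expect_equal(frc2$beta_hat, fplus$beta_hat)
  expect_equal(frc2$pi_hat, fpi$pi_hat)
  expect_equal(frc2$pi_hat, fplus$pi_hat)
})

test_that("bayesrc rejects overlapping annotations; bayesr ignores them", {
  d <- small_instance()
  A <- matrix(1L, 50, 2, dimnames = list(NULL, c("a", "b")))
  ann <- annotation_set(A)
  expect_error(bayes_fit(d$X, d$y, "bayesrc", annotations = ann,
                         config = sampler_config(100, 10, 1)),
               "disjoint")
  expect_message(bayes_fit(d$X, d$y, "bayesr", annotations = ann,
                           config = sampler_config(100, 10, 1)),
                 "ignored")
})

test_that("chain posterior matches exhaustive enumeration on a 3-SNP toy", {
  # Fixed mu, pi, sigma_e2, sigma_g2: the only unknowns are the three class
  # indicators and effects, so the posterior is available in closed form by
  # summing the 4^3 class configurations.
  n <- 20; p <- 3; K <- 4
  set.seed(61)
  X <- matrix(rnorm(n * p), n, p)
  X[, 3] <- 0.7 * X[, 2] + 0.5 * X[, 3]  # mild collinearity
  beta_true <- c(0.9, 0, -0.5)
  y <- drop(X %*% beta_true) + rnorm(n, sd = 1)
  r0 <- y - mean(y)
  se2 <- var(y) / 2; sg2 <- var(y) / 2
  theta <- c(0, 1e-4, 1e-3, 1e-2) * sg2
  piv <- rep(0.25, K)

  # oracle: enumerate class configurations
  grid <- expand.grid(k1 = 1:K, k2 = 1:K, k3 = 1:K)
  logw <- numeric(nrow(grid)); bmean <- matrix(0, nrow(grid), p)
  cls_prob <- matrix(0, p, K)
  for (gI in seq_len(nrow(grid))) {
    kk <- as.integer(grid[gI, ])
    D <- diag(theta[kk], p)
    S <- se2 * diag(n) + X %*% D %*% t(X)
    logw[gI] <- -0.5 * determinant(S)$modulus -
      0.5 * drop(crossprod(r0, solve(S, r0))) + sum(log(piv[kk]))
    bmean[gI, ] <- drop(D %*% t(X) %*% solve(S, r0))
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  beta_oracle <- drop(t(bmean) %*% w)
  for (j in 1:p) for (k in 1:K)
    cls_prob[j, k] <- sum(w[grid[[j]] == k])

  # five replicate chains with pinned mu/pi/variances
  reps <- lapply(1:5, function(s) {
    bayes_fit(X, y, "bayesr",
              config = sampler_config(13000, 1000, 2, seed = 100 + s,
                                      update_mu = FALSE, update_pi = FALSE,
                                      update_variances = FALSE))
  })
  bmat <- sapply(reps, `[[`, "beta_hat")           # p x 5
  cmat <- sapply(reps, function(f) as.vector(f$class_freq))
  b_se <- apply(bmat, 1, sd) / sqrt(5)
  c_se <- apply(cmat, 1, sd) / sqrt(5)
  expect_true(all(abs(rowMeans(bmat) - beta_oracle) <=
                    3 * b_se + 0.01 * max(abs(beta_oracle))))
  expect_true(all(abs(rowMeans(cmat) - as.vector(cls_prob)) <=
                    3 * c_se + 0.01))
})

test_that("a heritability-zero trait leaves almost all SNPs null", {
  # Shrinkage is only identifiable when n * theta_k / sigma_e2 is
  # appreciable, so this property is checked at a moderately large scale.
  g <- simulate_genotypes(1000, 1000, n_chrom = 4, seed = 71)
  X <- center_scale(g, allele_frequencies(g))
  set.seed(72)
  y <- rnorm(1000, 0, 10)
  fit <- bayes_fit(X, y, "bayesr", config = sampler_config(3000, 1000, 2, 73))
  nonnull_freq <- 1 - fit$class_freq[, 1]
  expect_lte(mean(nonnull_freq > 0.5), 0.01)
})

test_that("prediction is the intercept plus the genomic linear predictor", {
  d <- small_instance(n = 80, p = 20)
  fit <- bayes_fit(d$X, d$y, "bayesr",
                   config = sampler_config(800, 200, 2, seed = 81))
  # re-multiplication oracle
  set.seed(82)
  Xn <- matrix(rnorm(10 * 20), 10, 20)
  expect_lt(max(abs(predict(fit, Xn) -
                    (fit$mu_hat + drop(Xn %*% fit$beta_hat)))), 1e-10)
  # beta = 0 gives a constant prediction at the intercept
  fit0 <- fit; fit0$beta_hat <- rep(0, 20)
  expect_equal(unname(predict(fit0, Xn)), rep(fit0$mu_hat, 10))
  # single SNP, unit effect
  fit1 <- fit0; fit1$beta_hat <- c(1, rep(0, 19))
  X1 <- matrix(0, 3, 20); X1[, 1] <- c(-1, 0, 1)
  expect_equal(unname(predict(fit1, X1) - fit1$mu_hat), c(-1, 0, 1))
  expect_error(predict(fit, matrix(0, 3, 5)), "column mismatch")
})

test_that("sampled mixing proportions and PAIP rows are normalized", {
  d <- small_instance()
  set.seed(91)
  A <- matrix(rbinom(100, 1, 0.5), 50, 2, dimnames = list(NULL, c("a", "b")))
  ann <- annotation_set(A)
  fit <- bayes_fit(d$X, d$y, "bayesrcpi", annotations = ann,
                   config = sampler_config(1500, 500, 2, seed = 92))
  expect_lt(max(abs(rowSums(fit$paip) - 1)), 1e-12)
  # PAIP support within C_i
  expect_true(all(fit$paip[ann$A == 0] == 0))
  # pi draws in the trace are normalized per category
  picols <- grep("^pi_", colnames(fit$trace))
  pis <- fit$trace[, picols]
  m <- ncol(ann$A)
  for (cc in seq_len(m)) {
    block <- pis[, (cc - 1) * 4 + 1:4]
    expect_lt(max(abs(rowSums(block) - 1)), 1e-12)
  }
  # V_hat >= beta_hat^2 (Jensen)
  expect_true(all(fit$V_hat - fit$beta_hat^2 >= -1e-12))
})

test_that("the kept beta chain reproduces the accumulated summaries", {
  d <- small_instance(n = 60, p = 10)
  fit <- bayes_fit(d$X, d$y, "bayesr",
                   config = sampler_config(600, 100, 5, seed = 95,
                                           store_beta = TRUE))
  expect_equal(nrow(fit$beta_chain), fit$n_kept)
  expect_equal(colMeans(fit$beta_chain), fit$beta_hat)
  expect_equal(posterior_variance(fit$beta_chain), fit$beta_sq_hat)
})
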