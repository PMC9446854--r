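#' Effect-class mixture prior
#'
#' The four-component spike-and-slab normal mixture on standardized SNP
#' effects: class variances are fixed fractions `kappa = (0, 1e-4, 1e-3,
#' 1e-2)` of the total additive variance (null, small, medium, large, i.e.
#' 0%, 0.01%, 0.1% and 1% of sigma_g^2), with a flat Dirichlet(1,1,1,1)
#' prior on the mixing proportions.
#'
#' @param kappa variance fractions per class; first entry must be 0.
#' @param alpha Dirichlet pseudocounts, all positive.
#' @return a list of class `mixture_prior`.
#' @export
mixture_prior <- function(kappa = c(0, 0.0001, 0.001, 0.01),
                          alpha = rep(1, length(kappa))) {
  if (kappa[1] != 0) stop("the first class must be the null class (kappa = 0)")
  if (length(kappa) > 1 && any(diff(kappa[-1]) <= 0))
    stop("kappa must be strictly increasing over the non-null classes")
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  if (length(alpha) != length(kappa)) stop("alpha/kappa length mismatch")
  structure(list(kappa = kappa, alpha = alpha, n_classes = length(kappa)),
            class = "mixture_prior")
}

#' Sampler configuration
#'
#' Defaults follow common practice for these models: 50,000 iterations with
#' a 20,000-iteration burn-in and thinning rate 10 (3,000 kept samples).
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded.
#' @param thin thinning rate (>= 1).
#' @param seed integer seed (drives all chain randomness).
#' @param update_order `"genome"` (map order) or `"permuted"` (fresh random
#'   permutation of SNP updates each iteration).
#' @param store_beta keep the thinned chain of beta (kept x p matrix); only
#'   sensible for small p.
#' @param update_mu,update_pi,update_variances switches to pin the
#'   intercept, mixing proportions, or variance components at their initial
#'   values (used for conjugate-oracle validation; leave TRUE for analysis).
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 50000, burn_in = 20000, thin = 10,
                           seed = 1L, update_order = c("genome", "permuted"),
                           store_beta = FALSE, update_mu = TRUE,
                           update_pi = TRUE, update_variances = TRUE) {
  update_order <- match.arg(update_order)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 update_order = update_order, store_beta = store_beta,
                 update_mu = update_mu, update_pi = update_pi,
                 update_variances = update_variances),
            class = "sampler_config")
}

.model_codes <- c(bayescpi = 0L, bayesr = 1L, bayesrc = 2L, bayesrcpi = 3L,
                  bayesrcplus = 4L)

#' Fit a Bayesian genomic prediction model by Gibbs sampling
#'
#' Fits one of five models sharing the same spike-and-slab mixture machinery:
#' `bayescpi` (two classes, null + normal), `bayesr` (four classes, no
#' annotations), `bayesrc` (per-category mixing proportions, disjoint
#' annotations), `bayesrcpi` (overlapping annotations with preferential
#' per-SNP category assignment and PAIP output), and `bayesrcplus`
#' (overlapping annotations with cumulative per-annotation sub-effects,
#' beta_i = sum of its per-annotation effects).
#'
#' Initialization: beta = 0 (all classes null), mu = mean(y),
#' sigma_e^2 = sigma_g^2 = var(y)/2, pi_c at the prior mean, per-SNP
#' annotation weights uniform over C_i. Variance components use flat scaled
#' inverse-chi-square hyper-priors (nu_0 = -2, s_0^2 = 0).
#'
#' @param X an n x p standardized genotype matrix or a `std_genotypes`
#'   object from [center_scale()].
#' @param y numeric phenotype vector of length n.
#' @param model one of `"bayescpi"`, `"bayesr"`, `"bayesrc"`, `"bayesrcpi"`,
#'   `"bayesrcplus"`.
#' @param annotations an [annotation_set()]; required for the RC-family
#'   models (`bayesrc` additionally requires a disjoint set); ignored (with
#'   a message) by `bayesr`/`bayescpi`, which use a single category.
#' @param config a [sampler_config()].
#' @param prior a [mixture_prior()]; for `bayescpi` the default is the
#'   two-class prior `kappa = (0, 1)` with the effect variance sampled.
#' @return an object of class `bayes_fit`: posterior means (`beta_hat`,
#'   `beta_sq_hat`, `V_hat`, `mu_hat`, `sigma_e2_hat`, `sigma_g2_hat`,
#'   `pi_hat`), per-SNP class-membership frequencies (`class_freq`), the
#'   PAIP matrix (`paip`), the kept hyperparameter trace (`trace`), and the
#'   configuration used.
#' @export
bayes_fit <- function(X, y, model = c("bayesr", "bayescpi", "bayesrc",
                                      "bayesrcpi", "bayesrcplus"),
                      annotations = NULL, config = sampler_config(),
                      prior = NULL) {
  model <- match.arg(model)
  f <- NULL; map <- NULL
  if (inherits(X, "std_genotypes")) { f <- X$f; map <- X$map; X <- X$X }
  X <- as.matrix(X)
  if (anyNA(y) || any(!is.finite(y))) stop("phenotypes contain NaN/NA")
  if (nrow(X) != length(y)) stop("X rows do not align with y")
  p <- ncol(X)
  if (is.null(prior)) {
    prior <- if (model == "bayescpi") mixture_prior(c(0, 1), c(1, 1))
             else mixture_prior()
  }
  if (model %in% c("bayesr", "bayescpi")) {
    if (!is.null(annotations))
      message("annotations are ignored by ", model,
              " (single-category model)")
    annotations <- annotation_set(
      matrix(1L, p, 1, dimnames = list(NULL, "other")))
  }
  if (is.null(annotations))
    stop(model, " requires an annotation set")
  if (nrow(annotations$A) != p)
    stop("annotation rows do not match marker count")
  if (model == "bayesrc" && !is_disjoint(annotations))
    stop("bayesrc requires disjoint annotations; see downsample_overlaps()")

  K <- prior$n_classes
  m <- ncol(annotations$A)
  pi0 <- matrix(rep(prior$alpha / sum(prior$alpha), each = m), m, K)
  vy <- stats::var(y)

  set.seed(config$seed)
  res <- .gibbs_core(X, as.numeric(y), .model_codes[[model]], annotations$A,
                     prior$kappa, prior$alpha, config$n_iter, config$burn_in,
                     config$thin, config$update_order == "permuted",
                     config$update_mu, config$update_pi,
                     config$update_variances, mean(y), vy / 2, vy / 2, pi0,
                     config$store_beta)

  colnames(res$paip) <- annotations$category_names
  rownames(res$pi_hat) <- annotations$category_names
  out <- list(model = model, beta_hat = res$beta_hat,
              beta_sq_hat = res$beta_sq_hat, V_hat = res$beta_sq_hat,
              class_freq = res$class_freq, paip = res$paip,
              pi_hat = res$pi_hat, mu_hat = res$mu_hat,
              sigma_e2_hat = res$sigma_e2_hat,
              sigma_g2_hat = res$sigma_g2_hat, n_kept = res$n_kept,
              trace = res$trace, max_residual_dev = res$max_residual_dev,
              annotations = annotations, prior = prior, config = config,
              train_f = f, map = map)
  if (config$store_beta) out$beta_chain <- res$beta_chain
  colnames(out$trace) <- c("mu", "sigma_e2", "sigma_g2",
                           paste0("pi_",
                                  rep(annotations$category_names, each = K),
                                  "_k", rep(seq_len(K), times = m)))
  class(out) <- "bayes_fit"
  out
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("bayes_fit (%s): %d markers, %d kept samples\n", x$model,
              length(x$beta_hat), x$n_kept))
  cat(sprintf("  mu_hat = %.4f, sigma_e2_hat = %.4f, sigma_g2_hat = %.4f\n",
              x$mu_hat, x$sigma_e2_hat, x$sigma_g2_hat))
  invisible(x)
}

#' Predict phenotypes from a fitted model
#'
#' Computes the linear predictor (genomic estimated breeding value plus
#' intercept) `y_hat = mu_hat + X_new beta_hat`. New genotypes must be
#' standardized with the training-sample allele frequencies.
#'
#' @param object a [bayes_fit()] result.
#' @param X_new standardized genotype matrix or `std_genotypes` object.
#' @param ... unused.
#' @return numeric vector of predicted phenotypic values.
#' @export
predict.bayes_fit <- function(object, X_new, ...) {
  if (inherits(X_new, "std_genotypes")) X_new <- X_new$X
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$beta_hat))
    stop(sprintf("column mismatch: %d columns vs %d fitted effects",
                 ncol(X_new), length(object$beta_hat)))
  drop(object$mu_hat + X_new %*% object$beta_hat)
}

#' Log marginal likelihoods of the effect classes for one SNP
#'
#' For class variance theta_k, returns (up to a constant shared across
#' classes, absorbed so the null class is 0)
#' `-log(1 + s theta_k / se2)/2 + t^2 theta_k / (2 se2 (se2 + s theta_k))`
#' with `s = x'x` and `t = x'r_adj`, where `r_adj` is the residual with the
#' SNP's own contribution restored.
#'
#' @param x standardized genotype column.
#' @param r_adj adjusted residual vector.
#' @param theta class variances (first entry 0 for the null class).
#' @param sigma_e2 residual variance.
#' @return numeric vector of log marginal likelihoods, one per class.
#' @export
class_log_likelihoods <- function(x, r_adj, theta, sigma_e2) {
  if (any(!is.finite(x)) || any(!is.finite(r_adj)) ||
      any(!is.finite(theta)) || !is.finite(sigma_e2) || sigma_e2 <= 0)
    stop("non-finite inputs to class_log_likelihoods")
  if (theta[1] != 0) stop("theta[1] must be 0 (null class)")
  .cls_loglik_cpp(sum(x * x), sum(x * r_adj), theta, sigma_e2)
}

#' Draw updated mixing proportions
#'
#' Conjugate Dirichlet update: a draw from Dirichlet(alpha + gamma), where
#' gamma holds the current class counts for the category.
#'
#' @param gamma_counts non-negative class counts.
#' @param alpha Dirichlet pseudocounts.
#' @return a probability vector summing to 1.
#' @export
update_mixing_proportions <- function(gamma_counts, alpha = rep(1, length(gamma_counts))) {
  if (any(gamma_counts < 0)) stop("counts must be non-negative")
  g <- stats::rgamma(length(gamma_counts), shape = alpha + gamma_counts,
                     rate = 1)
  g / sum(g)
}
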