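#' Validation prediction accuracy
#'
#' Pearson correlation between observed and predicted phenotypes in the
#' validation set.
#'
#' @param y observed phenotypes.
#' @param y_hat predicted phenotypes.
#' @return Pearson r in `[-1, 1]`.
#' @export
prediction_accuracy <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::sd(y) == 0 || stats::sd(y_hat) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(y, y_hat)
}

#' Per-SNP posterior variance
#'
#' On standardized genotypes, the posterior variance of SNP i reduces to the
#' posterior mean of the squared effect, `V_i = mean(beta_i^2)` over kept
#' samples. Accepts either a fitted model (uses its accumulated
#' `beta_sq_hat`) or a kept-samples chain matrix (kept x p).
#'
#' @param fit_or_chain a `bayes_fit` object or a numeric matrix of kept beta
#'   samples.
#' @return numeric vector of per-SNP posterior variances.
#' @export
posterior_variance <- function(fit_or_chain) {
  if (inherits(fit_or_chain, "bayes_fit")) return(fit_or_chain$beta_sq_hat)
  ch <- as.matrix(fit_or_chain)
  if (nrow(ch) == 0) stop("empty chain")
  colMeans(ch^2)
}

#' PAIP summary from an assignment chain
#'
#' Tallies, for every marker, the kept-sample frequency of assignment to
#' each of its annotation categories (the posterior annotation inclusion
#' probability), and derives a maximum a posteriori category per marker.
#' Single-annotated markers have PAIP 1 in their category.
#'
#' @param assignments kept x p integer matrix of assigned category indices
#'   (columns of the annotation matrix), or a `bayes_fit` from `bayesrcpi`
#'   (its accumulated PAIP matrix is used directly).
#' @param annotations an [annotation_set()].
#' @return list with `paip` (p x m matrix), `map_category` (character),
#'   and `tie` (logical flags for ties broken toward the lowest index).
#' @export
paip_summary <- function(assignments, annotations) {
  m <- ncol(annotations$A)
  if (inherits(assignments, "bayes_fit")) {
    paip <- assignments$paip
  } else {
    ch <- as.matrix(assignments)
    p <- ncol(ch)
    paip <- matrix(0, p, m, dimnames = list(NULL, annotations$category_names))
    for (i in seq_len(p)) {
      if (any(annotations$A[i, ch[, i]] == 0))
        stop("integrity error: assignment outside C_i for marker ", i)
      tab <- tabulate(ch[, i], nbins = m)
      paip[i, ] <- tab / nrow(ch)
    }
  }
  map_idx <- apply(paip, 1, which.max)
  tie <- apply(paip, 1, function(r) sum(r == max(r)) > 1)
  list(paip = paip,
       map_category = annotations$category_names[map_idx],
       tie = tie)
}

#' Mean rank of a QTL set by posterior variance
#'
#' Markers are ranked in decreasing order of posterior variance (average
#' ranks for ties); returns the mean rank of the designated set. With 5
#' QTLs, the best attainable value is 3 (the average of ranks 1 to 5).
#'
#' @param V_hat per-SNP posterior variances.
#' @param qtl_idx indices of the designated QTLs.
#' @return mean rank (numeric scalar).
#' @export
qtl_mean_rank <- function(V_hat, qtl_idx) {
  if (length(qtl_idx) == 0) stop("qtl_idx must be non-empty")
  if (any(qtl_idx < 1 | qtl_idx > length(V_hat))) stop("qtl_idx out of range")
  rk <- rank(-V_hat, ties.method = "average")
  mean(rk[qtl_idx])
}

#' Top-k markers by posterior variance
#'
#' @param V_hat per-SNP posterior variances.
#' @param k number of markers.
#' @return integer indices of the top-k markers.
#' @export
top_k_markers <- function(V_hat, k = 100) {
  order(V_hat, decreasing = TRUE)[seq_len(min(k, length(V_hat)))]
}

#' Annotation enrichment profile
#'
#' For each annotation category, the fraction of its MAP-assigned markers
#' whose effect-size class is medium or large. The default aggregation uses
#' the modal class per marker over kept samples; `aggregate = "mean"`
#' instead averages the kept-sample frequency of medium/large membership.
#' Categories are returned sorted by decreasing enrichment.
#'
#' @param class_freq p x K matrix of kept-sample class-membership
#'   frequencies (columns null..large).
#' @param map_category MAP category per marker (from [paip_summary()]).
#' @param categories category names defining the output order/universe.
#' @param aggregate `"modal"` or `"mean"`.
#' @return data.frame with columns `category`, `n_markers`,
#'   `prop_medium_large`, `empty` (flag for categories with no markers).
#' @export
annotation_enrichment_profile <- function(class_freq, map_category,
                                          categories = sort(unique(map_category)),
                                          aggregate = c("modal", "mean")) {
  aggregate <- match.arg(aggregate)
  K <- ncol(class_freq)
  big <- seq_len(K) >= K - 1  # medium and large = top two classes
  val <- if (aggregate == "modal") {
    modal <- apply(class_freq, 1, which.max)
    as.numeric(big[modal])
  } else {
    rowSums(class_freq[, big, drop = FALSE])
  }
  out <- do.call(rbind, lapply(categories, function(cc) {
    sel <- map_category == cc
    data.frame(category = cc, n_markers = sum(sel),
               prop_medium_large = if (any(sel)) mean(val[sel]) else 0,
               empty = !any(sel))
  }))
  out[order(-out$prop_medium_large), , drop = FALSE]
}

#' Grouped cross-validation folds
#'
#' Builds k folds whose validation sets are unions of whole groups (e.g.,
#' sibling families defined by sire), so that no group straddles the
#' train/validation boundary. Groups are batched into folds in order of
#' first appearance; each individual appears in exactly one validation set.
#'
#' @param group_ids per-individual group labels.
#' @param k number of folds (must not exceed the number of groups).
#' @return list of `k` lists with `train` and `validation` index vectors.
#' @export
grouped_folds <- function(group_ids, k = 10) {
  groups <- unique(group_ids)
  if (k > length(groups))
    stop(sprintf("k = %d exceeds the %d available groups", k, length(groups)))
  batch <- rep(seq_len(k), length.out = length(groups))
  idx <- seq_along(group_ids)
  lapply(seq_len(k), function(fold) {
    val_groups <- groups[batch == fold]
    val <- idx[group_ids %in% val_groups]
    list(train = setdiff(idx, val), validation = val)
  })
}
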