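#' Genetic architecture configuration
#'
#' Defines the simulated trait architecture: 5 large-effect QTLs (each
#' explaining `k_large` of the additive variance, one of 1%, 2.5%, 5%),
#' 300 medium QTLs at 0.1% each, and small QTLs at 0.01% each filling the
#' remaining additive variance (6500/5750/4500 for the three `k_large`
#' settings). Phenotypic variance is 100, mean 0, heritability 0.2 or 0.5,
#' and QTLs are drawn among markers with MAF >= 0.15.
#'
#' Smaller maps can use a scaled architecture (e.g. `n_medium = 30`,
#' `k_small = 0.001`), with `n_small` always derived so the per-QTL
#' variance fractions sum to 1.
#'
#' @param n_large,k_large number and variance fraction of large QTLs.
#' @param n_medium,k_medium number and variance fraction of medium QTLs.
#' @param k_small variance fraction of small QTLs (count is derived).
#' @param h2 SNP heritability.
#' @param sigma_y2 phenotypic variance.
#' @param mu phenotypic mean.
#' @param qtl_maf_min minimum MAF for a marker to be eligible as a QTL.
#' @return a list of class `architecture_config` (with derived `n_small`
#'   and `sigma_g2`).
#' @export
architecture_config <- function(n_large = 5, k_large = 0.01, n_medium = 300,
                                k_medium = 0.001, k_small = 0.0001,
                                h2 = 0.5, sigma_y2 = 100, mu = 0,
                                qtl_maf_min = 0.15) {
  cfg <- list(n_large = n_large, k_large = k_large, n_medium = n_medium,
              k_medium = k_medium, k_small = k_small, h2 = h2,
              sigma_y2 = sigma_y2, mu = mu, qtl_maf_min = qtl_maf_min)
  class(cfg) <- "architecture_config"
  cfg$n_small <- compute_n_small(cfg)
  cfg$sigma_g2 <- h2 * sigma_y2
  cfg
}

#' Number of small-effect QTLs filling the residual additive variance
#'
#' `n_small = (1 - n_large k_large - n_medium k_medium) / k_small`, which
#' must be a non-negative integer (asserted to 1e-9): 6500, 5750 and 4500
#' for `k_large` = 1%, 2.5% and 5% under the default architecture.
#'
#' @param cfg an [architecture_config()] (or compatible list).
#' @return integer count of small QTLs.
#' @export
compute_n_small <- function(cfg) {
  rem <- 1 - cfg$n_large * cfg$k_large - cfg$n_medium * cfg$k_medium
  if (rem < -1e-12)
    stop("configuration error: large+medium QTLs exceed the additive variance")
  ns <- rem / cfg$k_small
  if (abs(ns - round(ns)) > 1e-9)
    stop(sprintf("configuration error: n_small = %.12f is not an integer", ns))
  as.integer(round(ns))
}

#' Simulate biallelic genotypes with local LD
#'
#' Haplotypes are generated per chromosome from a stationary Gaussian
#' copula: a latent AR(1) process with autocorrelation `ld_rho` is
#' thresholded at the quantile of each marker's target allele frequency
#' (drawn uniformly from `maf_range`), giving exact marginal frequencies
#' and adjacent-marker LD that increases monotonically with `ld_rho`.
#' Genotypes are the sum of two independent haplotypes.
#'
#' @param n number of individuals.
#' @param p number of markers.
#' @param n_chrom number of chromosomes (markers split into contiguous
#'   blocks).
#' @param ld_rho latent autocorrelation in `[0, 1)`.
#' @param maf_range target allele-frequency interval, inside (0, 0.5].
#' @param seed integer seed.
#' @return a [raw_genotypes()] object (no missing calls).
#' @export
simulate_genotypes <- function(n, p, n_chrom = 10, ld_rho = 0.7,
                               maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(ld_rho >= 0, ld_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  set.seed(seed)
  f <- stats::runif(p, maf_range[1], maf_range[2])
  chrom <- sort(rep_len(seq_len(n_chrom), p))
  H <- matrix(0L, 2 * n, p)
  thr <- stats::qnorm(f)
  for (chr in seq_len(n_chrom)) {
    idx <- which(chrom == chr)
    z <- stats::rnorm(2 * n)
    H[, idx[1]] <- as.integer(z < thr[idx[1]])
    if (length(idx) > 1) {
      sd_innov <- sqrt(1 - ld_rho^2)
      for (j in idx[-1]) {
        z <- ld_rho * z + sd_innov * stats::rnorm(2 * n)
        H[, j] <- as.integer(z < thr[j])
      }
    }
  }
  w <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  pos <- stats::ave(seq_len(p), chrom, FUN = seq_along) * 1000L
  map <- marker_map(paste0("snp_", seq_len(p)), as.character(chrom), pos)
  raw_genotypes(w, map = map)
}

#' Select QTL index sets
#'
#' Samples disjoint sets of large, medium and small QTLs uniformly without
#' replacement among markers with MAF at or above the eligibility floor.
#'
#' @param f allele frequencies.
#' @param cfg an [architecture_config()].
#' @param seed integer seed.
#' @return list of class `true_effects` with index vectors `large`,
#'   `medium`, `small`, the non-QTL `null` markers, and `p`.
#' @export
select_qtls <- function(f, cfg, seed = 1L) {
  maf <- pmin(f, 1 - f)
  eligible <- which(maf >= cfg$qtl_maf_min)
  need <- cfg$n_large + cfg$n_medium + cfg$n_small
  if (length(eligible) < need)
    stop(sprintf("insufficient eligible markers: need %d, have %d (short %d)",
                 need, length(eligible), need - length(eligible)))
  set.seed(seed)
  pick <- sample(eligible, need)
  out <- list(large = pick[seq_len(cfg$n_large)],
              medium = pick[cfg$n_large + seq_len(cfg$n_medium)],
              small = pick[cfg$n_large + cfg$n_medium + seq_len(cfg$n_small)],
              p = length(f))
  out$null <- setdiff(seq_along(f), c(out$large, out$medium, out$small))
  class(out) <- "true_effects"
  out
}

#' Simulate true SNP effects
#'
#' Sets `beta_i = u_i sqrt(k sigma_g^2 / (2 f_i (1 - f_i)))` for each QTL,
#' with `u_i` uniform on \{-1, +1\}, so the explained variance of every QTL
#' of a class equals `k sigma_g^2` exactly regardless of its frequency, and
#' the explained variances sum to `sigma_g^2`. `literal = TRUE` applies an
#' additional 1/2 factor (an alternative parameterization under which the
#' summed explained variance is `sigma_g^2 / 4`); the default preserves the
#' variance bookkeeping exactly.
#'
#' @param qtls a `true_effects` set from [select_qtls()].
#' @param f allele frequencies.
#' @param cfg an [architecture_config()].
#' @param seed integer seed (signs).
#' @param literal apply the 1/2 factor (audit mode).
#' @return numeric length-p vector of true effects on the allele-count
#'   scale; sign vector in attribute `"u"`.
#' @export
simulate_effects <- function(qtls, f, cfg, seed = 1L, literal = FALSE) {
  beta <- numeric(qtls$p)
  set.seed(seed)
  fac <- if (literal) 0.5 else 1
  for (cls in c("large", "medium", "small")) {
    k <- cfg[[paste0("k_", cls)]]
    idx <- qtls[[cls]]
    if (length(idx) == 0) next
    fi <- f[idx]
    if (any(fi <= 0 | fi >= 1)) stop("QTL with degenerate frequency")
    u <- sample(c(-1, 1), length(idx), replace = TRUE)
    beta[idx] <- fac * u * sqrt(k * cfg$sigma_g2 / (2 * fi * (1 - fi)))
  }
  u_all <- sign(beta)
  attr(beta, "u") <- u_all
  beta
}

#' Simulate phenotypes
#'
#' `y = mu + w beta + e` on the raw allele-count scale, with
#' `e ~ N(0, sigma_y^2 (1 - h^2))`.
#'
#' @param g a [raw_genotypes()] object.
#' @param beta true effect vector (allele-count scale).
#' @param cfg an [architecture_config()].
#' @param seed integer seed (noise).
#' @return numeric phenotype vector.
#' @export
simulate_phenotypes <- function(g, beta, cfg, seed = 1L) {
  se2 <- cfg$sigma_y2 * (1 - cfg$h2)
  if (se2 < 0) stop("h2 must not exceed 1")
  set.seed(seed)
  drop(cfg$mu + g$w %*% beta + stats::rnorm(nrow(g$w), 0, sqrt(se2)))
}

# Seed counts per enrichment level: large / medium / low-or-null markers.
.enrichment_recipes <- list(
  strongly   = c(large = 5, medium = 300, lownull = 150),
  moderately = c(large = 2, medium = 100, lownull = 300),
  weakly     = c(large = 0, medium = 20,  lownull = 400),
  unenriched = c(large = 0, medium = 0,   lownull = 450))

# Annotations per scenario, by enrichment level.
.scenario_recipes <- list(
  A = c(strongly = 1, moderately = 1, weakly = 0, unenriched = 0),
  B = c(strongly = 1, moderately = 1, weakly = 1, unenriched = 1),
  C = c(strongly = 0, moderately = 2, weakly = 1, unenriched = 1),
  D = c(strongly = 2, moderately = 2, weakly = 3, unenriched = 2))

#' Build one enriched annotation column
#'
#' Samples seed markers according to the enrichment recipe (e.g. strongly
#' enriched: 5 large + 300 medium + 150 low/null) and includes each seed
#' plus its immediate up- and downstream neighbors (truncated at chromosome
#' ends). Large and medium seeds are sampled without replacement within the
#' annotation but may be reused across annotations (there are only 5 large
#' QTLs in total, so e.g. two strongly enriched annotations necessarily
#' share them). Low/null seeds are drawn from the pooled small-effect QTLs
#' and null markers. On a full-scale map each annotation covers roughly
#' 1200-1400 markers.
#'
#' @param level `"strongly"`, `"moderately"`, `"weakly"` or `"unenriched"`.
#' @param qtls a `true_effects` set.
#' @param map a [marker_map()].
#' @param seed integer seed.
#' @param scale scaling factor applied to the medium and low/null seed
#'   counts (for reduced maps); large counts are capped at the available
#'   large QTLs.
#' @return integer vector of member marker indices, with attribute
#'   `"seeds"` (list of seed indices by class).
#' @export
build_enriched_annotation <- function(level = c("strongly", "moderately",
                                                "weakly", "unenriched"),
                                      qtls, map, seed = 1L, scale = 1) {
  level <- match.arg(level)
  recipe <- .enrichment_recipes[[level]]
  n_large <- min(recipe["large"], length(qtls$large))
  if (recipe["large"] > length(qtls$large) && scale >= 1)
    stop(sprintf("recipe demands %d large QTLs but only %d exist",
                 recipe["large"], length(qtls$large)))
  n_medium <- round(recipe["medium"] * scale)
  n_lownull <- round(recipe["lownull"] * scale)
  if (n_medium > length(qtls$medium))
    stop("recipe demands more medium QTLs than exist")
  pool <- c(qtls$small, qtls$null)
  set.seed(seed)
  seeds <- list(
    large = if (n_large > 0) sample(qtls$large, n_large) else integer(0),
    medium = if (n_medium > 0) sample(qtls$medium, n_medium) else integer(0),
    lownull = if (n_lownull > 0) sample(pool, n_lownull) else integer(0))
  all_seeds <- unlist(seeds, use.names = FALSE)
  members <- sort(unique(c(all_seeds, .map_neighbors(map, all_seeds))))
  attr(members, "seeds") <- seeds
  members
}

# immediate up/downstream neighbors in map order, same chromosome
.map_neighbors <- function(map, idx) {
  chrom <- map$chromosome
  p <- nrow(map)
  lo <- idx - 1L; hi <- idx + 1L
  lo_ok <- lo >= 1L & chrom[pmax(lo, 1L)] == chrom[idx]
  hi_ok <- hi <= p & chrom[pmin(hi, p)] == chrom[idx]
  c(lo[lo_ok], hi[hi_ok])
}

#' Build a scenario annotation set
#'
#' Combines enriched annotations per the scenario recipe (A: one strongly +
#' one moderately enriched; B: one of each level; C: two moderately + one
#' weakly + one unenriched; D: nine annotations of mixed levels), appends
#' the `"other"` category, and records the ground-truth seed content.
#'
#' @param scenario `"A"`, `"B"`, `"C"` or `"D"`.
#' @param qtls a `true_effects` set.
#' @param map a [marker_map()].
#' @param seed integer seed (one sub-seed per annotation).
#' @param scale seed-count scaling for reduced maps (see
#'   [build_enriched_annotation()]).
#' @return an [annotation_set()] with attribute `"truth"`: a list per
#'   annotation of its enrichment level and seed indices by class.
#' @export
build_scenario <- function(scenario = c("A", "B", "C", "D"), qtls, map,
                           seed = 1L, scale = 1) {
  scenario <- match.arg(scenario)
  recipe <- .scenario_recipes[[scenario]]
  p <- nrow(map)
  cols <- list(); truth <- list()
  k <- 0L
  for (level in names(recipe)) {
    for (r in seq_len(recipe[[level]])) {
      k <- k + 1L
      nm <- paste0(level, "_", r)
      members <- build_enriched_annotation(level, qtls, map,
                                           seed = seed + 1000L * k,
                                           scale = scale)
      col <- integer(p); col[members] <- 1L
      cols[[nm]] <- col
      truth[[nm]] <- c(list(level = level), attr(members, "seeds"))
    }
  }
  a <- annotation_set(do.call(cbind, cols))
  attr(a, "truth") <- truth
  a
}

#' Deterministic train/validation split
#'
#' Splits individuals by order (standing in for an age ordering): the first
#' `floor(n * fraction)` form the training set, the rest the validation set.
#'
#' @param n number of individuals.
#' @param fraction training fraction in (0, 1).
#' @return list with `train` and `validation` index vectors.
#' @export
train_validation_split <- function(n, fraction = 0.8) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  n_train <- floor(n * fraction)
  list(train = seq_len(n_train), validation = seq(n_train + 1, n))
}

#' Simulate a complete dataset
#'
#' Convenience pipeline: genotypes, QTL selection, effects, phenotypes, and
#' (optionally) a scenario annotation set. One master seed fans out to named
#' sub-streams so components can be varied independently.
#'
#' @param n,p,n_chrom,ld_rho,maf_range genotype simulation settings (see
#'   [simulate_genotypes()]).
#' @param cfg an [architecture_config()].
#' @param scenario optional scenario letter (`NULL` for no annotations).
#' @param scale annotation seed-count scaling.
#' @param seed master seed.
#' @return list of class `simulated_dataset`: `genotypes`, `f`, `qtls`,
#'   `beta`, `y`, `annotations` (or NULL), `cfg`.
#' @export
simulate_dataset <- function(n, p, cfg = architecture_config(),
                             n_chrom = 10, ld_rho = 0.7,
                             maf_range = c(0.05, 0.5), scenario = NULL,
                             scale = 1, seed = 1L) {
  set.seed(seed)
  sub <- sample.int(10^7, 5)
  g <- simulate_genotypes(n, p, n_chrom, ld_rho, maf_range, seed = sub[1])
  f <- allele_frequencies(g)
  qtls <- select_qtls(f, cfg, seed = sub[2])
  beta <- simulate_effects(qtls, f, cfg, seed = sub[3])
  y <- simulate_phenotypes(g, beta, cfg, seed = sub[4])
  ann <- if (!is.null(scenario))
    build_scenario(scenario, qtls, g$map, seed = sub[5], scale = scale)
  out <- list(genotypes = g, f = f, qtls = qtls, beta = beta, y = y,
              annotations = ann, cfg = cfg, seed = seed)
  class(out) <- "simulated_dataset"
  out
}
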