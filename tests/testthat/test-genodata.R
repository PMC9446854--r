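test_that("text genotype round-trip reproduces counts and map exactly", {
  g <- toy_genotypes(10, 20)
  prefix <- file.path(withr::local_tempdir(), "g")
  write_genotypes(g, prefix)
  g2 <- suppressMessages(read_genotypes(prefix, "text"))
  expect_identical(unname(g2$w), unname(g$w))
  expect_equal(g2$map$position, g$map$position)
  expect_equal(g2$map$chromosome, g$map$chromosome)

  # direct read-back of a hand-written matrix
  writeLines(c("0 1 2", "2 1 0"), paste0(prefix, "2.geno"))
  g3 <- suppressMessages(read_genotypes(paste0(prefix, "2"), "text"))
  expect_equal(g3$w[1, 3], 2)
  expect_equal(g3$w[2, 1], 2)

  # empty file and ragged rows are format errors
  writeLines(character(0), paste0(prefix, "3.geno"))
  expect_error(suppressMessages(read_genotypes(paste0(prefix, "3"), "text")),
               "empty")
  writeLines(c("0 1 2", "2 1"), paste0(prefix, "4.geno"))
  expect_error(suppressMessages(read_genotypes(paste0(prefix, "4"), "text")),
               "ragged")
  expect_error(raw_genotypes(matrix(c(0, 3), 1)), "not in \\{0,1,2")
})

test_that("plink bed round-trip reproduces counts for awkward n", {
  for (n in c(7, 8, 9)) {   # exercise byte-padding boundaries
    g <- toy_genotypes(n, 13, seed = n)
    g$w[1, 2] <- NA  # missing call survives the trip
    prefix <- file.path(withr::local_tempdir(), "p")
    write_plink_bed(g, prefix)
    g2 <- suppressMessages(read_genotypes(prefix, "plink-bed"))
    expect_identical(unname(g2$w), unname(g$w))
  }
  # corrupted magic bytes
  prefix <- file.path(withr::local_tempdir(), "bad")
  g <- toy_genotypes(5, 4)
  write_plink_bed(g, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  raw[1] <- as.raw(0)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(suppressMessages(read_genotypes(prefix, "plink-bed")),
               "magic")
})

test_that("allele frequencies average allele counts over the subset", {
  g <- raw_genotypes(cbind(c(0, 1, 2, 1), c(0, 0, 0, 0), c(2, 2, 1, 1)))
  f <- allele_frequencies(g)
  expect_equal(unname(f), c(0.5, 0, 0.75))
  expect_equal(unname(allele_frequencies(g, individuals = 1:2)),
               c(0.25, 0, 1))
  g$w[, 2] <- NA
  expect_error(allele_frequencies(g), "entirely missing")
})

test_that("MAF filter drops below-threshold markers, keeps the boundary", {
  w <- matrix(1, 4, 3)
  g <- raw_genotypes(w)
  f <- c(0.009, 0.010, 0.995)
  kept <- suppressMessages(filter_maf(g, f, 0.01))
  expect_equal(kept$map$marker_id, "snp_2")  # min(f,1-f): .009 / .010 / .005
  expect_equal(kept$map$index, 1L)
  expect_length(attr(kept, "removed"), 2)
  # threshold 0 is the identity
  expect_equal(ncol(suppressMessages(filter_maf(g, f, 0))$w), 3)
  expect_error(suppressMessages(filter_maf(g, f, 0.2)), "all markers removed")
})

test_that("center_scale matches the closed form and imputes missing to 0", {
  g <- raw_genotypes(matrix(c(0, 1, 2, 1), 4, 1))
  X <- center_scale(g, 0.5)$X
  expect_equal(drop(X), c(-sqrt(2), 0, sqrt(2), 0))
  expect_error(center_scale(g, 0), "monomorphic")

  g <- toy_genotypes(50, 10, seed = 3)
  f <- allele_frequencies(g)
  std <- center_scale(g, f)
  expect_lt(max(abs(colMeans(std$X))), 1e-12)
  v_indep <- colSums(sweep(g$w, 2, 2 * f)^2) / (nrow(g$w) * 2 * f * (1 - f))
  expect_lt(max(abs(apply(std$X, 2, function(x) sum(x^2) / length(x)) -
                    v_indep)), 1e-12)

  g$w[3, 4] <- NA
  std2 <- suppressMessages(center_scale(g, f))
  expect_equal(std2$X[3, 4], 0)
})

test_that("annotation reading materializes 'other' and round-trips", {
  d <- withr::local_tempdir()
  path <- file.path(d, "a.txt")
  writeLines(c("a b", "1 0", "1 1", "0 0"), path)
  a <- read_annotations(path, 3)
  cs <- marker_categories(a)
  expect_equal(cs[[1]], "a")
  expect_equal(cs[[2]], c("a", "b"))
  expect_equal(cs[[3]], "other")
  expect_true(all(rowSums(a$A) >= 1))
  # all-zero matrix: everything in "other"
  writeLines(c("a b", "0 0", "0 0"), path)
  a0 <- read_annotations(path, 2)
  expect_equal(unname(a0$A[, "other"]), c(1L, 1L))
  expect_error(read_annotations(path, 5), "dimension")
  # round trip
  set.seed(1)
  A <- matrix(rbinom(40, 1, 0.4), 10, 4,
              dimnames = list(NULL, c("w", "x", "y", "z")))
  a1 <- annotation_set(A)
  write_annotations(a1, path)
  a2 <- read_annotations(path, 10)
  expect_identical(a2$A, a1$A)
})

test_that("window strategies expand hits as regular/hard/fuzzy prescribe", {
  map <- five_marker_map()
  hits <- data.frame(category = "cat", chromosome = "1", position = 300)
  reg <- build_window_annotations(map, hits, "regular")
  expect_equal(which(reg$A[, "cat"] == 1), 3)
  hard <- build_window_annotations(map, hits, "hard")
  expect_equal(which(hard$A[, "cat"] == 1), 2:4)
  expect_equal(unname(hard$A[2:4, "other"]), rep(0L, 3))
  fuz <- build_window_annotations(map, hits, "fuzzy")
  expect_equal(marker_categories(fuz)[[3]], "cat")
  expect_setequal(marker_categories(fuz)[[2]], c("cat", "other"))
  expect_setequal(marker_categories(fuz)[[4]], c("cat", "other"))
  expect_equal(marker_categories(fuz)[[1]], "other")
  expect_equal(marker_categories(fuz)[[5]], "other")

  # chromosome ends truncate windows; unmatched hits are skipped
  hits2 <- data.frame(category = "cat", chromosome = "1",
                      position = c(100, 999))
  h2 <- suppressWarnings(build_window_annotations(map, hits2, "hard"))
  expect_equal(which(h2$A[, "cat"] == 1), 1:2)
  expect_equal(attr(h2, "skipped"), 1L)
  expect_warning(build_window_annotations(map, hits2, "hard"), "skipped")
})

test_that("hard windows contain the regular annotation per category", {
  map <- marker_map(paste0("m", 1:40), rep(c("1", "2"), each = 20),
                    rep(seq(100, 2000, by = 100), 2))
  set.seed(4)
  hits <- data.frame(category = sample(c("u", "v"), 8, TRUE),
                     chromosome = sample(c("1", "2"), 8, TRUE),
                     position = sample(seq(100, 2000, by = 100), 8))
  reg <- build_window_annotations(map, hits, "regular")
  hard <- build_window_annotations(map, hits, "hard")
  for (cc in c("u", "v"))
    expect_true(all(hard$A[reg$A[, cc] == 1, cc] == 1))
})

test_that("downsampling overlaps yields a disjoint set within the support", {
  A <- cbind(a = c(1, 1, 0, 1), b = c(1, 0, 1, 1), c = c(1, 1, 1, 0))
  a <- annotation_set(A)
  d1 <- downsample_overlaps(a, seed = 9)
  expect_true(is_disjoint(d1))
  # retained category always lies in the original set
  expect_true(all(d1$A[a$A == 0] == 0))
  # deterministic given the seed
  d2 <- downsample_overlaps(a, seed = 9)
  expect_identical(d1$A, d2$A)
  # already-disjoint input is unchanged
  dd <- annotation_set(cbind(a = c(1, 0), b = c(0, 1)))
  expect_identical(downsample_overlaps(dd, 1)$A, dd$A)
})

test_that("downsampling picks uniformly among a marker's categories", {
  p <- 10000
  a <- annotation_set(cbind(a = rep(1L, p), b = rep(1L, p)))
  d <- downsample_overlaps(a, seed = 21)
  frac_a <- mean(d$A[, "a"])
  se <- sqrt(0.25 / p)
  expect_lt(abs(frac_a - 0.5), 3 * se)
})

test_that("overlap report matches an independent histogram", {
  map <- five_marker_map()
  hits <- data.frame(category = "cat", chromosome = "1", position = 300)
  fuz <- build_window_annotations(map, hits, "fuzzy")
  rep_ <- overlap_report(fuz)
  expect_equal(attr(rep_, "fraction_multi"), 0.4)  # 2 of 5 markers

  set.seed(8)
  A <- matrix(rbinom(300, 1, 0.3), 100, 3)
  a <- annotation_set(A)
  rep2 <- overlap_report(a)
  hist_oracle <- table(rowSums(a$A))
  expect_equal(rep2$n_markers, as.integer(hist_oracle))
  expect_equal(sum(rep2$n_markers), 100)
  # disjoint set: all markers carry exactly one annotation
  dd <- downsample_overlaps(a, 3)
  expect_equal(overlap_report(dd)$fraction, 1)
})
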