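#' Annotation set constructor
#'
#' A p x m binary membership matrix over annotation categories, with
#' overlaps allowed. Markers belonging to no category are placed in an
#' `"other"` category, which is always materialized as an explicit column so
#' that every marker carries at least one annotation.
#'
#' @param A binary matrix (p x m), column names used as category names.
#' @param category_names optional character vector overriding colnames.
#' @param other name of the catch-all category (default `"other"`).
#' @return an object of class `annotation_set` with fields `A` and
#'   `category_names`.
#' @export
annotation_set <- function(A, category_names = NULL, other = "other") {
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("annotation entries must be 0 or 1")
  storage.mode(A) <- "integer"
  if (is.null(category_names)) category_names <- colnames(A)
  if (is.null(category_names))
    category_names <- paste0("annot_", seq_len(ncol(A)))
  if (length(category_names) != ncol(A))
    stop("category_names length mismatch")
  if (!other %in% category_names) {
    A <- cbind(A, 0L)
    category_names <- c(category_names, other)
  }
  oc <- which(category_names == other)
  none <- rowSums(A) == 0
  A[none, oc] <- 1L
  colnames(A) <- category_names
  structure(list(A = A, category_names = category_names, other = other),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d markers x %d categories (%s); %d multi-annotated\n",
              nrow(x$A), ncol(x$A), paste(x$category_names, collapse = ", "),
              sum(rowSums(x$A) >= 2)))
  invisible(x)
}

#' Per-marker annotation sets
#'
#' @param a an [annotation_set()].
#' @return list of character vectors, the categories of each marker.
#' @export
marker_categories <- function(a) {
  apply(a$A, 1, function(r) a$category_names[r == 1], simplify = FALSE)
}

#' Is the annotation set disjoint?
#'
#' @param a an [annotation_set()].
#' @return TRUE if every marker has exactly one category.
#' @export
is_disjoint <- function(a) all(rowSums(a$A) == 1)

#' Read an annotation matrix
#'
#' Whitespace-delimited p x m 0/1 matrix with one header row of category
#' names. An `"other"` column is appended/filled so every marker has at
#' least one category.
#'
#' @param path file path.
#' @param p expected marker count.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, p) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) != p)
    stop(sprintf("dimension error: %d annotation rows for %d markers",
                 nrow(tab), p))
  A <- as.matrix(tab)
  if (!all(A %in% c(0, 1)))
    stop("validation error: annotation entries must be 0 or 1")
  annotation_set(A, colnames(tab))
}

#' Write an annotation matrix
#'
#' @param a an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(a, path) {
  utils::write.table(a$A, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build annotations from QTL-hit positions with window strategies
#'
#' Matches hits to markers by exact (chromosome, position) equality, then
#' expands according to the strategy. Neighbors are adjacent markers in map
#' order on the same chromosome; windows truncate at chromosome ends.
#'
#' * `regular`: only the hit marker carries the category.
#' * `hard`: the hit marker and its nearest up- and downstream neighbors all
#'   carry the category (neighbors do not keep `"other"`).
#' * `fuzzy`: the hit marker carries the category; each neighbor carries both
#'   the category and `"other"` (ambiguous assignment), unless it is itself a
#'   hit marker for some category.
#'
#' @param map a [marker_map()].
#' @param hits data.frame with columns `category`, `chromosome`, `position`.
#' @param strategy one of `"regular"`, `"hard"`, `"fuzzy"`.
#' @return an [annotation_set()]; unmatched hits are counted in the
#'   attribute `"skipped"` (with a warning).
#' @export
build_window_annotations <- function(map, hits,
                                     strategy = c("regular", "hard", "fuzzy")) {
  strategy <- match.arg(strategy)
  stopifnot(all(c("category", "chromosome", "position") %in% names(hits)))
  p <- nrow(map)
  cats <- unique(as.character(hits$category))
  A <- matrix(0L, p, length(cats), dimnames = list(NULL, cats))
  fuzzy_other <- logical(p)
  is_seed <- logical(p)
  key <- paste(map$chromosome, map$position, sep = ":")
  skipped <- 0L
  for (h in seq_len(nrow(hits))) {
    i <- match(paste(hits$chromosome[h], hits$position[h], sep = ":"), key)
    if (is.na(i)) { skipped <- skipped + 1L; next }
    is_seed[i] <- TRUE
    c_ <- as.character(hits$category[h])
    A[i, c_] <- 1L
    if (strategy != "regular") {
      same_chr <- which(map$chromosome == map$chromosome[i])
      pos_in_chr <- match(i, same_chr)
      nb <- same_chr[c(pos_in_chr - 1, pos_in_chr + 1)]
      nb <- nb[!is.na(nb)]
      A[nb, c_] <- 1L
      if (strategy == "fuzzy") fuzzy_other[nb] <- TRUE
    }
  }
  if (skipped > 0)
    warning(skipped, " hit(s) had no matching marker and were skipped")
  a <- annotation_set(A)
  if (strategy == "fuzzy") {
    oc <- which(a$category_names == a$other)
    a$A[fuzzy_other & !is_seed, oc] <- 1L
  }
  attr(a, "skipped") <- skipped
  a
}

#' Down-sample overlapping annotations to a disjoint set
#'
#' For each multi-annotated marker, retains a single category drawn
#' uniformly from its annotation set (the naive work-around needed to run
#' BayesRC on overlapping annotations). Deterministic given `seed`.
#'
#' @param a an [annotation_set()].
#' @param seed integer seed.
#' @return a disjoint [annotation_set()] with the same categories.
#' @export
downsample_overlaps <- function(a, seed = 1L) {
  A <- a$A
  multi <- which(rowSums(A) > 1)
  if (length(multi) > 0) {
    rng <- local({ set.seed(seed); lapply(multi, function(i) {
      cs <- which(A[i, ] == 1)
      cs[sample.int(length(cs), 1)]
    }) })
    for (k in seq_along(multi)) {
      A[multi[k], ] <- 0L
      A[multi[k], rng[[k]]] <- 1L
    }
  }
  annotation_set(A, a$category_names, other = a$other)
}

#' Overlap report
#'
#' Tabulates markers by the number of annotations they carry (the catch-all
#' `"other"` category counts like any other, so markers in `"other"` alone
#' appear under k = 1 and never in the multi-annotated tally).
#'
#' @param a an [annotation_set()].
#' @return data.frame with columns `n_annotations`, `n_markers`, `fraction`,
#'   plus attribute `"fraction_multi"`.
#' @export
overlap_report <- function(a) {
  k <- rowSums(a$A)
  tab <- table(k)
  out <- data.frame(n_annotations = as.integer(names(tab)),
                    n_markers = as.integer(tab),
                    fraction = as.numeric(tab) / nrow(a$A))
  attr(out, "fraction_multi") <- mean(k >= 2)
  out
}
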