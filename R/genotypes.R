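#' Marker map constructor
#'
#' A marker map records, for each genotyped marker, its identifier,
#' chromosome, 1-based base-pair position, and its (1-based) column index in
#' the genotype matrix. Within a chromosome, positions must be
#' non-decreasing; marker order in the map defines the "immediate neighbor"
#' relation used by window-based annotation construction.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chromosome character (or coercible) chromosome labels.
#' @param position integer base-pair positions (1-based).
#' @param index optional integer column indices (defaults to `1:p`).
#' @return a `data.frame` of class `marker_map`.
#' @export
marker_map <- function(marker_id, chromosome, position, index = NULL) {
  p <- length(marker_id)
  if (is.null(index)) index <- seq_len(p)
  if (anyDuplicated(marker_id)) stop("marker_ids must be unique")
  if (!setequal(index, seq_len(p))) stop("indices must be a permutation of 1..p")
  mm <- data.frame(marker_id = as.character(marker_id),
                   chromosome = as.character(chromosome),
                   position = as.integer(position),
                   index = as.integer(index),
                   stringsAsFactors = FALSE)
  for (chr in unique(mm$chromosome)) {
    pos <- mm$position[mm$chromosome == chr]
    if (is.unsorted(pos)) stop("positions must be non-decreasing within chromosome ", chr)
  }
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' Raw genotype container
#'
#' Holds an n x p matrix `w` of alternative-allele counts in \{0, 1, 2\}
#' (NA allowed for missing calls), individual identifiers, and a marker map.
#'
#' @param w integer/numeric matrix of allele counts.
#' @param individual_ids character vector (defaults to `ind_1..ind_n`).
#' @param map a [marker_map()]; defaults to a single-chromosome map.
#' @return an object of class `raw_genotypes`.
#' @export
raw_genotypes <- function(w, individual_ids = NULL, map = NULL) {
  w <- as.matrix(w)
  storage.mode(w) <- "double"
  bad <- !is.na(w) & !(w %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("genotype entry not in {0,1,2,NA} at row %d, column %d",
                 idx[1], idx[2]))
  }
  n <- nrow(w); p <- ncol(w)
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(n))
  if (length(individual_ids) != n) stop("individual_ids length mismatch")
  if (is.null(map)) {
    map <- marker_map(paste0("snp_", seq_len(p)), rep("1", p), seq_len(p))
  }
  if (nrow(map) != p) stop("map rows do not match genotype columns")
  structure(list(w = w, individual_ids = as.character(individual_ids),
                 map = map),
            class = "raw_genotypes")
}

#' @export
print.raw_genotypes <- function(x, ...) {
  cat(sprintf("raw_genotypes: %d individuals x %d markers (%d chromosomes), %d missing calls\n",
              nrow(x$w), ncol(x$w), length(unique(x$map$chromosome)),
              sum(is.na(x$w))))
  invisible(x)
}

#' Read genotypes from disk
#'
#' Two dialects are supported: `"text"`, a whitespace-delimited n x p matrix
#' of 0/1/2 counts (NA for missing) at `<prefix>.geno` with a 4-column map
#' (`marker_id chromosome position index`, with header) at `<prefix>.map`;
#' and `"plink-bed"`, the PLINK1 binary triple `<prefix>.bed/.bim/.fam`
#' (SNP-major only). For PLINK input, `w` counts copies of the A1 allele
#' (fifth .bim column).
#'
#' @param prefix file path prefix.
#' @param dialect `"text"` or `"plink-bed"`.
#' @return a [raw_genotypes()] object.
#' @export
read_genotypes <- function(prefix, dialect = c("text", "plink-bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") {
    gfile <- paste0(prefix, ".geno"); mfile <- paste0(prefix, ".map")
    if (!file.exists(gfile)) stop("genotype file not found: ", gfile)
    lines <- readLines(gfile)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("format error: empty genotype file ", gfile)
    rows <- strsplit(trimws(lines), "\\s+")
    p <- length(rows[[1]])
    ok <- vapply(rows, length, 1L) == p
    if (!all(ok))
      stop(sprintf("format error in %s: ragged row at line %d", gfile,
                   which(!ok)[1]))
    w <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                nrow = length(rows), ncol = p, byrow = TRUE)
    map <- if (file.exists(mfile)) {
      md <- utils::read.table(mfile, header = TRUE, stringsAsFactors = FALSE)
      marker_map(md$marker_id, md$chromosome, md$position, md$index)
    } else NULL
    g <- raw_genotypes(w, map = map)
  } else {
    g <- read_plink_bed(prefix)
  }
  message(sprintf("read %d individuals x %d markers from %s (%s)",
                  nrow(g$w), ncol(g$w), prefix, dialect))
  g
}

#' Write genotypes to disk (text dialect)
#'
#' Writes `<prefix>.geno` and `<prefix>.map` in the format read by
#' [read_genotypes()].
#'
#' @param g a [raw_genotypes()] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(g, prefix) {
  utils::write.table(g$w, paste0(prefix, ".geno"), row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(as.data.frame(unclass(g$map))[
                       c("marker_id", "chromosome", "position", "index")],
                     paste0(prefix, ".map"), row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

# PLINK1 .bed/.bim/.fam reader (SNP-major). Codes: 00 = 2 copies of A1,
# 10 = 1 copy, 11 = 0 copies, 01 = missing.
read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)
  bimd <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  famd <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  p <- nrow(bimd); n <- nrow(famd)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error: bad magic bytes in ", bed)
  if (raw[3] != as.raw(0x01))
    stop("format error: only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)
  if (length(raw) != 3 + bpm * p)
    stop("format error: .bed size inconsistent with .bim/.fam dimensions")
  body <- raw[-(1:3)]
  # unpack 2-bit codes: bits() gives little-endian bits per byte
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  codes <- bits[seq(1, 8, 2), , drop = FALSE] +
           2L * bits[seq(2, 8, 2), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = 4 * bpm)[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0)  # codes 0b00, 0b01, 0b10, 0b11
  w <- matrix(lookup[codes + 1L], nrow = n, ncol = p)
  map <- marker_map(bimd[[2]], bimd[[1]], bimd[[4]])
  raw_genotypes(w, individual_ids = as.character(famd[[2]]), map = map)
}

#' Write a PLINK1 .bed/.bim/.fam triple (SNP-major)
#'
#' @param g a [raw_genotypes()] object; `w` is written as copies of A1.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_bed <- function(g, prefix) {
  n <- nrow(g$w); p <- ncol(g$w)
  code <- matrix(0L, nrow = 4 * ceiling(n / 4), ncol = p)  # pad bits stay 0
  enc <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  code[seq_len(n), ] <- ifelse(is.na(g$w), 1L, enc[as.character(g$w)])
  lo <- code %% 2L; hi <- code %/% 2L
  bits <- matrix(0L, nrow = 8, ncol = ceiling(n / 4) * p)
  bits[seq(1, 8, 2), ] <- matrix(lo, nrow = 4)
  bits[seq(2, 8, 2), ] <- matrix(hi, nrow = 4)
  body <- packBits(as.integer(bits) > 0, type = "raw")
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), body), paste0(prefix, ".bed"))
  utils::write.table(
    data.frame(g$map$chromosome, g$map$marker_id, 0, g$map$position, "A", "B"),
    paste0(prefix, ".bim"), row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(g$individual_ids, g$individual_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Alternative-allele frequencies
#'
#' Computes `f_j = mean(w[, j]) / 2` over non-missing entries of the selected
#' individuals.
#'
#' @param g a [raw_genotypes()] object.
#' @param individuals optional integer/logical row selector (default: all).
#' @return numeric vector of length p.
#' @export
allele_frequencies <- function(g, individuals = NULL) {
  w <- g$w
  if (!is.null(individuals)) w <- w[individuals, , drop = FALSE]
  if (nrow(w) == 0) stop("empty individual subset")
  nn <- colSums(!is.na(w))
  if (any(nn == 0))
    stop("marker(s) entirely missing in subset: ",
         paste(g$map$marker_id[nn == 0], collapse = ", "))
  colMeans(w, na.rm = TRUE) / 2
}

#' Filter markers on minor allele frequency
#'
#' Retains markers with `min(f, 1 - f) >= threshold` (markers exactly at the
#' threshold are kept) and re-indexes the map. A removed-marker report is
#' attached as attribute `"removed"`.
#'
#' @param g a [raw_genotypes()] object.
#' @param f allele frequencies (from [allele_frequencies()]).
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return a filtered [raw_genotypes()] object.
#' @export
filter_maf <- function(g, f, threshold = 0.01) {
  if (threshold < 0 || threshold > 0.5) stop("threshold must be in [0, 0.5]")
  maf <- pmin(f, 1 - f)
  keep <- maf >= threshold
  if (!any(keep)) stop("all markers removed by the MAF filter")
  removed <- g$map$marker_id[!keep]
  message(sprintf("MAF filter at %g removed %d of %d markers",
                  threshold, sum(!keep), length(keep)))
  map <- g$map[keep, , drop = FALSE]
  map$index <- seq_len(sum(keep))
  rownames(map) <- NULL
  out <- raw_genotypes(g$w[, keep, drop = FALSE], g$individual_ids,
                       marker_map(map$marker_id, map$chromosome,
                                  map$position, map$index))
  attr(out, "removed") <- removed
  out
}

#' Center and scale genotypes
#'
#' Standardizes allele counts as `X_ij = (w_ij - 2 f_j) / sqrt(2 f_j (1 - f_j))`.
#' Missing entries are imputed to the per-marker mean (0 on the standardized
#' scale). Validation/new individuals must be standardized with the training
#' frequencies; the `provenance` field records which sample `f` came from.
#'
#' @param g a [raw_genotypes()] object.
#' @param f allele frequencies, all strictly inside (0, 1).
#' @param provenance free-text note on the sample `f` was computed on.
#' @return an object of class `std_genotypes` with fields `X`, `f`, `map`,
#'   `provenance`.
#' @export
center_scale <- function(g, f, provenance = "training") {
  if (any(f <= 0 | f >= 1))
    stop("monomorphic marker(s): f must be strictly in (0,1); ",
         "apply filter_maf() first")
  n_missing <- sum(is.na(g$w))
  X <- sweep(g$w, 2, 2 * f)
  X <- sweep(X, 2, sqrt(2 * f * (1 - f)), "/")
  X[is.na(X)] <- 0
  if (n_missing > 0)
    message(sprintf("imputed %d missing genotype(s) to the marker mean",
                    n_missing))
  structure(list(X = X, f = f, map = g$map, provenance = provenance),
            class = "std_genotypes")
}

#' Read a phenotype vector
#'
#' Plain-text file with one value per line, or two whitespace-separated
#' columns `id value`.
#'
#' @param path file path.
#' @param n expected length (optional check).
#' @return numeric vector (named if ids present).
#' @export
read_phenotypes <- function(path, n = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  y <- if (ncol(tab) >= 2) stats::setNames(as.numeric(tab[[2]]), tab[[1]])
       else as.numeric(tab[[1]])
  if (any(!is.finite(y))) stop("non-finite phenotype value(s)")
  if (!is.null(n) && length(y) != n)
    stop(sprintf("phenotype length %d does not match %d individuals",
                 length(y), n))
  y
}
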