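# Panel-of-normals allele-fraction histograms and the beta-slice
# log-likelihood score.
#
# Every genomic position in a panel of normals is summarized by an 8-bin
# histogram of the normals' allele fractions.  A candidate variant's allele
# fraction is represented as a Beta posterior over its read counts, sliced
# at the same fraction boundaries, and scored against bins 3-8 of the
# histogram; a high score means many normals show similar alt evidence at
# the site (recurrent artifact or common germline), and the variant is
# filtered out.

# Allele-fraction slice boundaries shared by the histogram bins 3-8 and the
# beta slices: [0, 0.1%), [0.1%, 0.3%), [0.3%, 1%), [1%, 3%), [3%, 20%),
# [20%, 100%].
pon_slice_boundaries <- function() c(0, 0.001, 0.003, 0.01, 0.03, 0.2, 1)

#' Assign a normal sample's pileup to a histogram bin
#'
#' Bin scheme: bin 1 = total coverage < 8 (insufficient); bins 3-8 have
#' nested (alt count, alt fraction) thresholds — (1, 0.1\%), (2, 0.3\%),
#' (3, 1\%), (3, 3\%), (3, >20\%), (10, 20\%); a sample is assigned the
#' highest-index bin whose thresholds it meets, so the bins partition the
#' panel; bin 2 = covered but below every threshold.
#'
#' @param alt_count,total_count nonnegative integer vectors (alt <= total).
#' @return integer vector of bin indices in 1..8.
#' @export
assign_bin <- function(alt_count, total_count) {
  alt_count <- as.integer(alt_count)
  total_count <- as.integer(total_count)
  if (any(alt_count < 0 | total_count < 0 | alt_count > total_count)) {
    stop("assign_bin: need 0 <= alt_count <= total_count", call. = FALSE)
  }
  frac <- ifelse(total_count > 0, alt_count / total_count, 0)
  # highest satisfied bin among 3..8, else 2
  best <- pmax(3L * (alt_count >= 1  & frac >= 0.001),
               4L * (alt_count >= 2  & frac >= 0.003),
               5L * (alt_count >= 3  & frac >= 0.01),
               6L * (alt_count >= 3  & frac >= 0.03),
               7L * (alt_count >= 3  & frac > 0.2),
               8L * (alt_count >= 10 & frac >= 0.2))
  bin <- ifelse(best > 0L, best, 2L)
  bin[total_count < 8] <- 1L
  as.integer(bin)
}

#' Build a panel-of-normals histogram from per-normal pileups
#'
#' @param pileups data.frame with columns chrom, pos, alt_count, total_count;
#'   every stored position must carry exactly one row per normal, so all
#'   positions have the same number of rows (the panel size).
#' @return object of class \code{pon_histogram}: a positions x 8 count
#'   matrix (rows named "chrom:pos") plus the panel size.
#' @export
build_pon <- function(pileups) {
  if (nrow(pileups) == 0) stop("build_pon: empty panel", call. = FALSE)
  key <- paste(normalize_chrom(pileups$chrom), pileups$pos, sep = ":")
  sizes <- table(key)
  if (length(unique(as.integer(sizes))) != 1) {
    stop("build_pon: inconsistent panel size across positions", call. = FALSE)
  }
  n_normals <- as.integer(sizes[1])
  bins <- assign_bin(pileups$alt_count, pileups$total_count)
  upos <- unique(key)
  pos_idx <- match(key, upos)
  tab <- tabulate(bins + 8L * (pos_idx - 1L), nbins = 8L * length(upos))
  counts <- matrix(tab, ncol = 8, byrow = TRUE,
                   dimnames = list(upos, paste0("h", 1:8)))
  pon_histogram(counts, n_normals)
}

#' Construct a PoN histogram object from a count matrix
#'
#' @param counts positions x 8 integer matrix, rows named "chrom:pos".
#' @param n_normals panel size; every row must sum to it.
#' @return object of class \code{pon_histogram}.
#' @export
pon_histogram <- function(counts, n_normals) {
  counts <- as.matrix(counts)
  colnames(counts) <- paste0("h", 1:8)
  if (n_normals <= 0) stop("pon_histogram: panel size must be positive",
                           call. = FALSE)
  if (nrow(counts) > 0 && any(rowSums(counts) != n_normals)) {
    stop("pon_histogram: every position's bin counts must sum to the panel size",
         call. = FALSE)
  }
  structure(list(n_normals = as.integer(n_normals), counts = counts),
            class = "pon_histogram")
}

#' @export
print.pon_histogram <- function(x, ...) {
  cat("pon_histogram: ", nrow(x$counts), " positions over ", x$n_normals,
      " normals\n", sep = "")
  invisible(x)
}

#' Look up positions in a PoN histogram
#'
#' Positions absent from the panel map are interpreted as "all normals
#' covered, no alt evidence": h = (0, n_normals, 0, ..., 0).  This yields a
#' zero score, keeping the variant — the permissive choice when the panel
#' carries no evidence.
#'
#' @param pon a \code{pon_histogram}.
#' @param chrom,pos vectors of query positions.
#' @return numeric matrix (queries x 8) of bin counts.
#' @export
pon_lookup <- function(pon, chrom, pos) {
  key <- paste(normalize_chrom(chrom), pos, sep = ":")
  idx <- match(key, rownames(pon$counts))
  out <- matrix(0, nrow = length(key), ncol = 8,
                dimnames = list(NULL, paste0("h", 1:8)))
  out[, 2] <- pon$n_normals
  hit <- !is.na(idx)
  out[hit, ] <- pon$counts[idx[hit], , drop = FALSE]
  out
}

#' Slice the allele-fraction Beta posterior at the histogram boundaries
#'
#' The variant's allele fraction is modeled as Beta(n_alt + 1, n_ref + 1)
#' (accounting for count-to-fraction uncertainty); the density is integrated
#' over the six fraction slices via the regularized incomplete beta function.
#' Slices are closed on the left, open on the right, the last closed at 1,
#' so the six masses sum exactly to 1.
#'
#' @param n_alt,n_ref nonnegative read counts (vectors of equal length
#'   recycle).
#' @return numeric matrix (length x 6) of slice masses; a vector input of
#'   length 1 returns a 1 x 6 matrix whose row sums to 1 within 1e-9.
#' @export
slice_beta <- function(n_alt, n_ref) {
  if (any(n_alt < 0) || any(n_ref < 0)) {
    stop("slice_beta: counts must be nonnegative", call. = FALSE)
  }
  b <- pon_slice_boundaries()
  n <- max(length(n_alt), length(n_ref))
  n_alt <- rep_len(n_alt, n)
  n_ref <- rep_len(n_ref, n)
  cdf <- vapply(b, function(q) pbeta(q, n_alt + 1, n_ref + 1), numeric(n))
  if (n == 1) cdf <- matrix(cdf, nrow = 1)
  f <- cdf[, -1, drop = FALSE] - cdf[, -length(b), drop = FALSE]
  colnames(f) <- paste0("f", 1:6)
  f
}

#' Beta-slice log-likelihood score against a PoN histogram
#'
#' S is the dot product of the variant's six beta-slice masses with bins 3-8
#' of the position's histogram; the reported score is log10(S), clamped to
#' -10 when S = 0 so the feature stays finite.
#'
#' @param f 6-slice mass vector/matrix from [slice_beta()].
#' @param h 8-bin histogram count vector/matrix.
#' @return data.frame with columns \code{S} and \code{log10S}.
#' @export
pon_score <- function(f, h) {
  f <- matrix(as.numeric(as.matrix(f)), ncol = 6)
  h <- matrix(as.numeric(as.matrix(h)), ncol = 8)
  n <- max(nrow(f), nrow(h))
  if (nrow(f) == 1 && n > 1) f <- f[rep(1, n), , drop = FALSE]
  if (nrow(h) == 1 && n > 1) h <- h[rep(1, n), , drop = FALSE]
  S <- rowSums(f * h[, 3:8, drop = FALSE])
  log10S <- ifelse(S > 0, log10(S), -10)
  data.frame(S = S, log10S = log10S)
}

#' Panel-of-normals filter
#'
#' A variant is filtered out when its beta-slice score against the panel
#' reaches the threshold: log10(S) >= -2.5 by default.
#'
#' @param variants data.frame with chrom, pos, t_alt_count, t_ref_count.
#' @param pon a \code{pon_histogram}.
#' @param threshold log10 score at or above which variants fail.
#' @return logical vector, TRUE = pass (kept).
#' @export
pon_filter <- function(variants, pon, threshold = -2.5) {
  f <- slice_beta(variants$t_alt_count, variants$t_ref_count)
  h <- pon_lookup(pon, variants$chrom, variants$pos)
  pon_score(f, h)$log10S < threshold
}

#' Write a PoN histogram to TSV
#'
#' Format: a first comment line \code{#n_normals=<k>}, then a header and one
#' row per position: chrom, pos, h1..h8.
#'
#' @param pon a \code{pon_histogram}.
#' @param path output path (".gz" suffix compresses).
#' @export
write_pon <- function(pon, path) {
  parts <- do.call(rbind, strsplit(rownames(pon$counts), ":", fixed = TRUE))
  tab <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                    pon$counts, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(sprintf("#n_normals=%d", pon$n_normals), con)
  close(con)
  fwrite(tab, path, sep = "\t", quote = FALSE, append = TRUE,
         col.names = TRUE)
  invisible(path)
}

#' Read a PoN histogram written by [write_pon()]
#' @param path PoN TSV path.
#' @return a \code{pon_histogram}.
#' @export
read_pon <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  first <- readLines(con, n = 1)
  close(con)
  if (!grepl("^#n_normals=", first)) {
    stop("read_pon: missing #n_normals header line in ", path, call. = FALSE)
  }
  n_normals <- as.integer(sub("^#n_normals=", "", first))
  tab <- fread(path, sep = "\t", header = TRUE, skip = 1, data.table = FALSE,
               colClasses = list(character = "chrom"))
  counts <- as.matrix(tab[, paste0("h", 1:8)])
  rownames(counts) <- paste(normalize_chrom(tab$chrom), tab$pos, sep = ":")
  pon_histogram(counts, n_normals)
}
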