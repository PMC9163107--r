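#' @importFrom data.table fread fwrite
#' @importFrom stats median pbeta pbinom quantile rbeta rbinom rexp rnbinom
#'   rnorm rpois runif setNames cor.test wilcox.test pchisq
#' @importFrom utils head
NULL

# Canonical chromosome set: autosomes 1-22 plus X and Y.  Everything else
# (MT, unplaced contigs, alt haplotypes) is dropped on ingest.
canonical_chromosomes <- function() c(as.character(1:22), "X", "Y")

#' Normalize chromosome names
#'
#' Strips a leading \code{"chr"} prefix so that \code{"chr1"} and \code{"1"}
#' compare equal (MAF convention: plain names, 1-based inclusive coordinates).
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# Column set a variant table must provide (after dialect mapping).
variant_required_columns <- function() {
  c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
    "t_ref_count", "t_alt_count", "t_lod_fstar", "tumor_f",
    "variant_classification", "gene_symbol")
}

variant_optional_columns <- function() {
  c("context7", "supporting_reads", "failure_reasons", "label")
}

#' Default column dialect for variant tables
#'
#' A dialect maps the canonical column names used throughout the package to
#' the column names found in a particular file.  The default is the identity
#' mapping; TCGA-style MAF headers can be accommodated with a dialect file
#' (YAML or two-column TSV of \code{canonical: file_column} pairs) without
#' code changes.
#'
#' @return named character vector, names are canonical columns.
#' @export
default_dialect <- function() {
  cols <- c(variant_required_columns(), variant_optional_columns())
  setNames(cols, cols)
}

#' Read a column dialect from a YAML or TSV file
#'
#' @param path path to a YAML mapping or a two-column (canonical, file_column)
#'   tab-separated file.
#' @return named character vector suitable for [read_variant_table()].
#' @export
read_dialect <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    m <- yaml::read_yaml(path)
    dialect <- unlist(m)
  } else {
    tab <- fread(path, sep = "\t", header = FALSE, data.table = FALSE)
    dialect <- setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  }
  base <- default_dialect()
  base[names(dialect)] <- dialect
  base
}

#' Read a MAF-like variant table
#'
#' Reads a tab-separated variant table (optionally gzipped), applies the
#' column dialect, normalizes chromosome names, drops rows on non-canonical
#' contigs (with a message reporting the count), and type-checks the numeric
#' columns.
#'
#' @param path path to a TSV (or .gz) file with a header row.
#' @param dialect named character vector mapping canonical column names to
#'   file column names, or a path to a dialect file; see [default_dialect()].
#' @return data.frame of variant records in file order (canonical rows only),
#'   with canonical column names.  Optional columns absent from the file are
#'   filled with \code{NA}.
#' @export
read_variant_table <- function(path, dialect = default_dialect()) {
  if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect)) {
    dialect <- read_dialect(dialect)
  }
  raw <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
               colClasses = list(character = unname(
                 dialect[c("chrom", "ref_allele", "alt_allele")])))
  req <- variant_required_columns()
  missing_cols <- req[!dialect[req] %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("variant table ", path, " is missing required column(s): ",
         paste0(dialect[missing_cols], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    matrix(nrow = nrow(raw), ncol = 0))
  for (canon in c(req, variant_optional_columns())) {
    fc <- dialect[[canon]]
    out[[canon]] <- if (fc %in% names(raw)) raw[[fc]] else
      rep(NA, nrow(raw))
  }
  num_cols <- c("pos", "t_ref_count", "t_alt_count", "t_lod_fstar", "tumor_f")
  for (nc in num_cols) {
    orig <- out[[nc]]
    parsed <- suppressWarnings(as.numeric(orig))
    bad <- which(is.na(parsed) & !is.na(orig) & trimws(as.character(orig)) != "")
    if (length(bad) > 0) {
      stop("unparsable value in column '", nc, "' at data row ", bad[1],
           " of ", path, ": '", orig[bad[1]], "'", call. = FALSE)
    }
    out[[nc]] <- parsed
  }
  out$pos <- as.integer(out$pos)
  out$t_ref_count <- as.integer(out$t_ref_count)
  out$t_alt_count <- as.integer(out$t_alt_count)
  out$chrom <- normalize_chrom(out$chrom)
  keep <- out$chrom %in% canonical_chromosomes()
  if (any(!keep)) {
    message("read_variant_table: dropped ", sum(!keep),
            " row(s) on non-canonical contigs")
  }
  out[keep, , drop = FALSE]
}

#' Write a variant table
#'
#' Writes the canonical columns as TSV, the exact inverse of
#' [read_variant_table()] for canonical rows.
#'
#' @param variants data.frame of variant records.
#' @param path output path (".gz" suffix compresses).
#' @export
write_variant_table <- function(variants, path) {
  cols <- intersect(c(variant_required_columns(), variant_optional_columns()),
                    names(variants))
  fwrite(variants[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
         na = "")
  invisible(path)
}

# Caller rejection tags that indicate germline evidence in the matched normal.
germline_failure_tags <- function() {
  c("normal_lod", "germline_risk", "alt_allele_in_normal")
}

#' Derive training labels from matched-normal caller output
#'
#' In the training cohort a matched normal is available, so each candidate
#' variant can be labeled: variants the caller rejected specifically for
#' germline evidence in the normal (\code{normal_lod}, \code{germline_risk},
#' or \code{alt_allele_in_normal}) are germline; variants that passed the
#' full calling-and-filtering pipeline with none of those tags are somatic;
#' anything else (rejected for artifact reasons) is excluded from training
#' as \code{"unlabeled"} rather than treated as germline, to avoid label
#' noise from caller artifacts.
#'
#' @param failure_reasons character vector; per record, a comma-separated
#'   string of caller rejection tags ("" or NA when the record passed).
#' @param passed_full_pipeline logical vector; whether the record passed the
#'   full matched-normal calling pipeline.
#' @return factor with levels \code{somatic}, \code{germline},
#'   \code{unlabeled}.
#' @export
label_from_matched_normal <- function(failure_reasons, passed_full_pipeline) {
  failure_reasons <- as.character(failure_reasons)
  failure_reasons[is.na(failure_reasons)] <- ""
  tags <- strsplit(failure_reasons, ",", fixed = TRUE)
  germ <- vapply(tags, function(tt) {
    any(trimws(tt) %in% germline_failure_tags())
  }, logical(1))
  out <- rep("unlabeled", length(failure_reasons))
  out[germ] <- "germline"
  out[!germ & passed_full_pipeline] <- "somatic"
  factor(out, levels = c("somatic", "germline", "unlabeled"))
}

germline_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

#' Load a germline population resource
#'
#' Reads a TSV (chrom, pos, ref, alt, af) of known germline variants with
#' population allele frequencies.  AF entries may be empty; the resource-wide
#' mean AF over non-empty entries is recorded and used to impute missing AFs
#' at lookup time.  A degenerate resource with no recorded AFs falls back to
#' mean AF 0.5 with a warning.
#'
#' @param path TSV (or .gz) with columns chrom, pos, ref, alt, af.
#' @param name resource name (e.g. "dbSNP", "gnomAD", "1000G", "ESP", "ExAC").
#' @return object of class \code{germline_resource}.
#' @export
load_germline_resource <- function(path, name = basename(path)) {
  tab <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
               colClasses = list(character = c("chrom", "ref", "alt")))
  tab$af <- suppressWarnings(as.numeric(tab$af))
  germline_resource(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                    alt = tab$alt, af = tab$af, name = name)
}

#' Construct a germline resource from vectors
#'
#' @param chrom,pos,ref,alt site and alleles of each known variant.
#' @param af population allele frequency, NA when unrecorded.
#' @param name resource name.
#' @return object of class \code{germline_resource}: lookups are exact on
#'   (chrom, pos, ref, alt).
#' @export
germline_resource <- function(chrom, pos, ref, alt, af, name = "resource") {
  af <- as.numeric(af)
  known <- af[!is.na(af)]
  if (length(known) == 0) {
    warning("germline resource '", name,
            "' has no recorded allele frequencies; mean AF falls back to 0.5")
    mean_af <- 0.5
  } else {
    mean_af <- mean(known)
  }
  structure(list(name = name,
                 key = germline_key(chrom, pos, ref, alt),
                 af = af,
                 mean_af = mean_af),
            class = "germline_resource")
}

#' Look up variants in a germline resource
#'
#' @param resource a \code{germline_resource}.
#' @param chrom,pos,ref,alt vectors describing the query variants.
#' @return data.frame with columns \code{present} (0/1) and \code{af}
#'   (recorded AF when present and recorded, otherwise the resource mean AF).
#' @export
germline_lookup <- function(resource, chrom, pos, ref, alt) {
  idx <- match(germline_key(chrom, pos, ref, alt), resource$key)
  present <- as.integer(!is.na(idx))
  af <- resource$af[idx]
  af[is.na(af)] <- resource$mean_af
  data.frame(present = present, af = af)
}

#' @export
print.germline_resource <- function(x, ...) {
  cat("germline_resource '", x$name, "': ", length(x$key), " variants, mean AF ",
      signif(x$mean_af, 4), "\n", sep = "")
  invisible(x)
}

#' Load an RNA-editing site list
#'
#' @param path TSV with columns chrom, pos.
#' @return character vector of "chrom:pos" keys, canonical chromosomes only.
#' @export
load_site_list <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
               colClasses = list(character = "chrom"))
  chrom <- normalize_chrom(tab$chrom)
  keep <- chrom %in% canonical_chromosomes()
  unique(paste(chrom[keep], tab$pos[keep], sep = ":"))
}

#' Load a gene list (pseudogene / IgG)
#'
#' @param path TSV with a gene_symbol column (or a one-column file).
#' @return character vector of gene symbols.
#' @export
load_gene_list <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  col <- if ("gene_symbol" %in% names(tab)) "gene_symbol" else names(tab)[1]
  unique(as.character(tab[[col]]))
}

#' Write a germline resource to TSV
#' @param resource a \code{germline_resource}.
#' @param path output TSV path.
#' @export
write_germline_resource <- function(resource, path) {
  parts <- do.call(rbind, strsplit(resource$key, ":", fixed = TRUE))
  fwrite(data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                    ref = parts[, 3], alt = parts[, 4], af = resource$af),
         path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}
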