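# Assembly of the 31-feature vector used by the somatic/germline classifier:
#   1-4   tumor read counts, caller LOD, allele fraction
#   5-12  presence + allele frequency in each of four germline databases
#   13    non-coding variant-classification indicator
#   14-22 DNA PoN 8-bin histogram + beta-slice log10 score
#   23-31 RNA PoN 8-bin histogram + beta-slice log10 score

# Variant classifications counted as non-coding: transcripts from these
# regions arise mostly from fuzzy transcription, and with germline variants
# outnumbering somatic by orders of magnitude, a variant there is far more
# likely germline.
noncoding_classes <- function() c("IGR", "Intron", "RNA", "lincRNA")

# Known variant-classification vocabulary (MAF convention).
variant_classification_vocabulary <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "Silent",
    "Splice_Site", "Translation_Start_Site", "IGR", "Intron", "RNA",
    "lincRNA", "3'UTR", "5'UTR", "5'Flank", "3'Flank", "De_novo_Start_InFrame",
    "De_novo_Start_OutOfFrame", "Start_Codon_SNP")
}

#' Non-coding classification indicator (feature 13)
#'
#' @param variant_classification character vector of classifications.
#' @return integer 0/1 vector; 1 iff the classification is one of IGR,
#'   Intron, RNA, lincRNA (exact match).  Unknown classifications map to 0
#'   with a warning.
#' @export
noncoding_indicator <- function(variant_classification) {
  unknown <- !variant_classification %in% variant_classification_vocabulary()
  if (any(unknown)) {
    warning("noncoding_indicator: ", sum(unknown),
            " unknown variant classification(s), treated as coding (0)")
  }
  as.integer(variant_classification %in% noncoding_classes())
}

# Database slots in feature order; each contributes a presence flag and an AF.
germline_db_slots <- function() c("dbsnp", "gnomad", "g1000", "esp")

#' Frozen feature ordering
#'
#' @return character vector of the 31 feature names in their fixed order.
#' @export
feature_names <- function() {
  c("t_ref_count", "t_alt_count", "t_lod_fstar", "tumor_f",
    as.vector(t(outer(germline_db_slots(), c("_present", "_af"), paste0))),
    "noncoding",
    paste0("dna_pon_h", 1:8), "dna_pon_log10S",
    paste0("rna_pon_h", 1:8), "rna_pon_log10S")
}

#' Hash of an ordered feature-name list
#'
#' Small polynomial rolling hash (base 31 mod 2^31 - 1) of the ordered,
#' pipe-joined names.  Stored inside every trained model and checked at
#' prediction time so that models are never applied to reordered or
#' renamed features.
#'
#' @param names character vector of feature names (default: the frozen order).
#' @return integer hash.
#' @export
feature_hash <- function(names = feature_names()) {
  codes <- utf8ToInt(paste(names, collapse = "|"))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

#' Database presence / allele-frequency features
#'
#' For one germline resource: (1, AF) when the variant is present with a
#' recorded AF; (1, mean AF) when present without one; (0, mean AF) when
#' absent — the resource-wide mean AF stands in whenever no specific AF is
#' recorded.
#'
#' @param variants data.frame with chrom, pos, ref_allele, alt_allele.
#' @param resource a \code{germline_resource}.
#' @return data.frame with columns \code{present}, \code{af}.
#' @export
db_features <- function(variants, resource) {
  germline_lookup(resource, variants$chrom, variants$pos,
                  variants$ref_allele, variants$alt_allele)
}

#' Extract the 31-feature matrix for a variant table
#'
#' Deterministic, pure assembly of the classifier's feature block: per-record
#' counts and caller statistics, presence/AF in the four germline databases,
#' the non-coding indicator, and both PoN histogram blocks with their
#' beta-slice log10 scores (absent PoN positions use the no-evidence default
#' histogram; a zero score is clamped to -10).
#'
#' @param variants data.frame of variant records (canonical chromosomes).
#' @param resources named list of four \code{germline_resource} objects with
#'   names \code{dbsnp}, \code{gnomad}, \code{g1000}, \code{esp}.
#' @param dna_pon,rna_pon \code{pon_histogram} panels.
#' @return data.frame with the 31 feature columns in frozen order, one row
#'   per variant.
#' @export
extract_features <- function(variants, resources, dna_pon, rna_pon) {
  slots <- germline_db_slots()
  missing_res <- setdiff(slots, names(resources))
  if (length(missing_res) > 0) {
    stop("extract_features: missing resource(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(t_ref_count = as.numeric(variants$t_ref_count),
                    t_alt_count = as.numeric(variants$t_alt_count),
                    t_lod_fstar = as.numeric(variants$t_lod_fstar),
                    tumor_f = as.numeric(variants$tumor_f))
  for (slot in slots) {
    db <- db_features(variants, resources[[slot]])
    out[[paste0(slot, "_present")]] <- db$present
    out[[paste0(slot, "_af")]] <- db$af
  }
  out$noncoding <- noncoding_indicator(variants$variant_classification)
  f <- slice_beta(variants$t_alt_count, variants$t_ref_count)
  for (panel in list(list(name = "dna", pon = dna_pon),
                     list(name = "rna", pon = rna_pon))) {
    h <- pon_lookup(panel$pon, variants$chrom, variants$pos)
    colnames(h) <- paste0(panel$name, "_pon_h", 1:8)
    out <- cbind(out, as.data.frame(h))
    out[[paste0(panel$name, "_pon_log10S")]] <- pon_score(f, h)$log10S
  }
  stopifnot(identical(names(out), feature_names()))
  out
}
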