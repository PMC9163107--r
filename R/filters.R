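# RNA-specific filter chain applied to predicted-somatic variants.
#
# Order (the numbered order of the underlying RNA calling pipeline):
#   1. minimum alt-read support (>= 3)
#   2. DNA panel-of-normals beta-slice score
#   3. realignment hook (pass-through unless the user supplies one)
#   4. RNA panel-of-normals beta-slice score
#   5. population allele frequency (ExAC MAF > 5%)
#   6. non-coding regions
#   7. RNA-editing sites
#   8. duplicate supporting-read collapse (then re-check alt support)
#   9. sequencing-leakage context
#  10. pseudogene / IgG genes
# A removed variant is attributed to the first filter that removes it.

#' Filter-chain configuration
#'
#' @param min_alt_reads minimum alt-supporting reads (default 3).
#' @param exac_max_af population MAF above which variants are removed
#'   (strictly greater than; default 0.05).
#' @param leakage_min_matches flanking alt-base matches at which the
#'   leakage rule fires (default 3, "at least").
#' @param pon_log10_threshold PoN score threshold (default -2.5).
#' @return list of thresholds consumed by [apply_filter_chain()].
#' @export
filter_config <- function(min_alt_reads = 3, exac_max_af = 0.05,
                          leakage_min_matches = 3,
                          pon_log10_threshold = -2.5) {
  stopifnot(min_alt_reads > 0, exac_max_af > 0, leakage_min_matches > 0)
  list(min_alt_reads = min_alt_reads, exac_max_af = exac_max_af,
       leakage_min_matches = leakage_min_matches,
       pon_log10_threshold = pon_log10_threshold)
}

#' Minimum alt-read filter
#' @param variants variant data.frame.
#' @param min_alt_reads threshold (default 3).
#' @return logical pass vector.
#' @export
min_alt_filter <- function(variants, min_alt_reads = 3) {
  variants$t_alt_count >= min_alt_reads
}

#' Population allele-frequency filter
#'
#' Removes variants recorded in the population resource with a minor allele
#' frequency strictly above the cutoff.  Variants absent from the resource,
#' or present without a recorded AF, pass.
#'
#' @param variants variant data.frame.
#' @param exac a \code{germline_resource} (population exome resource).
#' @param max_af MAF cutoff (default 0.05).
#' @return logical pass vector.
#' @export
exac_filter <- function(variants, exac, max_af = 0.05) {
  idx <- match(germline_key(variants$chrom, variants$pos,
                            variants$ref_allele, variants$alt_allele),
               exac$key)
  af <- exac$af[idx]              # NA when absent or unrecorded
  !(!is.na(af) & af > max_af)
}

#' Non-coding region filter
#' @param variants variant data.frame.
#' @return logical pass vector; fails IGR/Intron/RNA/lincRNA classifications.
#' @export
noncoding_filter <- function(variants) {
  noncoding_indicator(variants$variant_classification) == 0L
}

#' RNA-editing site filter
#' @param variants variant data.frame.
#' @param sites character vector of "chrom:pos" editing-site keys
#'   (see [load_site_list()]).
#' @return logical pass vector.
#' @export
editing_site_filter <- function(variants, sites) {
  !(paste(normalize_chrom(variants$chrom), variants$pos, sep = ":") %in% sites)
}

# supporting_reads encoding: "start-end;start-end;..." per record.
parse_supporting_reads <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Collapse duplicate alt-supporting reads
#'
#' When several alt-supporting reads align to exactly the same (start, end)
#' coordinates, only one is kept and the alt count is reduced by the number
#' of duplicates removed (such stacks are PCR/alignment duplicates, not
#' independent evidence).  Records without supporting-read coordinates pass
#' through unchanged with a logged note.  The minimum-alt-read rule is
#' re-evaluated after collapsing, inside [apply_filter_chain()].
#'
#' @param variants variant data.frame with a \code{supporting_reads} column
#'   ("start-end;start-end" encoding).
#' @return the variant data.frame with deduplicated \code{supporting_reads}
#'   and reduced \code{t_alt_count}.
#' @export
duplicate_read_collapse <- function(variants) {
  sr <- as.character(variants$supporting_reads)
  absent <- is.na(sr) | !nzchar(sr)
  if (any(absent)) {
    message("duplicate_read_collapse: ", sum(absent),
            " record(s) without supporting-read coordinates passed through")
  }
  for (i in which(!absent)) {
    reads <- parse_supporting_reads(sr[i])
    uniq <- unique(reads)
    removed <- length(reads) - length(uniq)
    if (removed > 0) {
      variants$t_alt_count[i] <- max(0L, variants$t_alt_count[i] - removed)
      variants$supporting_reads[i] <- paste(uniq, collapse = ";")
    }
  }
  variants
}

#' Sequencing-leakage filter
#'
#' Fails variants whose alternate base matches at least
#' \code{min_matches} of the six flanking bases in the 7-mer reference
#' context (+/- 3 bases around the variant; the variant base itself is
#' excluded since the reference context carries the reference base there).
#' Records without a context pass with a logged note.
#'
#' @param variants variant data.frame with \code{context7} and
#'   \code{alt_allele}.
#' @param min_matches match count at which the rule fires (default 3).
#' @return logical pass vector.
#' @export
leakage_filter <- function(variants, min_matches = 3) {
  ctx <- as.character(variants$context7)
  absent <- is.na(ctx) | !nzchar(ctx)
  if (any(absent)) {
    message("leakage_filter: ", sum(absent),
            " record(s) without context passed through")
  }
  pass <- rep(TRUE, nrow(variants))
  for (i in which(!absent)) {
    bases <- strsplit(ctx[i], "")[[1]]
    if (length(bases) != 7) {
      stop("leakage_filter: context7 must have length 7 (record ", i, ")",
           call. = FALSE)
    }
    flanks <- bases[c(1:3, 5:7)]
    pass[i] <- sum(flanks == variants$alt_allele[i]) < min_matches
  }
  pass
}

#' Pseudogene / IgG gene filter
#' @param variants variant data.frame.
#' @param genes character vector of noisy-alignment gene symbols.
#' @return logical pass vector.
#' @export
pseudogene_filter <- function(variants, genes) {
  !(variants$gene_symbol %in% genes)
}

#' Apply the full RNA filter chain
#'
#' Runs every filter in the fixed order above on variants already classified
#' somatic, attributing each removed variant to the first filter that
#' removes it.  The realignment step requires external aligners and is
#' exposed only as a hook: a function \code{(variants) -> logical pass
#' vector}; when absent the step is an identity pass and the report notes
#' it, since precision may be overestimated without it.
#'
#' @param variants data.frame of predicted-somatic variant records.
#' @param config thresholds from [filter_config()].
#' @param exac population \code{germline_resource}.
#' @param dna_pon,rna_pon \code{pon_histogram} panels.
#' @param editing_sites character vector of "chrom:pos" keys.
#' @param artifact_genes character vector of pseudogene/IgG symbols.
#' @param realign_hook optional function(variants) -> logical pass vector.
#' @return list with \code{survivors} (filtered variant data.frame, with
#'   duplicate reads collapsed) and \code{report} (a \code{filter_report}:
#'   per-variant removal attribution and per-filter counts).
#' @export
apply_filter_chain <- function(variants, config = filter_config(),
                               exac, dna_pon, rna_pon,
                               editing_sites = character(0),
                               artifact_genes = character(0),
                               realign_hook = NULL) {
  n <- nrow(variants)
  removed_by <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  mark <- function(pass, name) {
    newly <- alive & !pass
    removed_by[newly] <<- name
    alive <<- alive & pass
  }
  mark(min_alt_filter(variants, config$min_alt_reads), "min_alt")
  mark(pon_filter(variants, dna_pon, config$pon_log10_threshold), "dna_pon")
  if (is.null(realign_hook)) {
    realignment_applied <- FALSE
  } else {
    realignment_applied <- TRUE
    mark(realign_hook(variants), "realignment")
  }
  mark(pon_filter(variants, rna_pon, config$pon_log10_threshold), "rna_pon")
  mark(exac_filter(variants, exac, config$exac_max_af), "exac")
  mark(noncoding_filter(variants), "noncoding")
  mark(editing_site_filter(variants, editing_sites), "editing_site")
  collapsed <- duplicate_read_collapse(variants)
  # the re-check only concerns still-alive records; removal by the reduced
  # count is attributed to the collapse that caused it
  mark(min_alt_filter(collapsed, config$min_alt_reads),
       "duplicate_read_collapse")
  mark(leakage_filter(collapsed, config$leakage_min_matches), "leakage")
  mark(pseudogene_filter(collapsed, artifact_genes), "pseudogene_igg")
  filter_order <- c("min_alt", "dna_pon",
                    if (realignment_applied) "realignment",
                    "rna_pon", "exac", "noncoding", "editing_site",
                    "duplicate_read_collapse", "leakage", "pseudogene_igg")
  counts <- vapply(filter_order,
                   function(f) sum(removed_by == f, na.rm = TRUE), integer(1))
  report <- structure(list(n_input = n, n_survivors = sum(alive),
                           removed_by = removed_by,
                           filter_counts = counts,
                           realignment_applied = realignment_applied),
                      class = "filter_report")
  list(survivors = collapsed[alive, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: ", x$n_input, " in, ", x$n_survivors, " surviving\n",
      sep = "")
  for (f in names(x$filter_counts)) {
    cat(sprintf("  %-24s %d\n", f, x$filter_counts[[f]]))
  }
  if (!x$realignment_applied) {
    cat("  note: realignment step not applied (no hook supplied);",
        "precision may be overestimated\n")
  }
  invisible(x)
}
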