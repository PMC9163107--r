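# Shared fixtures, built in code.  The full-size cohort bundle and its
# end-to-end study are expensive, so they are built once per test run and
# memoized.

.fixture_cache <- new.env(parent = emptyenv())

# Small bundle parameters with optional overrides.
small_sim_params <- function(...) {
  defaults <- list(n_samples = 6, somatic_mean = 10,
                   germline_per_sample = 60, pon_panel_size = 20,
                   master_seed = 777)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

cached_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- simulate_cohort(simulation_params())
  }
  .fixture_cache$bundle
}

cached_study <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- suppressMessages(
      run_cohort_study(cached_bundle(), n_train = 100, seed = 1))
  }
  .fixture_cache$study
}

# Minimal variant-record data.frame with sensible defaults.
make_variants <- function(n = 1, sample_id = "S1", chrom = "1",
                          pos = seq(1000, by = 100, length.out = n),
                          ref_allele = "A", alt_allele = "G",
                          t_ref_count = 20L, t_alt_count = 10L,
                          t_lod_fstar = 20, tumor_f = NULL,
                          variant_classification = "Missense_Mutation",
                          gene_symbol = "GENE1", context7 = NA_character_,
                          supporting_reads = NA_character_,
                          failure_reasons = "") {
  df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                   ref_allele = ref_allele, alt_allele = alt_allele,
                   t_ref_count = as.integer(t_ref_count),
                   t_alt_count = as.integer(t_alt_count),
                   t_lod_fstar = t_lod_fstar, tumor_f = 0,
                   variant_classification = variant_classification,
                   gene_symbol = gene_symbol, context7 = context7,
                   supporting_reads = supporting_reads,
                   failure_reasons = failure_reasons,
                   stringsAsFactors = FALSE)
  df$tumor_f <- if (is.null(tumor_f)) {
    ifelse(df$t_alt_count + df$t_ref_count > 0,
           df$t_alt_count / (df$t_alt_count + df$t_ref_count), 0)
  } else {
    tumor_f
  }
  df
}

# Tiny germline resource over explicit variants.
make_resource <- function(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          af = numeric(0), name = "test") {
  if (length(chrom) == 0) {
    # nonempty dummy entry far away so mean_af is defined without a warning
    return(germline_resource("22", 1L, "A", "C", 0.5, name = name))
  }
  germline_resource(chrom, pos, ref, alt, af, name = name)
}

# PoN whose every stored position carries the same 8-bin histogram.
make_pon <- function(keys = character(0), h = c(0, 10, 0, 0, 0, 0, 0, 0),
                     n_normals = sum(h)) {
  counts <- matrix(rep(h, each = length(keys)), ncol = 8,
                   dimnames = list(keys, paste0("h", 1:8)))
  if (length(keys) == 0) counts <- matrix(integer(0), ncol = 8)
  pon_histogram(counts, n_normals)
}

# Empty (no positions stored) PoN: every lookup hits the no-evidence default.
empty_pon <- function(n_normals = 10) {
  pon_histogram(matrix(integer(0), ncol = 8), n_normals)
}

# The 12-variant filter-chain fixture: 9 records each violating exactly one
# rule of the chain (in chain order) plus 3 clean records.  PoN-violating
# records sit at positions stored in hot panels; everything else is clean
# for every other rule.
filter_chain_fixture <- function() {
  v <- make_variants(n = 12, sample_id = "FX",
                     pos = seq(5000, by = 1000, length.out = 12),
                     t_ref_count = 40L, t_alt_count = 10L,
                     context7 = "CCCATTT", alt_allele = "G",
                     supporting_reads = NA)
  # distinct clean supporting reads everywhere first
  v$supporting_reads <- vapply(seq_len(12), function(i) {
    starts <- v$pos[i] - 40 - 7 * seq_len(v$t_alt_count[i])
    paste(paste0(starts, "-", starts + 75), collapse = ";")
  }, character(1))
  v$violated <- c("min_alt", "dna_pon", "rna_pon", "exac", "noncoding",
                  "editing_site", "duplicate_read_collapse", "leakage",
                  "pseudogene_igg", "clean", "clean", "clean")
  # 1: below the 3-read floor
  v$t_alt_count[1] <- 2L
  v$supporting_reads[1] <- paste0(v$pos[1] - 47, "-", v$pos[1] + 28, ";",
                                  v$pos[1] - 54, "-", v$pos[1] + 21)
  v$tumor_f[1] <- 2 / 42
  # 7: all supporting reads stack at identical coordinates -> collapses to 1
  one <- paste0(v$pos[7] - 40, "-", v$pos[7] + 35)
  v$supporting_reads[7] <- paste(rep(one, v$t_alt_count[7]), collapse = ";")
  # 8: four of the six flanking bases equal the alternate base
  v$context7[8] <- "GGGAGTC"
  # 5: non-coding classification
  v$variant_classification[5] <- "Intron"
  # 9: pseudogene
  v$gene_symbol[9] <- "PSG001"
  hot <- c(0, 0, 0, 0, 0, 0, 5, 5)  # bins 7/8 populated: log10S >= -2.5
  list(
    variants = v,
    exac = make_resource(v$chrom[4], v$pos[4], v$ref_allele[4],
                         v$alt_allele[4], af = 0.12, name = "exac"),
    dna_pon = make_pon(paste(v$chrom[2], v$pos[2], sep = ":"), h = hot),
    rna_pon = make_pon(paste(v$chrom[3], v$pos[3], sep = ":"), h = hot),
    editing_sites = paste(v$chrom[6], v$pos[6], sep = ":"),
    artifact_genes = "PSG001")
}

# Small four-resource list for feature extraction on toy variants.
toy_resources <- function() {
  list(dbsnp = make_resource(), gnomad = make_resource(),
       g1000 = make_resource(), esp = make_resource())
}
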