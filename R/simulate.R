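# Synthetic-cohort simulator.
#
# Generates labeled variant cohorts with the statistical structure the
# pipeline assumes: per-sample somatic burdens (negative binomial) swamped
# by a 50:1 excess of germline variants; germline variants mostly present in
# the population databases and panels of normals, somatic variants almost
# never; RNA allele fractions that overlap heavily between the classes
# (purity-diluted somatic fractions vs. allele-specific-expression-dispersed
# heterozygous fractions), so that no single feature separates them; a small
# rate of RNA artifact records each violating one rule of the filter chain;
# and exponential survival times whose hazard is tied to log10(TMB + 1).
# Sub-seeds are derived from the master seed by a fixed counter scheme
# (master + 7919 * index) so earlier samples are unaffected when the cohort
# grows.

#' Simulation parameters
#'
#' Defaults are the bundled study conditions; see the methods vignette for
#' the rationale behind each value.
#'
#' @param n_samples cohort size (default 200: 100 train + 100 test).
#' @param somatic_mean,somatic_dispersion negative-binomial mean / size of
#'   the per-sample somatic count (default 20 / 2).
#' @param germline_per_sample germline variants per sample (default 1000,
#'   i.e. a 50:1 germline excess).
#' @param purity_range tumor purity drawn uniformly on this interval.
#' @param db_presence_germline,db_presence_somatic marginal probability that
#'   a variant is recorded in each germline database (0.95 / 0.01).
#' @param rare_fraction fraction of germline variants that are
#'   population-rare; rare variants are recorded in each database with
#'   probability \code{db_presence_rare} and the common-variant presence is
#'   solved so the marginal matches \code{db_presence_germline}.
#' @param db_presence_rare per-database presence of rare germline variants.
#' @param pon_panel_size normals per panel (default 100).
#' @param pon_presence_germline_dna,pon_presence_germline_rna probability a
#'   germline position is represented in the DNA / RNA panel (0.8 / 0.7).
#' @param pon_artifact_dna,pon_artifact_rna probability an artifact
#'   record is a recurrent panel artifact (0.02 / 0.05).
#' @param mean_depth mean RNA coverage per site (default 80).
#' @param ase_shape Beta(ase_shape, ase_shape) allele-specific-expression
#'   spread of heterozygous germline fractions around 0.5 (default 5).
#' @param rna_noise_rate fraction of records that are RNA artifacts with a
#'   planted filter violation (default 0.01).
#' @param log_tmb_coef survival log-hazard coefficient on log10(TMB + 1)
#'   (default -0.5; higher burden, lower hazard).
#' @param baseline_hazard exponential baseline hazard per day.
#' @param censor_hazard independent exponential censoring hazard.
#' @param master_seed master RNG seed.
#' @return list of class \code{sim_params}.
#' @export
simulation_params <- function(n_samples = 200,
                              somatic_mean = 20, somatic_dispersion = 2,
                              germline_per_sample = 1000,
                              purity_range = c(0.2, 1),
                              db_presence_germline = 0.95,
                              db_presence_somatic = 0.01,
                              rare_fraction = 0.1,
                              db_presence_rare = 0.65,
                              pon_panel_size = 100,
                              pon_presence_germline_dna = 0.8,
                              pon_presence_germline_rna = 0.7,
                              pon_artifact_dna = 0.02,
                              pon_artifact_rna = 0.05,
                              mean_depth = 80,
                              ase_shape = 5,
                              rna_noise_rate = 0.01,
                              log_tmb_coef = -0.5,
                              baseline_hazard = 1 / 1200,
                              censor_hazard = 1 / 3000,
                              master_seed = 20260101) {
  p <- as.list(environment())
  probs <- unlist(p[grepl("^(db_presence|pon_presence|pon_artifact|rare_fraction|rna_noise)", names(p))])
  stopifnot(all(probs >= 0 & probs <= 1), n_samples >= 1,
            somatic_mean > 0, germline_per_sample > 0, pon_panel_size >= 0)
  # presence of common germline variants solved so the marginal presence
  # matches db_presence_germline given the rare mixture
  p$db_presence_common <- min(1, (db_presence_germline -
    rare_fraction * db_presence_rare) / (1 - rare_fraction))
  structure(p, class = "sim_params")
}

sub_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

random_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# One of the three bases different from ref, uniformly.
random_alt_bases <- function(ref) {
  bases <- c("A", "C", "G", "T")
  idx <- (match(ref, bases) - 1L + sample(1:3, length(ref), replace = TRUE)) %% 4L
  bases[idx + 1L]
}

# Random 7-mer contexts centered on ref, constrained so fewer than
# `max_matches` of the six flanking bases equal alt: records emitted by the
# full matched-normal chain have by definition survived the leakage rule, so
# clean records must respect it (a planted leakage violation overrides the
# context afterwards).
random_context7 <- function(ref, alt, max_matches = 2) {
  n <- length(ref)
  flanks <- matrix(sample(c("A", "C", "G", "T"), 6 * n, replace = TRUE),
                   nrow = n)
  m <- flanks == alt
  excess <- matrix(FALSE, n, 6)
  cum <- rep(0L, n)
  for (j in 1:6) {
    cum <- cum + m[, j]
    excess[, j] <- m[, j] & cum > max_matches
  }
  if (any(excess)) {
    # rotate offending bases one step past alt in the alphabet
    bases <- c("A", "C", "G", "T")
    repl <- bases[(match(alt, bases) %% 4L) + 1L]
    repl_m <- matrix(rep(repl, 6), n, 6)
    flanks[excess] <- repl_m[excess]
  }
  paste0(flanks[, 1], flanks[, 2], flanks[, 3], ref,
         flanks[, 4], flanks[, 5], flanks[, 6])
}

# Distinct (start, end) supporting-read coordinates left of each position;
# vectorized over records, one string per record.
clean_supporting_reads <- function(pos, n_reads) {
  n_reads <- pmax(0L, as.integer(n_reads))
  row <- rep(seq_along(pos), n_reads)
  if (length(row) == 0) return(rep("", length(pos)))
  offset <- sequence(n_reads)
  starts <- pos[row] - 40L - 7L * offset
  piece <- paste0(starts, "-", starts + 75L)
  out <- rep("", length(pos))
  grouped <- vapply(split(piece, row), paste, character(1), collapse = ";")
  out[as.integer(names(grouped))] <- grouped
  out
}

filter_violation_types <- function() {
  c("low_alt", "noncoding", "editing_site", "exac_common",
    "duplicate_reads", "leakage", "pseudogene", "pon_hot")
}

#' Simulate one sample's variant records
#'
#' Draws the sample's somatic variants (binomial read counts at allele
#' fraction purity/2 x clonality, floored at 3 alt reads to emulate the
#' caller's detection threshold), its germline variants (heterozygous
#' fractions Beta-dispersed around 0.5 by allele-specific expression,
#' homozygous near 1), and a small number of RNA artifact records each
#' violating one filter rule.  Byte-identical given the seed.
#'
#' @param sample_id sample identifier.
#' @param params \code{sim_params}.
#' @param seed per-sample seed.
#' @return data.frame of variant records with columns of
#'   [read_variant_table()] plus \code{truth} (somatic / germline /
#'   artifact), \code{pop_af}, \code{rarity}, db presence flags and
#'   \code{violation}.
#' @export
simulate_sample <- function(sample_id, params, seed) {
  set.seed(seed)
  purity <- runif(1, params$purity_range[1], params$purity_range[2])
  n_som <- max(1L, rnbinom(1, mu = params$somatic_mean,
                           size = params$somatic_dispersion))
  n_germ <- params$germline_per_sample
  n_art <- rbinom(1, n_som + n_germ, params$rna_noise_rate)
  n <- n_som + n_germ + n_art
  truth <- rep(c("somatic", "germline", "artifact"),
               c(n_som, n_germ, n_art))

  chrom <- sample(canonical_chromosomes(), n, replace = TRUE,
                  prob = c(rep(1, 22), 0.5, 0.1))
  pos <- sample(1e7:2e8, n)
  ref <- random_bases(n)
  alt <- random_alt_bases(ref)
  depth <- pmax(10L, rpois(n, params$mean_depth))

  # true allele fractions
  af <- numeric(n)
  is_som <- truth == "somatic"
  is_germ <- truth == "germline"
  is_art <- truth == "artifact"
  clonality <- ifelse(runif(n_som) < 0.7, 1, runif(n_som, 0.2, 1))
  af[is_som] <- purity * clonality / 2
  hom <- runif(n_germ) < 0.2
  af_het <- rbeta(n_germ, params$ase_shape, params$ase_shape)
  af[is_germ] <- ifelse(hom, rbeta(n_germ, 60, 2), af_het)
  af[is_art] <- runif(n_art, 0.05, 0.4)

  alt_count <- rbinom(n, depth, af)
  # caller detection floor for somatic and artifact records (germline
  # records below the floor are real caller output and stay as drawn)
  alt_count[is_som | is_art] <- pmax(alt_count[is_som | is_art], 3L)
  alt_count <- pmin(alt_count, depth)
  ref_count <- depth - alt_count
  tumor_f <- ifelse(depth > 0, alt_count / depth, 0)
  lod <- pmax(6.3, 4 + 1.6 * alt_count + rnorm(n, 0, 3))

  # truth-somatic records have by definition survived the full
  # matched-normal chain, which removes non-coding calls; germline calls
  # land in fuzzy-transcription regions at an appreciable rate
  classification <- character(n)
  coding_classes <- c("Missense_Mutation", "Silent", "Nonsense_Mutation",
                      "Splice_Site", "3'UTR", "5'UTR")
  coding_probs <- c(0.52, 0.25, 0.05, 0.04, 0.09, 0.05)
  classification[is_som] <- sample(coding_classes, n_som, replace = TRUE,
                                   prob = coding_probs)
  classification[is_germ] <- ifelse(
    runif(n_germ) < 0.25,
    sample(noncoding_classes(), n_germ, replace = TRUE),
    sample(coding_classes, n_germ, replace = TRUE, prob = coding_probs))
  classification[is_art] <- sample(coding_classes, n_art, replace = TRUE,
                                   prob = coding_probs)

  gene <- sprintf("GENE%04d", sample(1:2000, n, replace = TRUE))
  context7 <- random_context7(ref, alt)
  supporting <- clean_supporting_reads(pos, alt_count)

  # population rarity and database membership
  rarity <- rep("none", n)
  rarity[is_germ] <- ifelse(runif(n_germ) < params$rare_fraction,
                            "rare", "common")
  pop_af <- numeric(n)
  pop_af[rarity == "common"] <- rbeta(sum(rarity == "common"), 2, 5)
  pop_af[rarity == "rare"] <- rbeta(sum(rarity == "rare"), 1, 200)
  presence_p <- rep(params$db_presence_somatic, n)
  presence_p[rarity == "common"] <- params$db_presence_common
  presence_p[rarity == "rare"] <- params$db_presence_rare
  db_present <- vapply(germline_db_slots(), function(slot) {
    runif(n) < presence_p
  }, logical(n))
  if (n == 1) db_present <- matrix(db_present, nrow = 1)
  colnames(db_present) <- paste0("in_", germline_db_slots())

  # planted filter violations on artifact records
  violation <- rep(NA_character_, n)
  if (n_art > 0) {
    violation[is_art] <- sample(filter_violation_types(), n_art,
                                replace = TRUE)
    art_idx <- which(is_art)
    for (i in art_idx) {
      switch(violation[i],
        low_alt = {
          alt_count[i] <- sample(0:2, 1)
          ref_count[i] <- depth[i] - alt_count[i]
          tumor_f[i] <- alt_count[i] / depth[i]
          supporting[i] <- clean_supporting_reads(pos[i], alt_count[i])
        },
        noncoding = {
          classification[i] <- sample(noncoding_classes(), 1)
        },
        duplicate_reads = {
          one <- paste0(pos[i] - 40, "-", pos[i] + 35)
          supporting[i] <- paste(rep(one, alt_count[i]), collapse = ";")
        },
        leakage = {
          flank_idx <- c(1:3, 5:7)
          bases <- strsplit(context7[i], "")[[1]]
          bases[sample(flank_idx, 4)] <- alt[i]
          context7[i] <- paste(bases, collapse = "")
        },
        pseudogene = {
          gene[i] <- sprintf("PSG%03d", sample(1:20, 1))
        },
        NULL)  # editing_site / exac_common / pon_hot handled at bundle level
    }
  }

  out <- data.frame(
    sample_id = sample_id, chrom = chrom, pos = pos,
    ref_allele = ref, alt_allele = alt,
    t_ref_count = as.integer(ref_count), t_alt_count = as.integer(alt_count),
    t_lod_fstar = round(lod, 3), tumor_f = round(tumor_f, 6),
    variant_classification = classification, gene_symbol = gene,
    context7 = context7, supporting_reads = supporting,
    failure_reasons = "", truth = truth,
    pop_af = round(pop_af, 6), rarity = rarity,
    violation = violation, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(db_present))
  # matched-normal caller outcome used for training labels
  out$failure_reasons[is_germ] <- sample(germline_failure_tags(), n_germ,
                                         replace = TRUE)
  out$failure_reasons[is_art] <- "clustered_read_position"
  out$passed_full_pipeline <- is_som
  out$label <- ifelse(is_som, "somatic", ifelse(is_germ, "germline", ""))
  out
}

# Simulate one panel's histograms for the cohort's variant positions.
# Carrier positions (germline variants represented in the panel) draw
# per-normal genotypes at the population AF (Hardy-Weinberg) with binomial
# read counts; artifact-hot positions give a subset of normals low-fraction
# alt evidence; everything else is left out of the panel map (no-evidence
# default at lookup).
#' Simulate a panel-of-normals histogram table
#'
#' @param variants cohort variant table from [simulate_sample()] rows.
#' @param params \code{sim_params}.
#' @param seed RNG seed.
#' @param presence_germline probability a germline position is in the panel.
#' @param artifact_somatic probability a somatic/artifact position is a
#'   recurrent panel artifact.
#' @return a \code{pon_histogram} over the represented positions.
#' @export
simulate_pon <- function(variants, params, seed,
                         presence_germline, artifact_somatic) {
  set.seed(seed)
  if (params$pon_panel_size <= 0) {
    stop("simulate_pon: panel size must be positive", call. = FALSE)
  }
  m <- params$pon_panel_size
  is_germ <- variants$truth == "germline"
  is_art <- variants$truth == "artifact"
  carrier <- is_germ & runif(nrow(variants)) < presence_germline
  # only artifact records can be panel-hot: truth-somatic calls have by
  # definition survived both PoN filters of the matched-normal chain
  hot <- is_art & (runif(nrow(variants)) < artifact_somatic |
                     (!is.na(variants$violation) &
                        variants$violation == "pon_hot"))
  keep <- carrier | hot
  if (!any(keep)) {
    return(pon_histogram(matrix(integer(0), ncol = 8), m))
  }
  v <- variants[keep, , drop = FALSE]
  n_pos <- nrow(v)
  q <- ifelse(v$truth == "germline", pmax(v$pop_af, 0.005), 0)
  # per-normal fractions: HW genotypes for carriers, sporadic low-fraction
  # noise for artifact-hot positions
  qm <- matrix(rep(q, each = m), nrow = m)
  u <- matrix(runif(n_pos * m), nrow = m)
  frac <- matrix(0.001, nrow = m, ncol = n_pos)
  frac[u < qm^2 + 2 * qm * (1 - qm)] <- 0.5
  frac[u < qm^2] <- 0.98
  hot_cols <- which(v$truth != "germline")
  if (length(hot_cols) > 0) {
    noisy <- matrix(runif(length(hot_cols) * m) < 0.3, nrow = m)
    frac[, hot_cols][noisy] <- runif(sum(noisy), 0.03, 0.15)
  }
  depth <- matrix(pmax(1L, rpois(n_pos * m, 60)), nrow = m)
  alt <- matrix(rbinom(n_pos * m, depth, frac), nrow = m)
  bins <- assign_bin(as.vector(alt), as.vector(depth))
  pos_idx <- rep(seq_len(n_pos), each = m)
  tab <- tabulate(bins + 8L * (pos_idx - 1L), nbins = 8L * n_pos)
  counts <- matrix(tab, ncol = 8, byrow = TRUE,
                   dimnames = list(paste(normalize_chrom(v$chrom), v$pos,
                                         sep = ":"),
                                   paste0("h", 1:8)))
  pon_histogram(counts, m)
}

# Build one germline database resource from the cohort's membership draws.
resource_from_cohort <- function(variants, slot, seed) {
  set.seed(seed)
  in_db <- variants[[paste0("in_", slot)]]
  v <- variants[in_db, , drop = FALSE]
  af <- v$pop_af
  af[v$truth != "germline"] <- round(rbeta(sum(v$truth != "germline"),
                                           1, 500), 6)
  af[runif(nrow(v)) < 0.1] <- NA  # some entries carry no AF
  germline_resource(v$chrom, v$pos, v$ref_allele, v$alt_allele, af,
                    name = slot)
}

#' Simulate a full cohort bundle
#'
#' Generates every input the pipeline consumes: the labeled variant table,
#' the four germline database resources, a population-exome resource for the
#' frequency filter, DNA and RNA panels of normals, the RNA-editing site and
#' pseudogene/IgG gene lists, and per-sample clinical records whose
#' exponential survival hazard is multiplied by
#' exp(log_tmb_coef x log10(TMB + 1)).
#'
#' @param params \code{sim_params} from [simulation_params()].
#' @return list of class \code{sim_bundle} with elements \code{variants},
#'   \code{resources} (named list dbsnp/gnomad/g1000/esp), \code{exac},
#'   \code{dna_pon}, \code{rna_pon}, \code{editing_sites},
#'   \code{artifact_genes}, \code{clinical}, \code{params}.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  samples <- sprintf("S%04d", seq_len(params$n_samples))
  per_sample <- lapply(seq_along(samples), function(i) {
    simulate_sample(samples[i], params, sub_seed(params$master_seed, i))
  })
  variants <- as.data.frame(data.table::rbindlist(per_sample))

  n_total <- params$n_samples
  resources <- setNames(lapply(seq_along(germline_db_slots()), function(j) {
    resource_from_cohort(variants, germline_db_slots()[j],
                         sub_seed(params$master_seed, 100000 + j))
  }), germline_db_slots())

  # population-exome resource for the MAF filter: common germline variants
  # plus the planted exac_common artifacts
  set.seed(sub_seed(params$master_seed, 200000))
  in_exac <- (variants$rarity == "common" & runif(nrow(variants)) < 0.95) |
    (!is.na(variants$violation) & variants$violation == "exac_common")
  ev <- variants[in_exac, , drop = FALSE]
  exac_af <- ev$pop_af
  planted <- !is.na(ev$violation) & ev$violation == "exac_common"
  exac_af[planted] <- runif(sum(planted), 0.06, 0.5)
  exac <- germline_resource(ev$chrom, ev$pos, ev$ref_allele, ev$alt_allele,
                            round(exac_af, 6), name = "exac")

  dna_pon <- simulate_pon(variants, params,
                          sub_seed(params$master_seed, 300000),
                          params$pon_presence_germline_dna,
                          params$pon_artifact_dna)
  rna_pon <- simulate_pon(variants, params,
                          sub_seed(params$master_seed, 300001),
                          params$pon_presence_germline_rna,
                          params$pon_artifact_rna)

  set.seed(sub_seed(params$master_seed, 400000))
  planted_edit <- !is.na(variants$violation) &
    variants$violation == "editing_site"
  decoys <- sprintf("%s:%d", sample(canonical_chromosomes(), 200, TRUE),
                    sample(1e7:2e8, 200))
  editing_sites <- unique(c(
    paste(normalize_chrom(variants$chrom[planted_edit]),
          variants$pos[planted_edit], sep = ":"), decoys))
  artifact_genes <- unique(c(sprintf("PSG%03d", 1:20),
                             sprintf("IGHV%d", 1:5)))

  # clinical records linked to the true TMB
  tmb_true <- compute_tmb(variants[variants$truth == "somatic", , drop = FALSE],
                          sample_ids = samples)
  set.seed(sub_seed(params$master_seed, 500000))
  hazard <- params$baseline_hazard *
    exp(params$log_tmb_coef * log10(tmb_true + 1))
  event_time <- rexp(n_total, hazard)
  censor_time <- rexp(n_total, params$censor_hazard)
  clinical <- data.frame(
    sample_id = samples,
    os_time = round(pmin(event_time, censor_time), 1),
    os_event = as.integer(event_time <= censor_time),
    age = round(rnorm(n_total, 60, 10), 1),
    stage = sample(c("I", "II", "III", "IV"), n_total, TRUE,
                   prob = c(0.2, 0.3, 0.35, 0.15)),
    stringsAsFactors = FALSE)

  structure(list(variants = variants, resources = resources, exac = exac,
                 dna_pon = dna_pon, rna_pon = rna_pon,
                 editing_sites = editing_sites,
                 artifact_genes = artifact_genes,
                 clinical = clinical, params = params),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle: ", x$params$n_samples, " samples, ",
      nrow(x$variants), " variant records (",
      sum(x$variants$truth == "somatic"), " somatic, ",
      sum(x$variants$truth == "germline"), " germline, ",
      sum(x$variants$truth == "artifact"), " artifact)\n", sep = "")
  invisible(x)
}

#' Write a simulated bundle to a directory of TSV files
#'
#' Emits the same plain-text formats the pipeline readers consume:
#' variants.tsv, one TSV per germline resource, exac.tsv, dna_pon.tsv,
#' rna_pon.tsv, editing_sites.tsv, artifact_genes.tsv, clinical.tsv.
#'
#' @param bundle a \code{sim_bundle}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(bundle$variants, file.path(dir, "variants.tsv"))
  truth_cols <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
                  "truth")
  data.table::fwrite(bundle$variants[, truth_cols],
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE)
  for (slot in names(bundle$resources)) {
    write_germline_resource(bundle$resources[[slot]],
                            file.path(dir, paste0(slot, ".tsv")))
  }
  write_germline_resource(bundle$exac, file.path(dir, "exac.tsv"))
  write_pon(bundle$dna_pon, file.path(dir, "dna_pon.tsv"))
  write_pon(bundle$rna_pon, file.path(dir, "rna_pon.tsv"))
  parts <- do.call(rbind, strsplit(bundle$editing_sites, ":", fixed = TRUE))
  data.table::fwrite(data.frame(chrom = parts[, 1],
                                pos = as.integer(parts[, 2])),
                     file.path(dir, "editing_sites.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(data.frame(gene_symbol = bundle$artifact_genes),
                     file.path(dir, "artifact_genes.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(bundle$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}
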