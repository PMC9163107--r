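test_that("variant tables round-trip and non-canonical contigs are dropped", {
  v <- make_variants(n = 4, chrom = c("1", "chr2", "X", "22"),
                     context7 = "CCCATTT", supporting_reads = "10-85;20-95",
                     failure_reasons = "germline_risk")
  v$chrom <- c("1", "chr2", "X", "22")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  back <- read_variant_table(path)
  expect_equal(nrow(back), 4)
  expect_equal(back$chrom, c("1", "2", "X", "22"))  # chr prefix stripped
  expect_equal(back$pos, v$pos)
  expect_equal(back$tumor_f, v$tumor_f)
  expect_equal(back$supporting_reads, v$supporting_reads)

  # a second round trip after normalization is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(back, path2)
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(read_variant_table(path2), path3)
  expect_identical(readLines(path2), readLines(path3))

  # MT row dropped with a message; header-only file gives an empty table
  v5 <- make_variants(n = 5)
  v5$chrom <- c("1", "2", "MT", "3", "4")
  write_variant_table(v5, path)
  expect_message(got <- read_variant_table(path), "dropped 1")
  expect_equal(nrow(got), 4)
  write_variant_table(v5[0, ], path)
  expect_equal(nrow(read_variant_table(path)), 0)
})

test_that("missing columns and unparsable numerics are reported by name", {
  v <- make_variants(n = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- v[, setdiff(names(v), "tumor_f")]
  data.table::fwrite(tab, path, sep = "\t")
  expect_error(read_variant_table(path), "tumor_f")

  v$t_alt_count <- c("7", "oops")
  data.table::fwrite(v, path, sep = "\t")
  expect_error(read_variant_table(path), "row 2")
})

test_that("dialect mapping loads tables with foreign headers", {
  v <- make_variants(n = 2)
  names(v)[names(v) == "chrom"] <- "Chromosome"
  names(v)[names(v) == "pos"] <- "Start_position"
  path <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(v, path, sep = "\t")
  dialect <- default_dialect()
  dialect[c("chrom", "pos")] <- c("Chromosome", "Start_position")
  got <- read_variant_table(path, dialect)
  expect_equal(got$pos, c(1000L, 1100L))

  dpath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("chrom: Chromosome", "pos: Start_position"), dpath)
  expect_equal(read_variant_table(path, read_dialect(dpath))$pos,
               c(1000L, 1100L))
})

test_that("labeling is a pure function of tags and pipeline outcome", {
  expect_equal(as.character(label_from_matched_normal("germline_risk", FALSE)),
               "germline")
  expect_equal(as.character(label_from_matched_normal("", TRUE)), "somatic")
  expect_equal(as.character(
    label_from_matched_normal("clustered_read_position", FALSE)), "unlabeled")

  # exhaustive enumeration over subsets of the tag vocabulary x outcome
  vocab <- c("normal_lod", "germline_risk", "alt_allele_in_normal",
             "clustered_read_position", "poor_mapping", "strand_artifact")
  germline_tags <- vocab[1:3]
  for (mask in 0:(2^length(vocab) - 1)) {
    tags <- vocab[bitwAnd(mask, 2^(seq_along(vocab) - 1)) > 0]
    joined <- paste(tags, collapse = ",")
    for (passed in c(TRUE, FALSE)) {
      got <- as.character(label_from_matched_normal(joined, passed))
      expected <- if (any(tags %in% germline_tags)) "germline"
        else if (passed) "somatic" else "unlabeled"
      expect_identical(got, expected)
    }
  }
})

test_that("germline resources compute mean AF and impute it on lookup", {
  r <- germline_resource(c("1", "1"), c(100L, 200L), c("A", "C"),
                         c("G", "T"), c(0.1, 0.3), name = "toy")
  expect_equal(r$mean_af, 0.2)
  hit <- germline_lookup(r, "1", 100, "A", "G")
  expect_equal(hit$present, 1L)
  expect_equal(hit$af, 0.1)
  miss <- germline_lookup(r, "1", 100, "A", "T")  # allele-exact matching
  expect_equal(miss$present, 0L)
  expect_equal(miss$af, 0.2)

  expect_warning(
    r2 <- germline_resource("1", 100L, "A", "G", NA_real_), "0.5")
  expect_equal(germline_lookup(r2, "1", 100, "A", "G")$af, 0.5)

  # round trip through TSV preserves lookups and mean AF
  path <- withr::local_tempfile(fileext = ".tsv")
  write_germline_resource(r, path)
  r3 <- load_germline_resource(path, "toy")
  expect_equal(r3$mean_af, r$mean_af)
  expect_equal(germline_lookup(r3, "1", 200, "C", "T")$af, 0.3)
})

test_that("site and gene lists load from TSV", {
  spath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos", "chr1\t500", "MT\t7", "2\t900"), spath)
  sites <- load_site_list(spath)
  expect_setequal(sites, c("1:500", "2:900"))  # MT excluded, chr stripped
  gpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol", "PSG001", "IGHV1"), gpath)
  expect_setequal(load_gene_list(gpath), c("PSG001", "IGHV1"))
})
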