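test_that("individual filters implement their thresholds exactly", {
  v <- make_variants(n = 3, t_alt_count = c(3L, 2L, 0L))
  expect_equal(min_alt_filter(v), c(TRUE, FALSE, FALSE))

  exac <- germline_resource(c("1", "1", "1"), c(1000L, 1100L, 1200L),
                            rep("A", 3), rep("G", 3), c(0.06, 0.05, NA),
                            name = "exac")
  ve <- make_variants(n = 4, pos = c(1000L, 1100L, 1200L, 1300L))
  # AF 0.06 fails; AF exactly 0.05 passes (strict >); unrecorded AF and
  # absent variants pass
  expect_equal(exac_filter(ve, exac), c(FALSE, TRUE, TRUE, TRUE))

  vc <- make_variants(n = 3,
                      variant_classification = c("Intron", "Missense_Mutation",
                                                 "IGR"))
  expect_equal(noncoding_filter(vc), c(FALSE, TRUE, FALSE))

  vs <- make_variants(n = 2, pos = c(500L, 600L))
  expect_equal(editing_site_filter(vs, "1:500"), c(FALSE, TRUE))
  expect_equal(editing_site_filter(vs, character(0)), c(TRUE, TRUE))

  vg <- make_variants(n = 2, gene_symbol = c("PSG001", "GENE1"))
  expect_equal(pseudogene_filter(vg, "PSG001"), c(FALSE, TRUE))
  expect_equal(pseudogene_filter(vg, character(0)), c(TRUE, TRUE))
})

test_that("duplicate supporting reads collapse to single evidence", {
  v <- make_variants(n = 3, t_alt_count = c(3L, 3L, 5L),
                     supporting_reads = c("100-175;100-175;102-177",
                                          "100-175;101-176;102-177",
                                          paste(rep("100-175", 5),
                                                collapse = ";")))
  out <- suppressMessages(duplicate_read_collapse(v))
  expect_equal(out$t_alt_count, c(2L, 3L, 1L))
  expect_equal(out$supporting_reads[1], "100-175;102-177")
  expect_equal(out$supporting_reads[2], v$supporting_reads[2])
  # records without coordinates pass through with a note
  v2 <- make_variants(n = 1, supporting_reads = NA)
  expect_message(out2 <- duplicate_read_collapse(v2), "without")
  expect_equal(out2$t_alt_count, v2$t_alt_count)
})

test_that("the leakage rule counts alternate matches among the six flanks", {
  v <- make_variants(n = 4, alt_allele = c("G", "A", "G", "G"),
                     ref_allele = c("A", "G", "A", "A"),
                     context7 = c("GGGAGTA", "CCCGGGG", "GGAAGTA", "GGGAGTC"))
  # GGG|A|GTA vs alt G: 4 matches -> fail; CCC|G|GGG vs alt A: 0 -> pass;
  # GGA|A|GTA vs alt G: 3 matches -> fail (at least 3); 4th record 4 -> fail
  expect_equal(leakage_filter(v), c(FALSE, TRUE, FALSE, FALSE))
  v2 <- make_variants(n = 1, context7 = NA)
  expect_message(pass <- leakage_filter(v2), "without context")
  expect_true(pass)
  expect_error(leakage_filter(make_variants(n = 1, context7 = "ACGT")),
               "length 7")
})

test_that("the chain removes the planted violation of every rule and only those", {
  fx <- filter_chain_fixture()
  res <- suppressMessages(
    apply_filter_chain(fx$variants, filter_config(), fx$exac, fx$dna_pon,
                       fx$rna_pon, fx$editing_sites, fx$artifact_genes))
  expect_equal(res$report$n_input, 12)
  expect_equal(res$report$n_survivors, 3)
  expect_setequal(res$survivors$pos, fx$variants$pos[fx$variants$violated ==
                                                       "clean"])
  # each removing filter claims exactly its designed victim
  expected <- c(min_alt = 1L, dna_pon = 1L, rna_pon = 1L, exac = 1L,
                noncoding = 1L, editing_site = 1L,
                duplicate_read_collapse = 1L, leakage = 1L,
                pseudogene_igg = 1L)
  expect_equal(res$report$filter_counts[names(expected)], expected)
  # attribution matches the design record by record
  removed <- res$report$removed_by
  expect_equal(removed[fx$variants$violated != "clean"],
               fx$variants$violated[fx$variants$violated != "clean"])
  # counts are consistent: survivors + removed = input
  expect_equal(sum(res$report$filter_counts), 12 - 3)
})

test_that("the chain is idempotent and attributes double violations to the first filter", {
  fx <- filter_chain_fixture()
  res <- suppressMessages(
    apply_filter_chain(fx$variants, filter_config(), fx$exac, fx$dna_pon,
                       fx$rna_pon, fx$editing_sites, fx$artifact_genes))
  again <- suppressMessages(
    apply_filter_chain(res$survivors, filter_config(), fx$exac, fx$dna_pon,
                       fx$rna_pon, fx$editing_sites, fx$artifact_genes))
  expect_equal(again$report$n_survivors, res$report$n_survivors)
  expect_equal(nrow(again$survivors), nrow(res$survivors))

  # a variant violating both the non-coding and pseudogene rules is
  # attributed to the earlier (non-coding) filter
  v <- fx$variants[5, , drop = FALSE]
  v$gene_symbol <- "PSG001"
  both <- suppressMessages(
    apply_filter_chain(v, filter_config(), fx$exac, fx$dna_pon, fx$rna_pon,
                       fx$editing_sites, fx$artifact_genes))
  expect_equal(both$report$removed_by, "noncoding")
})

test_that("an all-clean table passes the chain untouched and hooks are honored", {
  fx <- filter_chain_fixture()
  clean <- fx$variants[fx$variants$violated == "clean", , drop = FALSE]
  res <- suppressMessages(
    apply_filter_chain(clean, filter_config(), fx$exac, fx$dna_pon,
                       fx$rna_pon, fx$editing_sites, fx$artifact_genes))
  expect_equal(res$report$n_survivors, nrow(clean))
  expect_false(res$report$realignment_applied)

  # a user-supplied realignment hook participates in the chain
  drop_first <- function(v) seq_len(nrow(v)) != 1
  res2 <- suppressMessages(
    apply_filter_chain(clean, filter_config(), fx$exac, fx$dna_pon,
                       fx$rna_pon, fx$editing_sites, fx$artifact_genes,
                       realign_hook = drop_first))
  expect_true(res2$report$realignment_applied)
  expect_equal(res2$report$filter_counts[["realignment"]], 1L)
  expect_equal(res2$report$n_survivors, nrow(clean) - 1)
})
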