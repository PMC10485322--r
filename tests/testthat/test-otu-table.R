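test_that("TSV round trip preserves counts, lineage and confidence", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "otu_id\tpoolA\tpoolB\ttaxonomy\tconfidence",
    "OTU_7\t120\t0\tp__Arthropoda;c__Arachnida;o__Araneae;f__Lycosidae\t0.95",
    "OTU_8\t3\t9\t\t0.80"), tmp)
  md <- data.frame(pool_id = c("poolA", "poolB"),
                   species = c("sp1", "sp2"),
                   site = c("s1", "s2"), habitat = "h",
                   elevation_m = c(100, 200))
  x <- read_otu_table(tmp, metadata = md)
  expect_equal(unname(x$counts["OTU_7", ]), c(120, 0))
  expect_equal(x$lineage["OTU_7", "family"], "Lycosidae")
  expect_true(is.na(x$lineage["OTU_7", "genus"]))
  # empty taxonomy is retained with an empty lineage
  expect_true(all(is.na(x$lineage["OTU_8", ])))
  expect_equal(nrow(x$counts), 2L)
})

test_that("format errors are caught with useful messages", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tpoolA\ttaxonomy",
               "OTU_1\t5\tp__Arthropoda",
               "OTU_1\t2\tp__Arthropoda"), tmp)
  expect_error(read_otu_table(tmp), "duplicate otu_id")
  writeLines(c("otu_id\tpoolX\ttaxonomy",
               "OTU_1\t5\tp__Arthropoda"), tmp)
  md <- data.frame(pool_id = "poolA", species = "s", site = "x",
                   habitat = "h", elevation_m = 0)
  expect_error(read_otu_table(tmp, metadata = md),
               "absent from metadata")
  writeLines(c("otu_id\tpoolA\ttaxonomy",
               "OTU_1\t5\tp__Arthropoda;what_is_this"), tmp)
  expect_error(read_otu_table(tmp), "row 1")
})

test_that("plain dialect parses with a rank map", {
  m <- parse_lineage("Arthropoda;Insecta;Coleoptera", dialect = "plain",
                     rank_map = c("phylum", "class", "order"))
  expect_equal(unname(m[1, "order"]), "Coleoptera")
  expect_true(is.na(m[1, "family"]))
  expect_error(parse_lineage("x", dialect = "plain"), "rank_map")
})

test_that("filtering drops phyla and hosts, truncates low confidence", {
  lin <- parse_lineage(c(
    "p__Arthropoda;c__Insecta;o__Coleoptera",
    "p__Streptophyta;c__X;o__Y",
    "p__Chordata;c__Reptilia;o__Squamata;f__Phrynosomatidae;g__Sceloporus;s__jarrovii",
    "p__Arthropoda;c__Insecta;o__Diptera"))
  counts <- matrix(1, 4, 1, dimnames = list(paste0("O", 1:4), "p1"))
  x <- otu_table(counts, lin, c(0.9, 0.9, 0.99, 0.65))
  f <- filter_otus(x, host_taxa = "Sceloporus", min_confidence = 0.7)
  expect_setequal(rownames(f$counts), c("O1", "O4"))
  # O4's order support (0.65) fell below threshold: truncated, not dropped
  expect_true(is.na(f$lineage["O4", "order"]))
  expect_equal(f$lineage["O4", "class"], "Insecta")
  # idempotence
  expect_identical(filter_otus(f, host_taxa = "Sceloporus"), f)
  expect_error(filter_otus(x, host_taxa = character(0)), "host list")
})

test_that("synthetic study table yields 51 prey OTUs after filtering", {
  fit <- study_fixture_fit()
  f <- filter_otus(fit$otu, host_taxa = "Sceloporus")
  expect_equal(nrow(fit$otu$counts), 53L)
  expect_equal(nrow(f$counts), 51L)
})

test_that("incidence construction unions pools and is order-invariant", {
  md <- data.frame(pool_id = c("a1", "a2"), species = "A",
                   site = c("s1", "s2"), habitat = "h",
                   elevation_m = 0)
  lin <- parse_lineage(rep("p__Arthropoda", 3))
  counts <- matrix(c(5, 0,  0, 0,  0, 2), 3, 2, byrow = TRUE,
                   dimnames = list(c("O2", "O1", "O3"), c("a1", "a2")))
  x <- otu_table(counts, lin)
  inc <- build_incidence(x, md, group_by = "species")
  # present in exactly one pool => present for the species (union)
  expect_equal(unname(inc["A", c("O2", "O3")]), c(1L, 1L))
  # all-zero resource dropped; columns sorted
  expect_false("O1" %in% colnames(inc))
  expect_equal(colnames(inc), sort(colnames(inc)))
  # row-order invariance of the input
  x2 <- otu_table(counts[c(3, 1, 2), ], lin)
  expect_identical(unclass(build_incidence(x2, md,
                                           group_by = "species")),
                   unclass(inc))
  # min_reads threshold
  inc2 <- build_incidence(x, md, group_by = "species", min_reads = 3)
  expect_false("O3" %in% colnames(inc2))
})

test_that("species grouping of the study fixture gives richness 15/13/28", {
  fit <- study_fixture_fit()
  f <- filter_otus(fit$otu, host_taxa = "Sceloporus")
  inc <- build_incidence(f, fit$fx$metadata, group_by = "species")
  expect_equal(ncol(inc), 51L)
  expect_equal(rowSums(inc)[c("Sceloporus jarrovii", "Sceloporus slevini",
                              "Sceloporus virgatus")],
               c("Sceloporus jarrovii" = 15, "Sceloporus slevini" = 13,
                 "Sceloporus virgatus" = 28))
})

test_that("incidence TSV round trip is exact", {
  m <- incidence_matrix(random_presence_matrix(3, 10))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_incidence(m, tmp)
  m2 <- read_incidence(tmp)
  expect_identical(unclass(m2), unclass(m))
  expect_identical(attr(m2, "mode"), "presence")
})
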