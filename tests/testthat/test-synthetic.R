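test_that("spec validation enforces inclusion-exclusion consistency", {
  expect_error(synthetic_spec(groups = c("A", "B"),
                              richness = c(A = 5, B = 5),
                              sharing = c(A = 5, B = 5, "A+B" = 1)),
               "inclusion-exclusion violated")
  expect_error(synthetic_spec(groups = "A", richness = c(A = 3),
                              sharing = c(A = 3, "A+Z" = 0)),
               "not valid group subsets")
  s <- synthetic_spec(groups = c("A", "B"), richness = c(A = 5, B = 4),
                      sharing = c(A = 3, B = 2, "A+B" = 2))
  expect_equal(s$total_R, 7L)
})

test_that("generated presence structure recovers the spec exactly", {
  spec <- synthetic_spec(
    groups = c("A", "B", "C"),
    richness = c(A = 9, B = 7, C = 10),
    sharing = c(A = 4, B = 3, C = 6, "A+B" = 2, "A+C" = 2,
                "B+C" = 1, "A+B+C" = 1),
    seed = 13L)
  gen <- generate_diet_data(spec)
  x <- otu_table_from_df(gen$table)
  inc <- build_incidence(x, gen$metadata, group_by = "species")
  expect_equal(ncol(inc), spec$total_R)
  expect_equal(unname(rowSums(inc)[c("A", "B", "C")]), c(9, 7, 10))
  v <- venn_counts(inc)
  expect_equal(v[["A&B"]], 2L)
  expect_equal(v[["A&C"]], 2L)
  expect_equal(v[["B&C"]], 1L)
  expect_equal(v[["A&B&C"]], 1L)
  # determinism under the spec seed
  gen2 <- generate_diet_data(spec)
  expect_identical(gen$table, gen2$table)
})

test_that("metrics on generated data equal closed forms to 1e-12", {
  spec <- synthetic_spec(groups = c("A", "B"),
                         richness = c(A = 5, B = 8),
                         sharing = c(A = 3, B = 6, "A+B" = 2),
                         seed = 2L)
  gen <- generate_diet_data(spec)
  x <- otu_table_from_df(gen$table)
  inc <- build_incidence(x, gen$metadata, group_by = "species")
  R <- spec$total_R
  b <- niche_breadth(inc)
  expect_equal(b$B[b$group == "A"], 5, tolerance = 1e-12)
  expect_equal(b$B_A[b$group == "B"], (8 - 1) / (R - 1),
               tolerance = 1e-12)
  o <- niche_overlap(inc)
  expect_equal(o$O, 2 / sqrt(5 * 8), tolerance = 1e-12)
  # single group, richness 5
  s1 <- synthetic_spec(groups = "A", richness = c(A = 5),
                       sharing = c(A = 5), seed = 1L)
  g1 <- generate_diet_data(s1)
  inc1 <- build_incidence(otu_table_from_df(g1$table), g1$metadata,
                          group_by = "species")
  expect_equal(niche_breadth(inc1)$B, 5, tolerance = 1e-12)
  # disjoint groups overlap exactly 0
  s0 <- synthetic_spec(groups = c("A", "B"),
                       richness = c(A = 4, B = 6),
                       sharing = c(A = 4, B = 6), seed = 1L)
  g0 <- generate_diet_data(s0)
  inc0 <- build_incidence(otu_table_from_df(g0$table), g0$metadata,
                          group_by = "species")
  expect_identical(niche_overlap(inc0)$O, 0)
})

test_that("order-count generator recovers truth proportions", {
  orders <- paste0("ord", 1:6)
  g <- generate_order_counts(c("A", "B"), orders, concentration = 2,
                             totals = 400, seed = 21L)
  for (gr in c("A", "B")) {
    obs <- unclass(g$matrix)[gr, ]
    p <- g$truth[gr, colnames(g$matrix)]
    se <- sqrt(p * (1 - p) / 400)
    expect_true(all(abs(obs / 400 - p) < 3 * se + 1e-9))
  }
  # high concentration approaches evenness
  gu <- generate_order_counts("A", orders, concentration = 1e6,
                              totals = 6000, seed = 4L)
  J <- niche_breadth(gu$matrix)$J
  expect_gt(J, 0.99)
  # seed determinism
  expect_identical(unclass(generate_order_counts("A", orders, 1, 50,
                                                 seed = 8L)$matrix),
                   unclass(generate_order_counts("A", orders, 1, 50,
                                                 seed = 8L)$matrix))
})

test_that("study fixture bookkeeping is self-consistent", {
  fx <- study_fixture()
  expect_equal(sum(fx$truth$order_counts), 47)  # 42 distinct + 5 shared
  expect_equal(unname(rowSums(fx$truth$pool_order_counts)),
               c(3, 10, 3, 5, 8, 18))
  # pool-level table aggregates to the species-level table
  agg <- rowsum(fx$truth$pool_order_counts,
                fx$metadata$species[match(rownames(fx$truth$pool_order_counts),
                                          fx$metadata$pool_id)])
  expect_equal(agg[rownames(fx$truth$order_counts), ],
               fx$truth$order_counts)
})
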