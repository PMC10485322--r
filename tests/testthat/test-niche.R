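test_that("profiles follow the definitions in both modes", {
  pr <- resource_profile(c(1, 1, 0, 1), mode = "presence")
  expect_equal(pr$p, c(1/3, 1/3, 0, 1/3))
  expect_equal(pr$n_used, 3L)
  expect_equal(pr$R, 4L)
  pc <- resource_profile(c(4, 1, 0), mode = "count")
  expect_equal(pc$p, c(0.8, 0.2, 0))
  expect_error(resource_profile(c(0, 0)), "empty diet")
})

test_that("breadth indices match hand-computed oracles", {
  # 1/(0.64 + 0.04) = 1.470588...
  p <- resource_profile(c(4, 1), mode = "count")
  expect_equal(levins_breadth(p)[["B"]], 1 / 0.68, tolerance = 1e-12)
  # single resource: minimal breadth
  one <- resource_profile(c(0, 1, 0), mode = "presence")
  expect_equal(unname(levins_breadth(one)), c(1, 0))
  expect_equal(unname(shannon_breadth(one)), c(0, 0))
  # R < 2 has no standardized form
  expect_error(levins_breadth(resource_profile(1, "presence")),
               "R >= 2")
})

test_that("overlap indices match definitions and closed forms", {
  u <- resource_profile(c(1, 1, 0, 0), "presence")
  v <- resource_profile(c(0, 0, 1, 1), "presence")
  expect_equal(unname(macarthur_levins_overlap(u, v)), c(0, 0))
  expect_equal(pianka_overlap(u, v), 0)
  expect_equal(pianka_overlap(u, u), 1, tolerance = 1e-12)
  expect_equal(unname(macarthur_levins_overlap(u, u)), c(1, 1),
               tolerance = 1e-12)
  w <- resource_profile(c(1, 1, 1), "presence")
  expect_error(pianka_overlap(u, w), "different resource universes")
})

test_that("presence-mode closed forms agree with the general formulas", {
  set.seed(42)
  for (i in 1:300) {
    m <- random_presence_matrix(2, sample(4:12, 1))
    nj <- sum(m[1, ]); nk <- sum(m[2, ]); s <- sum(m[1, ] & m[2, ])
    pj <- resource_profile(m[1, ], "presence")
    pk <- resource_profile(m[2, ], "presence")
    expect_equal(levins_breadth(pj)[["B"]], nj, tolerance = 1e-12)
    expect_equal(pianka_overlap(pj, pk), s / sqrt(nj * nk),
                 tolerance = 1e-12)
    ml <- macarthur_levins_overlap(pj, pk)
    expect_equal(unname(ml), c(s / nk, s / nj), tolerance = 1e-12)
    expect_equal(shannon_breadth(pj)[["J"]],
                 log(nj) / log(ncol(m)), tolerance = 1e-12)
  }
})

test_that("bounds, symmetry and permutation invariance hold", {
  set.seed(7)
  for (i in 1:200) {
    R <- sample(3:15, 1)
    v1 <- rpois(R, 2); v2 <- rpois(R, 2)
    if (sum(v1) == 0 || sum(v2) == 0) next
    p1 <- resource_profile(v1, "count"); p2 <- resource_profile(v2, "count")
    lb <- levins_breadth(p1); sb <- shannon_breadth(p1)
    expect_true(lb[["B"]] >= 1 - 1e-12 && lb[["B"]] <= R + 1e-12)
    expect_true(lb[["B_A"]] >= -1e-12 && lb[["B_A"]] <= 1 + 1e-12)
    expect_true(sb[["J"]] >= -1e-12 && sb[["J"]] <= 1 + 1e-12)
    O <- pianka_overlap(p1, p2)
    expect_equal(O, pianka_overlap(p2, p1), tolerance = 1e-12)
    expect_true(O >= -1e-12 && O <= 1 + 1e-12)
    # permutation invariance
    perm <- sample(R)
    expect_equal(pianka_overlap(resource_profile(v1[perm], "count"),
                                resource_profile(v2[perm], "count")),
                 O, tolerance = 1e-12)
    expect_equal(levins_breadth(resource_profile(v1[perm], "count")),
                 lb, tolerance = 1e-12)
  }
  # B = R iff uniform over the full universe
  expect_equal(levins_breadth(resource_profile(rep(2, 6), "count"))[["B"]],
               6, tolerance = 1e-12)
})

test_that("Pianka reaches 1 exactly iff profiles are proportional", {
  v <- c(3, 1, 2, 0)
  p1 <- resource_profile(v, "count")
  p2 <- resource_profile(2 * v, "count")
  expect_equal(pianka_overlap(p1, p2), 1, tolerance = 1e-12)
  p3 <- resource_profile(c(3, 1, 1, 1), "count")
  expect_true(pianka_overlap(p1, p3) < 1 - 1e-12)
})

test_that("venn counts partition the resource set", {
  raw <- rbind(A = c(1, 1, 0, 0, 1),
               B = c(0, 1, 1, 0, 1),
               C = c(0, 0, 0, 1, 1))
  colnames(raw) <- paste0("r", 1:5)
  m <- incidence_matrix(raw)
  v <- venn_counts(m)
  expect_equal(sum(v), 5L)
  expect_equal(v[["A"]], 1L)
  expect_equal(v[["A&B"]], 1L)
  expect_equal(v[["A&B&C"]], 1L)
  # duplicated single group: everything in the intersection cell
  draw <- rbind(A = c(1, 1), B = c(1, 1))
  colnames(draw) <- c("r1", "r2")
  expect_equal(venn_counts(incidence_matrix(draw))[["A&B"]], 2L)
  set.seed(3)
  rm3 <- incidence_matrix(random_presence_matrix(3, 20))
  expect_equal(sum(venn_counts(rm3)), ncol(rm3))
  rm4 <- incidence_matrix(random_presence_matrix(4, 8))
  expect_error(venn_counts(rm4), "2 or 3 groups")
})

test_that("fixture pairwise sharing inverts the published overlap", {
  fit <- study_fixture_fit()
  f <- filter_otus(fit$otu, host_taxa = "Sceloporus")
  inc <- build_incidence(f, fit$fx$metadata, group_by = "species")
  v <- venn_counts(inc)
  expect_equal(v[["Sceloporus jarrovii&Sceloporus virgatus"]], 4L)
  expect_equal(v[["Sceloporus slevini&Sceloporus virgatus"]], 1L)
  expect_equal(v[["Sceloporus jarrovii&Sceloporus slevini"]], 0L)
  expect_equal(sum(v), 51L)
})
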