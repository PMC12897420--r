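test_that("the default trait schema has 8 traits and 41 categories", {
  sch <- default_trait_schema()
  expect_equal(nrow(sch), 41)
  expect_equal(length(levels(sch$trait)), 8)
  expect_equal(unname(table(sch$trait)[levels(sch$trait)]),
               c(7L, 4L, 4L, 6L, 3L, 6L, 8L, 3L), ignore_attr = TRUE)
  expect_silent(validate_trait_schema(sch))
  dup <- data.frame(trait = c("a", "a"), category = c("x", "x"))
  expect_error(validate_trait_schema(dup), "duplicate")
})

test_that("taxonomic indices match direct formula evaluation", {
  mono <- taxonomic_indices(c(0, 7, 0))
  expect_equal(mono[["H"]], 0)
  expect_equal(mono[["D"]], 1)
  expect_true(is.na(mono[["E"]]))

  unif <- taxonomic_indices(rep(6, 4))
  expect_equal(unif[["H"]], log(4))
  expect_equal(unif[["E"]], 1)
  expect_equal(unif[["D"]], 0.25)

  # frozen hand computation for counts (10, 5, 5)
  got <- taxonomic_indices(c(10, 5, 5))
  expect_equal(got[["H"]], 1.0397208, tolerance = 1e-6)
  expect_equal(got[["E"]], 0.9463948, tolerance = 1e-6)
  expect_equal(got[["D"]], 0.375)

  expect_error(taxonomic_indices(c(0, 0)), "all-zero")
})

test_that("trait normalisation yields per-trait probability profiles", {
  sch <- data.frame(trait = c("t1", "t1", "t1", "t1", "t2", "t2"),
                    category = c("a", "b", "c", "d", "e", "f"))
  tm <- rbind(c(3, 0, 0, 0, 1, 1),
              c(1, 1, 1, 0, 0, 0))
  out <- normalize_traits(tm, sch)
  expect_equal(out$profiles[1, 1:4], c(1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(out$profiles[2, 1:4], c(1, 1, 1, 0) / 3, ignore_attr = TRUE)
  expect_true(out$missing[2, "t2"])   # all-zero block flagged, not fatal
  expect_false(out$missing[1, "t2"])
  expect_error(normalize_traits(rbind(c(4, 0, 0, 0, 0, 0)), sch), "0, 3")
})

test_that("trait distances are bounded, symmetric and match brute force", {
  sch <- default_trait_schema()
  tm <- gen_trait_matrix(6, sch, seed = 5)
  prof <- normalize_traits(tm, sch)
  d <- trait_distance(prof, sch)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 6), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(d), oracle_trait_distance(prof$profiles, prof$missing, sch),
               tolerance = 1e-12)

  # identical profiles at distance zero
  tm2 <- rbind(tm[1, ], tm[1, ])
  d2 <- trait_distance(normalize_traits(tm2, sch), sch)
  expect_equal(d2[1, 2], 0)

  # disjoint single-category affinities in every trait give distance one
  sch2 <- data.frame(trait = rep(c("t1", "t2"), each = 2),
                     category = c("a", "b", "c", "d"))
  tmd <- rbind(c(3, 0, 3, 0), c(0, 3, 0, 3))
  dd <- trait_distance(normalize_traits(tmd, sch2), sch2)
  expect_equal(dd[1, 2], 1)
})

test_that("Rao entropy equals the double-loop oracle and its closed forms", {
  # two families at distance 1 with equal shares
  expect_equal(rao_entropy(c(0.5, 0.5), matrix(c(0, 1, 1, 0), 2)), 0.5)
  # functionally identical present families
  d0 <- matrix(0, 3, 3)
  expect_equal(rao_entropy(c(0.2, 0.3, 0.5), d0), 0)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:10, 1)
    d <- as.matrix(dist(matrix(runif(n * 3), n)))
    d <- d / max(d)
    p <- rgamma(n, 1); p <- p / sum(p)
    expect_equal(rao_entropy(p, d), oracle_rao(p, d), tolerance = 1e-12)
    expect_lte(rao_entropy(p, d), max(d))
    # zero-abundance families leave Rao unchanged
    expect_equal(rao_entropy(c(p, 0), rbind(cbind(d, 1), c(rep(1, n), 0))),
                 rao_entropy(p, d))
  }
})

test_that("FAD1 equals the pairwise-sum oracle and grows with richness", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2)
  expect_equal(fad1(c(TRUE, FALSE), d), 0)
  expect_equal(fad1(c(TRUE, TRUE), d), 0.4)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:10, 1)
    dm <- as.matrix(dist(matrix(runif(n * 4), n)))
    pres <- runif(n) > 0.4
    expect_equal(fad1(pres, dm), oracle_fad1(pres, dm), tolerance = 1e-12)
    # adding a family never decreases FAD1
    grow <- pres
    grow[which(!pres)[1]] <- TRUE
    if (any(!pres)) expect_gte(fad1(grow, dm), fad1(pres, dm))
  }
})

test_that("weighted functional divergence has the stated closed forms", {
  sch <- default_trait_schema()
  tm <- gen_trait_matrix(2, sch, seed = 9)
  prof <- normalize_traits(tm, sch)
  # single present family
  expect_equal(wfdc(c(1, 0), prof, sch), 0)
  # identical profiles
  tm_same <- rbind(tm[1, ], tm[1, ])
  prof_same <- normalize_traits(tm_same, sch)
  expect_equal(wfdc(c(0.3, 0.7), prof_same, sch), 0)
  # two distinct profiles with equal shares: half the Euclidean distance
  x <- prof$profiles
  expect_equal(wfdc(c(0.5, 0.5), prof, sch),
               0.5 * sqrt(sum((x[1, ] - x[2, ])^2)))
})

test_that("the diversity table is invariant to relabeling and rescaling", {
  sch <- default_trait_schema()
  tm <- gen_trait_matrix(8, sch, seed = 13)
  set.seed(14)
  ab <- matrix(rpois(8 * 5, 12), 8, 5,
               dimnames = list(rownames(tm), paste0("e", 1:5)))
  ab[ab == 0] <- 1
  div <- diversity_table(ab, tm, sch)
  expect_equal(nrow(div), 5)
  expect_equal(names(div), c("event", "H", "E", "D", "Rao", "FAD1", "wFDc"))

  # permuting family order changes nothing
  perm <- sample(8)
  div_p <- diversity_table(ab[perm, ], tm[perm, ], sch)
  expect_equal(div_p[-1], div[-1], tolerance = 1e-12)

  # doubling all counts in an event changes nothing
  ab2 <- ab; ab2[, 3] <- 2L * ab2[, 3]
  expect_equal(diversity_table(ab2, tm, sch)[-1], div[-1], tolerance = 1e-12)

  # H <= ln(S) always
  s_per_event <- colSums(ab > 0)
  expect_true(all(div$H <= log(s_per_event) + 1e-12))
  expect_true(all(div$D >= 1 / s_per_event - 1e-12))
})
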