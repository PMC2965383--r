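test_that("r-squared matches hand enumeration and its invariances", {
  H <- rbind(
    c(1L, 1L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L), c(0L, 0L, 1L),
    c(0L, 0L, 1L), c(0L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L)
  )
  p <- haplotype_panel(H, c(100L, 200L, 300L), rep("A", 3), rep("C", 3))
  # identical columns
  expect_equal(ld_r2(p, 1, 2), 1)
  # hand enumeration for columns 1 and 3:
  # pa = 4/8, pb = 4/8, p11 = 1/8 -> ((1/8 - 1/4)^2) / (1/16) = 0.25
  expect_equal(ld_r2(p, 1, 3), 0.25)
  # symmetry
  expect_equal(ld_r2(p, 3, 1), ld_r2(p, 1, 3))
  # allele relabeling (complement a column)
  H2 <- H
  H2[, 3] <- 1L - H2[, 3]
  p2 <- haplotype_panel(H2, p$positions, p$ref, p$alt)
  expect_equal(ld_r2(p2, 1, 3), ld_r2(p, 1, 3))
  # exactly complementary columns
  H3 <- cbind(H[, 1], 1L - H[, 1])
  p3 <- haplotype_panel(H3, c(1L, 2L), c("A", "A"), c("C", "C"))
  expect_equal(ld_r2(p3, 1, 2), 1)
  # monomorphic site
  H4 <- cbind(H[, 1], rep(1L, 8))
  p4 <- haplotype_panel(H4, c(1L, 2L), c("A", "A"), c("C", "C"))
  expect_error(ld_r2(p4, 1, 2), "monomorphic")
})

test_that("flanking high-LD evidence requires a spanning pair", {
  # two perfectly correlated outer markers spanning two inner positions
  H <- rbind(
    c(1L, 1L, 0L, 1L), c(1L, 0L, 1L, 1L), c(0L, 1L, 1L, 0L),
    c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L), c(0L, 0L, 1L, 0L)
  )
  p <- haplotype_panel(H, c(1000L, 2000L, 3000L, 4000L),
                       rep("A", 4), rep("C", 4))
  # columns 1 and 4 are identical: r2 = 1
  ev <- has_flanking_high_ld_pair(p, 2000L, 3000L, r2_threshold = 0.8)
  expect_true(ev$found)
  expect_true(any(ev$evidence$m1 == 1000 & ev$evidence$m2 == 4000))
  # a weak threshold fails when only low-LD spanning pairs exist
  ev2 <- has_flanking_high_ld_pair(p, 1500L, 2500L, r2_threshold = 0.999)
  expect_true(all(ev2$evidence$r2 >= 0.999) || !ev2$found)
  # nothing to the left of the leftmost site
  ev3 <- has_flanking_high_ld_pair(p, 500L, 900L)
  expect_false(ev3$found)
})

test_that("candidate prioritization applies all four rules and severity order", {
  # panel with strong LD backbone: identical outer columns
  H <- matrix(0L, 8, 6)
  H[1:4, ] <- 1L
  H[5, 2] <- 1L
  H[6, 5] <- 1L
  p <- haplotype_panel(
    H, positions = c(10000L, 50000L, 100000L, 150000L, 200000L, 400000L),
    ref = rep("A", 6), alt = rep("G", 6)
  )
  ann <- structure(list(
    genes = tibble::tibble(gene_id = "g1", start = 1L, end = 500000L),
    paralog_pairs = tibble::tibble(),
    disease_markers = tibble::tibble(
      position = c(100000L, 400000L),
      phenotype = c("t1", "t2"), known = TRUE
    ),
    known_variants = c(10000L, 100000L, 400000L)
  ), class = "annotation_set")
  calls <- tibble::tibble(
    position = c(10000L, 50000L, 100000L, 150000L, 200000L, 400000L),
    ref = "A",
    genotype = c("AG", "AG", "AG", "GG", "AA", "AA"),
    filter = "PASS",
    consequence = c("other", "non_synonymous", "other", "stop_gained",
                    "splice", "other")
  )
  out <- prioritize_novel_variants(calls, ann, p, max_distance = 250000L,
                                   r2_threshold = 0.8)
  # 10000 is known; 200000 is hom ref (not a variant); 400000 is a
  # homozygous marker region anyway; 50000 and 150000 qualify via the
  # heterozygous marker at 100000
  expect_identical(out$position, c(150000L, 50000L))
  expect_identical(out$consequence, c("stop_gained", "non_synonymous"))
  expect_identical(out$marker_position, c(100000L, 100000L))

  # a marker that is homozygous contributes nothing: drop the het call
  calls2 <- calls
  calls2$genotype[3] <- "AA"
  out2 <- prioritize_novel_variants(calls2, ann, p)
  expect_identical(nrow(out2), 0L)

  # distance rule: shrink the window so nothing is close enough
  out3 <- prioritize_novel_variants(calls, ann, p, max_distance = 10000L)
  expect_identical(nrow(out3), 0L)

  # monotonicity: relaxing thresholds never removes candidates
  wide <- prioritize_novel_variants(calls, ann, p, max_distance = 500000L,
                                    r2_threshold = 0.5)
  expect_true(all(out$position %in% wide$position))
})

test_that("enrichment tests reproduce enumeration and handle edge cases", {
  # the deleterious-variant contingency test
  tab <- matrix(c(6, 744, 19, 7249), 2)
  f1 <- enrichment_test(tab, "fisher_one_sided")
  expect_equal(f1$p_value, enum_fisher_p(tab, "greater"), tolerance = 1e-10)
  f2 <- enrichment_test(tab, "fisher_two_sided")
  expect_equal(f2$p_value, enum_fisher_p(tab, "two.sided"), tolerance = 1e-8)

  # margin-fixed enumeration oracle over random small tables
  withr::with_seed(91, {
    for (rep in 1:20) {
      t2 <- matrix(stats::rpois(4, 8) + 1L, 2)
      expect_equal(enrichment_test(t2, "fisher_one_sided")$p_value,
                   enum_fisher_p(t2, "greater"), tolerance = 1e-10)
    }
  })

  # identical row proportions: OR 1, chi-square statistic 0
  t3 <- matrix(c(10, 20, 30, 60), 2)
  cs <- enrichment_test(t3, "chi_square")
  expect_equal(cs$statistic, 0, tolerance = 1e-12)
  expect_equal(cs$odds_ratio, 1)

  # zero cell triggers the Haldane correction flag
  t4 <- matrix(c(0, 10, 5, 20), 2)
  expect_true(enrichment_test(t4, "fisher_one_sided")$haldane)

  # zero margin is rejected
  expect_error(enrichment_test(matrix(c(0, 0, 5, 20), 2)), "margin")

  # one-sided p decreases as the observed corner grows with margins fixed
  p_small <- enum_fisher_p(matrix(c(3, 7, 7, 3), 2), "greater")
  p_large <- enum_fisher_p(matrix(c(6, 4, 4, 6), 2), "greater")
  expect_lt(p_large, p_small)
})
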