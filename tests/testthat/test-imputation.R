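test_that("forward-backward posteriors equal exhaustive path-pair enumeration", {
  params <- imputation_params(switch_rate = 1e-4, mutation_rate = 0.01)
  for (s in 1:4) {
    p <- simulate_panel(4, 4, region_length = 8000,
                        recombination_intensity = 1, seed = s)
    withr::with_seed(100 + s, {
      cond <- matrix(NA_real_, 4, 3)
      for (j in c(1, 2, 4)) {
        v <- stats::runif(3)
        cond[j, ] <- v / sum(v)
      }
    })
    fb <- lowpass:::pair_genotype_posterior(p, cond, 3L, params)
    en <- enum_pair_prior(p, cond, 3L, params)
    expect_equal(fb, en, tolerance = 1e-8)
  }
  # a 5-haplotype instance with evidence on every flanking site
  p5 <- simulate_panel(5, 5, region_length = 10000, seed = 9)
  withr::with_seed(9, {
    cond5 <- matrix(stats::runif(15), 5, 3)
    cond5 <- cond5 / rowSums(cond5)
    cond5[2, ] <- NA_real_
  })
  expect_equal(lowpass:::pair_genotype_posterior(p5, cond5, 2L, params),
               enum_pair_prior(p5, cond5, 2L, params), tolerance = 1e-8)
})

test_that("uniform neighbor evidence reduces the prior to panel Hardy-Weinberg", {
  p <- fixture_panel()
  nd <- replicate(8, genotype_dist(c(AA = 1, AG = 1, GG = 1)),
                  simplify = FALSE)
  params <- imputation_params(switch_rate = 1e-5, mutation_rate = 1e-8)
  for (t in c(2L, 5L)) {
    prior <- impute_genotype_prior(t, nd, p, params)
    f <- panel_allele_freq(p)[t]
    expect_equal(prior$value, c((1 - f)^2, 2 * f * (1 - f), f^2),
                 tolerance = 1e-6)
    expect_equal(sum(prior$value), 1, tolerance = 1e-9)
  }
})

test_that("truth-certain neighbors concentrate the prior on the true genotype", {
  p <- fixture_panel()
  params <- imputation_params(switch_rate = 1e-6, mutation_rate = 1e-6)
  # rows 3 and 4 differ everywhere: het at every site
  cond <- certain_evidence(p, 3L, 4L, target = 5L)
  post <- lowpass:::pair_genotype_posterior(p, cond, 5L, params)
  expect_gt(post[2], 0.99)
  # rows 2 and 2: homozygous alt at site 5
  cond2 <- certain_evidence(p, 2L, 2L, target = 5L)
  post2 <- lowpass:::pair_genotype_posterior(p, cond2, 5L, params)
  expect_gt(post2[3], 0.99)
})

test_that("a monomorphic target column yields a homozygous prior", {
  H <- rbind(c(0L, 1L, 0L), c(1L, 1L, 1L), c(0L, 1L, 1L), c(1L, 1L, 0L))
  p <- haplotype_panel(H, c(100L, 200L, 300L), rep("A", 3), rep("C", 3))
  nd <- replicate(3, genotype_dist(c(AA = 1, AC = 1, CC = 1)),
                  simplify = FALSE)
  prior <- impute_genotype_prior(2L, nd, p,
                                 imputation_params(mutation_rate = 1e-9))
  expect_equal(prior$value[3], 1, tolerance = 1e-6)
})

test_that("genotype frequency prior is the closed-form Hardy-Weinberg law", {
  H <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  p <- haplotype_panel(H, c(10L, 20L), c("A", "C"), c("T", "G"))
  pr <- genotype_frequency_prior(1L, p)
  expect_equal(pr$value, c(0.25, 0.5, 0.25))
  expect_identical(pr$genotype, c("AA", "AT", "TT"))
  expect_error(genotype_frequency_prior(5L, p), "panel site")
})

test_that("array-based imputation respects the reporting threshold and passthrough", {
  p <- simulate_panel(40, 120, region_length = 120000,
                      recombination_intensity = 1, seed = 31)
  d <- sample_diploid(p, 0, seed = 32)
  typed_idx <- seq(1L, n_sites(p), by = 2L)
  typed <- d$genotypes[typed_idx, c("position", "gt")]
  params <- imputation_params(report_threshold = 0.9)
  out <- impute_untyped_sites(typed, p, params)

  # typed passthrough
  t_out <- out[out$typed, ]
  expect_identical(t_out$gt, typed$gt)
  # emitted untyped sites all exceed the threshold, strictly
  u_out <- out[!out$typed, ]
  expect_true(all(u_out$posterior > 0.9))
  # emitted fraction is non-increasing in the threshold
  fracs <- vapply(c(0.5, 0.7, 0.9, 0.99), function(th) {
    o <- impute_untyped_sites(typed, p,
                              imputation_params(report_threshold = th))
    sum(!o$typed)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  # accuracy of confident imputations on a zero-recombination target
  truth_u <- d$genotypes[match(u_out$position, d$genotypes$position), ]
  expect_gt(mean(u_out$gt == truth_u$gt), 0.95)

  expect_error(impute_untyped_sites(typed[0, ], p), "at least one")
})

test_that("imputation concordance grows with panel size", {
  sizes <- c(10L, 40L, 100L)
  reps <- 8L
  conc <- matrix(NA_real_, reps, length(sizes))
  for (r in seq_len(reps)) {
    p_full <- simulate_panel(100, 150, region_length = 150000,
                             recombination_intensity = 1, seed = 200 + r)
    d <- sample_diploid(p_full, 1, seed = 300 + r)
    typed_idx <- seq(1L, n_sites(p_full), by = 2L)
    typed <- d$genotypes[typed_idx, c("position", "gt")]
    for (k in seq_along(sizes)) {
      sub <- haplotype_panel(
        p_full$haplotypes[seq_len(sizes[k]), , drop = FALSE] |>
          (\(H) {
            mac <- colSums(H)
            mono <- which(mac == 0L | mac == sizes[k])
            H[1L, mono] <- 1L - H[1L, mono]
            H
          })(),
        p_full$positions, p_full$ref, p_full$alt
      )
      out <- impute_untyped_sites(typed, sub,
                                  imputation_params(report_threshold = 0))
      u <- out[!out$typed, ]
      truth_u <- d$genotypes[match(u$position, d$genotypes$position), ]
      conc[r, k] <- mean(u$gt == truth_u$gt)
    }
  }
  means <- colMeans(conc)
  expect_gt(means[3], means[1])
  fit <- stats::lm(c(conc) ~ rep(log(sizes), each = reps))
  expect_gt(stats::coef(fit)[2], 0)
})
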