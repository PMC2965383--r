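test_that("Tajima's D equals a straight-line implementation on toy matrices", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      mat <- matrix(stats::rbinom(4 * 5, 1, 0.4), nrow = 4)
      got <- tajimas_d(mat)
      want <- oracle_tajimas_d(mat)
      expect_identical(got$S, want$S)
      expect_equal(got$pi, want$pi, tolerance = 1e-12)
      if (is.na(want$D)) expect_true(is.na(got$D))
      else expect_equal(got$D, want$D, tolerance = 1e-12)
    }
    # larger sample size
    mat21 <- matrix(stats::rbinom(21 * 12, 1, 0.3), nrow = 21)
    expect_equal(tajimas_d(mat21)$D, oracle_tajimas_d(mat21)$D,
                 tolerance = 1e-12)
  })
})

test_that("monomorphic windows have undefined D and singletons drive D negative", {
  mono <- matrix(0L, 21, 10)
  res <- tajimas_d(mono)
  expect_identical(res$S, 0L)
  expect_true(is.na(res$D))

  # every variant a singleton on a different chromosome
  singletons <- matrix(0L, 21, 15)
  for (j in 1:15) singletons[(j %% 21) + 1L, j] <- 1L
  expect_lt(tajimas_d(singletons)$D, 0)

  # intermediate-frequency variants drive D positive
  balanced <- matrix(0L, 21, 15)
  balanced[1:10, ] <- 1L
  expect_gt(tajimas_d(balanced)$D, 0)

  expect_error(tajimas_d(matrix(0L, 1, 3)), "n_chromosomes")
})

test_that("window tiling is 1-based inclusive with the documented starts", {
  v <- tibble::tibble(chromosome = "chr1",
                      position = c(1L, 5000L, 10000L, 10001L, 24000L),
                      alt_count = c(1L, 5L, 10L, 3L, 7L))
  w <- sliding_window_scan(v, 10000, 5000, 21, region_length = 25000)
  expect_identical(w$start, c(1L, 5001L, 10001L, 15001L))
  expect_identical(w$end, c(10000L, 15000L, 20000L, 25000L))
  # position 10000 falls in [1,10000] and [5001,15000], not [10001,20000]
  expect_identical(w$n_sites, c(3L, 2L, 1L, 1L))
  expect_error(sliding_window_scan(v, 0, 5000), "positive")
})

test_that("per-window segregating sites match an independent recount", {
  p <- simulate_panel(21, 2000, region_length = 1e6, seed = 72)
  v <- panel_to_variants(p)
  w <- sliding_window_scan(v, 10000, 5000, 21)
  for (i in sample.int(nrow(w), 25)) {
    inside <- v$position >= w$start[i] & v$position <= w$end[i]
    cnt <- v$alt_count[inside]
    expect_identical(w$n_sites[i], sum(inside))
    expect_identical(w$S[i], sum(cnt > 0 & cnt < 21))
  }
})

test_that("outlier windows merge into maximal regions covering their union", {
  w <- tibble::tibble(
    chromosome = "chr1",
    start = c(1L, 5001L, 10001L, 20001L, 30001L, 35001L),
    end = c(10000L, 15000L, 20000L, 30000L, 40000L, 45000L),
    D = c(-2.5, -2.1, -1.0, -3.0, -2.2, NA)
  )
  r <- merge_outlier_regions(w, cutoff = -2)
  expect_identical(nrow(r), 2L)
  expect_identical(r$start, c(1L, 20001L))
  expect_identical(r$end, c(15000L, 40000L))
  expect_identical(r$n_windows, c(2L, 2L))
  # window [20001,30000] and [30001,40000] abut and merge

  # union-length invariant
  qual <- w[!is.na(w$D) & w$D < -2, ]
  union_len <- sum(r$end - r$start + 1L)
  cover <- unique(unlist(purrr::map2(qual$start, qual$end, seq.int)))
  expect_identical(union_len, length(cover))

  # positive cutoff selects the other tail
  w$D <- -w$D
  r2 <- merge_outlier_regions(w, cutoff = 2)
  expect_identical(nrow(r2), 2L)

  # no qualifying windows
  expect_identical(nrow(merge_outlier_regions(w, cutoff = -5)), 0L)
})

test_that("gene averaging is the unweighted mean over overlapping defined windows", {
  w <- tibble::tibble(
    chromosome = "chr1",
    start = c(1L, 5001L, 10001L),
    end = c(10000L, 15000L, 20000L),
    D = c(-1, -3, NA)
  )
  genes <- tibble::tibble(
    gene_id = c("g0", "g1", "g2", "g3"),
    start = c(2000L, 2000L, 6000L, 50000L),
    end = c(3000L, 7000L, 12000L, 60000L)
  )
  gs <- gene_average_d(genes, w)
  expect_equal(gs$mean_D[1], -1)   # inside window 1 only
  expect_equal(gs$mean_D[2], -2)   # spans windows 1 and 2
  expect_equal(gs$mean_D[3], -2)   # overlaps 1, 2 and the NA window
  expect_true(is.na(gs$mean_D[4]))
  expect_identical(gs$n_windows, c(1L, 2L, 2L, 0L))
})

test_that("paralog stratification recovers a planted age effect and matches ranks", {
  withr::with_seed(73, {
    n_genes <- 120L
    genes <- tibble::tibble(
      gene_id = sprintf("G%03d", 1:n_genes),
      start = seq(1L, by = 600000L, length.out = n_genes),
      end = seq(1L, by = 600000L, length.out = n_genes) + 10000L,
      n_windows = 1L,
      mean_D = stats::rnorm(n_genes, 0, 0.5)
    )
    classes <- c("species_specific", "primate", "mammal", "vertebrate")
    pairs <- tibble::tibble(
      gene_id_1 = genes$gene_id[seq(1, 80, by = 2)],
      gene_id_2 = genes$gene_id[seq(2, 80, by = 2)],
      age_class = rep(classes, each = 10)
    )
    # plant: younger duplicates have lower D
    shift <- c(species_specific = -1.5, primate = -1.0, mammal = -0.5,
               vertebrate = 0)
    for (i in seq_len(nrow(pairs))) {
      ids <- c(pairs$gene_id_1[i], pairs$gene_id_2[i])
      genes$mean_D[match(ids, genes$gene_id)] <-
        genes$mean_D[match(ids, genes$gene_id)] +
        shift[[pairs$age_class[i]]]
    }
    res <- paralog_age_comparison(genes, pairs,
                                  greater_member_classes = "species_specific")
    summ <- res$class_summary
    ord <- summ$mean_D[match(classes, summ$age_class)]
    expect_true(all(diff(ord) > 0))
    expect_lt(res$kruskal$p.value, 1e-6)

    # the omnibus statistic matches a direct rank computation
    member <- res$member_d
    groups <- c(split(member$D, member$age_class),
                list(background = genes$mean_D[
                  !genes$gene_id %in% member$gene_id
                ]))
    x <- unlist(groups)
    g <- rep(seq_along(groups), lengths(groups))
    rk <- rank(x)
    n <- length(x)
    stat <- 12 / (n * (n + 1)) *
      sum(tapply(rk, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
    expect_equal(unname(res$kruskal$statistic), stat, tolerance = 1e-8)

    # greater-D members remain below background after the planted shift
    expect_lt(res$greater_member$p.value, 0.01)
  })
})

test_that("proximal paralog pairs are excluded from all summaries", {
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e", "f", "g", "h"),
    start = c(1L, 100001L, 1000001L, 2000001L, 3000001L, 4000001L,
              5000001L, 6000001L),
    end = c(10000L, 110000L, 1010000L, 2010000L, 3010000L, 4010000L,
            5010000L, 6010000L),
    mean_D = c(-3, -3, -2.5, -2.5, 0.1, -0.2, 0.3, 0)
  )
  pairs <- tibble::tibble(
    gene_id_1 = c("a", "c"),
    gene_id_2 = c("b", "d"),
    age_class = c("species_specific", "species_specific")
  )
  res <- paralog_age_comparison(genes, pairs)
  # pair (a, b) is 100 kb apart: excluded; only (c, d) used
  expect_identical(res$n_pairs_excluded, 1L)
  expect_identical(res$n_pairs_used, 1L)
  expect_false("a" %in% res$member_d$gene_id)
  summ <- res$class_summary
  expect_identical(summ$n[summ$age_class == "species_specific"], 2L)
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  withr::with_seed(74, {
    pvals <- vapply(1:200, function(r) {
      genes <- tibble::tibble(
        gene_id = sprintf("G%02d", 1:60),
        start = seq(1L, by = 600000L, length.out = 60),
        end = seq(10000L, by = 600000L, length.out = 60),
        mean_D = stats::rnorm(60)
      )
      pairs <- tibble::tibble(
        gene_id_1 = genes$gene_id[seq(1, 40, by = 2)],
        gene_id_2 = genes$gene_id[seq(2, 40, by = 2)],
        age_class = rep(c("young", "old"), each = 10)
      )
      paralog_age_comparison(genes, pairs)$kruskal$p.value
    }, numeric(1))
    expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
  })
})

test_that("neutral mosaic simulations give near-zero D and few outliers", {
  all_d <- numeric(0)
  for (s in 1:2) {
    p <- simulate_panel(21, 6000, region_length = 3e6,
                        recombination_intensity = 5, seed = 80 + s)
    w <- sliding_window_scan(panel_to_variants(p), 10000, 5000, 21)
    all_d <- c(all_d, w$D[!is.na(w$D)])
  }
  expect_gte(length(all_d), 500L)
  expect_gt(mean(all_d), -0.5)
  expect_lt(mean(all_d), 0.5)
  expect_lt(mean(abs(all_d) > 2), 0.05)
})

test_that("the frequency spectrum moves D in the expected direction", {
  withr::with_seed(75, {
    n <- 21L
    make_counts <- function(singleton_w) {
      # site frequencies drawn with adjustable weight on singletons
      probs <- c(singleton_w, rep((1 - singleton_w) / (n - 2), n - 2))
      sample(1:(n - 1), 400, replace = TRUE, prob = probs)
    }
    d_at <- vapply(c(0.1, 0.5, 0.9), function(wgt) {
      mean(vapply(1:10, function(r) {
        lowpass:::d_from_counts(make_counts(wgt), n)$D
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(d_at) < 0))
  })
})
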