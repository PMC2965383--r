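#' Simulate per-site read pileups for a diploid individual
#'
#' Per-site read depth is Poisson with mean `mean_depth`; each read
#' samples one of the two true haplotype alleles with equal probability
#' and reports it correctly with probability `1 - base_error`, otherwise
#' a uniformly chosen different base. All bases carry the same
#' Phred-scaled quality `base_quality`.
#'
#' @param truth A `diploid_truth` from [sample_diploid()].
#' @param mean_depth Mean reads per site (>= 0).
#' @param base_error Per-base sequencing error probability in [0, 0.75].
#' @param base_quality Phred score attached to every simulated base.
#' @param seed Integer seed.
#'
#' @return A pileup tibble: `position`, `ref`, `depth`, and list-columns
#'   `bases` (character vectors) and `quals` (integer vectors).
#' @export
simulate_pileups <- function(truth, mean_depth, base_error = 0.01,
                             base_quality = 20L, seed = NULL) {
  if (!inherits(truth, "diploid_truth")) {
    abort("`truth` must be a diploid_truth.")
  }
  if (!is.numeric(mean_depth) || length(mean_depth) != 1L || mean_depth < 0) {
    abort("`mean_depth` must be a single non-negative number.")
  }
  check_prob(base_error, "base_error", max = 0.75)
  panel <- truth$panel
  n <- length(panel$positions)
  with_seed(seed, {
    depth <- rpois(n, mean_depth)
    total <- sum(depth)
    site_of_read <- rep.int(seq_len(n), depth)
    from_b <- runif(total) < 0.5
    hap_allele <- ifelse(from_b, truth$hap_b[site_of_read],
                         truth$hap_a[site_of_read])
    true_base <- ifelse(hap_allele == 1L, panel$alt[site_of_read],
                        panel$ref[site_of_read])
    err <- runif(total) < base_error
    obs <- true_base
    if (any(err)) {
      # uniformly one of the three other bases
      shift <- sample.int(3L, sum(err), replace = TRUE)
      idx <- match(true_base[err], BASES)
      obs[err] <- BASES[1L + (idx - 1L + shift) %% 4L]
    }
    bases <- split(obs, factor(site_of_read, levels = seq_len(n)))
    tibble(
      position = panel$positions,
      ref = panel$ref,
      depth = as.integer(depth),
      bases = unname(lapply(bases, as.character)),
      quals = lapply(depth, function(d) rep(as.integer(base_quality), d))
    )
  })
}

#' Simulate an array-like genotype truth subset
#'
#' Emulates a genotyping bead array: a random subset of panel sites is
#' "typed", and each typed genotype equals the true genotype except with
#' probability `array_error`, in which case one of the other two
#' genotypes over the site's panel alleles is reported.
#'
#' @param truth A `diploid_truth` from [sample_diploid()].
#' @param site_fraction Expected fraction of sites on the array, in [0, 1].
#' @param array_error Per-genotype array error probability in [0, 0.5).
#' @param seed Integer seed.
#'
#' @return Tibble with `position` and `gt` (canonical genotype string)
#'   for the typed subset.
#' @export
simulate_array_truth <- function(truth, site_fraction = 0.25,
                                 array_error = 0.002, seed = NULL) {
  if (!inherits(truth, "diploid_truth")) {
    abort("`truth` must be a diploid_truth.")
  }
  check_prob(site_fraction, "site_fraction")
  check_prob(array_error, "array_error", max = 0.5 - 1e-12)
  panel <- truth$panel
  with_seed(seed, {
    typed <- runif(length(panel$positions)) < site_fraction
    gt <- truth$genotypes$gt[typed]
    ref <- panel$ref[typed]
    alt <- panel$alt[typed]
    flip <- runif(length(gt)) < array_error
    if (any(flip)) {
      space <- cbind(gt_string(ref, ref), gt_string(ref, alt),
                     gt_string(alt, alt))
      cur <- (gt == space[, 2L]) + 2L * (gt == space[, 3L]) # 0,1,2 index
      step <- sample.int(2L, length(gt), replace = TRUE)
      new_idx <- (cur + step) %% 3L + 1L
      gt[flip] <- space[cbind(which(flip), new_idx[flip])]
    }
    tibble(position = panel$positions[typed], gt = gt)
  })
}
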