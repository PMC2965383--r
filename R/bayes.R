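#' Combine a genotype prior with read-evidence conditionals
#'
#' The Bayes step: element-wise product of prior and conditional over a
#' shared genotype space, renormalized to sum to 1.
#'
#' @param prior,conditional Probability-kind [genotype_dist()] objects
#'   over the same genotype space (same site).
#'
#' @return A probability-kind [genotype_dist()].
#' @export
combine_posterior <- function(prior, conditional) {
  if (!inherits(prior, "genotype_dist") ||
      !inherits(conditional, "genotype_dist")) {
    abort("`prior` and `conditional` must be genotype_dist objects.")
  }
  if (dist_kind(prior) != "probability" ||
      dist_kind(conditional) != "probability") {
    abort("Both distributions must be probability kind.")
  }
  if (!setequal(prior$genotype, conditional$genotype)) {
    abort("Prior and conditional must share one genotype space.")
  }
  cond <- conditional$value[match(prior$genotype, conditional$genotype)]
  prod <- prior$value * cond
  if (sum(prod) <= 0) {
    abort("Degenerate site: prior and conditional have disjoint support.")
  }
  genotype_dist(setNames(prod, prior$genotype), "probability",
                attr(prior, "position"))
}

#' Bayesian genotype calling with panel-derived priors
#'
#' Calls genotypes at panel sites under one of three modes:
#' `sequence_only` (reads alone, identical to [call_sequence_only()]),
#' `freq_prior` (Hardy-Weinberg prior from panel allele frequencies),
#' or `haplotype_prior` (haplotype-copying prior fed with the
#' read-evidence conditionals of surrounding sites). In the prior modes
#' the read conditional at each site is computed over the site's two
#' panel alleles, multiplied by the prior and renormalized; depth
#' filters from `config` apply in every mode and exact posterior ties
#' are broken at random under `config$tie_break_seed`.
#'
#' @param pileups Pileup tibble over panel sites (one row per panel
#'   site, matching positions).
#' @param panel A [haplotype_panel()].
#' @param mode `"sequence_only"`, `"freq_prior"` or `"haplotype_prior"`.
#' @param config A [caller_config()].
#' @param params An [imputation_params()] (used by `haplotype_prior`).
#'
#' @return A call tibble as in [call_sequence_only()], with `mode` set
#'   accordingly.
#' @export
call_with_prior <- function(pileups, panel,
                            mode = c("haplotype_prior", "freq_prior",
                                     "sequence_only"),
                            config = caller_config(),
                            params = imputation_params()) {
  mode <- match.arg(mode)
  if (mode == "sequence_only") {
    return(call_sequence_only(pileups, config, "diploid"))
  }
  if (!inherits(panel, "haplotype_panel")) {
    abort("`panel` must be a haplotype_panel.")
  }
  site_idx <- match(pileups$position, panel$positions)
  if (anyNA(site_idx)) {
    abort("All pileup positions must be panel sites in prior modes.")
  }
  n <- nrow(pileups)
  depth <- vapply(pileups$bases, length, integer(1L))
  filter <- rep("PASS", n)
  filter[depth < config$min_depth] <- "LOW_DEPTH"
  filter[depth > config$max_depth] <- "HIGH_DEPTH"

  ref <- panel$ref[site_idx]
  alt <- panel$alt[site_idx]
  # read-evidence conditionals over (ref/ref, ref/alt, alt/alt)
  cond <- matrix(1 / 3, n, 3L)
  for (i in seq_len(n)) {
    if (depth[i] == 0L) next
    ll <- site_loglik3(pileups$bases[[i]], pileups$quals[[i]],
                       ref[i], alt[i])
    v <- exp(ll - max(ll))
    cond[i, ] <- v / sum(v)
  }

  if (mode == "freq_prior") {
    p <- panel_allele_freq(panel)[site_idx]
    prior <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  } else {
    evidence <- matrix(NA_real_, n_sites(panel), 3L)
    has_reads <- depth > 0L
    evidence[site_idx[has_reads], ] <- cond[has_reads, , drop = FALSE]
    prior <- t(vapply(site_idx, function(t) {
      pair_genotype_posterior(panel, evidence, t, params)
    }, numeric(3L)))
  }

  post <- prior * cond
  post <- post / rowSums(post)
  rng <- make_tie_rng(config$tie_break_seed)
  genotype <- rep(NA_character_, n)
  posterior <- rep(NA_real_, n)
  gt_space <- cbind(gt_string(ref, ref), gt_string(ref, alt),
                    gt_string(alt, alt))
  for (i in which(filter == "PASS")) {
    k <- pick_map(post[i, ], rng)
    genotype[i] <- gt_space[i, k]
    posterior[i] <- post[i, k]
  }
  finalize_calls(pileups, depth, genotype, posterior, filter, mode, config)
}

#' Filter short-indel candidates
#'
#' Applies spacing and quality filters to candidate indels: within any
#' run of candidates spaced less than 20 bp apart only the
#' highest-quality candidate is kept (resolved left to right after
#' sorting by position); survivors must then have mapping quality
#' strictly greater than 20 and read depth strictly between the lower
#' bound (4 for diploid autosomes, 2 for haploid sex chromosomes)
#' and 100.
#'
#' @param candidates Tibble with `position`, `length` (signed bases;
#'   negative deletions), `quality`, `mapping_quality`, `depth`.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param min_spacing Minimum separation in bp (default 20).
#'
#' @return The accepted subset of `candidates`, sorted by position.
#' @export
filter_indel_candidates <- function(candidates,
                                    ploidy = c("diploid", "haploid"),
                                    min_spacing = 20L) {
  ploidy <- match.arg(ploidy)
  if (nrow(candidates) == 0L) return(candidates)
  candidates <- arrange(candidates, .data$position)
  gap <- c(Inf, diff(candidates$position))
  cluster <- cumsum(gap >= min_spacing)
  kept <- candidates %>%
    mutate(.cluster = cluster) %>%
    group_by(.data$.cluster) %>%
    filter(.data$quality == max(.data$quality)) %>%
    filter(row_number() == 1L) %>%
    ungroup() %>%
    select(-".cluster")
  lower <- if (ploidy == "diploid") 4L else 2L
  kept %>%
    filter(.data$mapping_quality > 20,
           .data$depth > lower,
           .data$depth < 100)
}
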