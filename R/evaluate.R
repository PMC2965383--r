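#' Randomly thin pileups to a target mean depth
#'
#' Emulates depth titration by random read removal: each read is kept
#' independently with probability `target_mean_depth / current mean
#' depth`; qualities follow their reads.
#'
#' @param pileups Pileup tibble (see [simulate_pileups()]).
#' @param target_mean_depth Desired mean reads per site; must not exceed
#'   the current mean depth.
#' @param seed Integer seed.
#'
#' @return A pileup tibble of the same shape with thinned reads.
#' @export
downsample_pileups <- function(pileups, target_mean_depth, seed = NULL) {
  depth <- vapply(pileups$bases, length, integer(1L))
  cur <- mean(depth)
  if (target_mean_depth < 0) abort("`target_mean_depth` must be >= 0.")
  if (target_mean_depth > cur + 1e-9) {
    abort("`target_mean_depth` exceeds the current mean depth.")
  }
  p <- if (cur > 0) min(1, target_mean_depth / cur) else 0
  with_seed(seed, {
    keep <- lapply(depth, function(d) runif(d) < p)
    out <- pileups
    out$bases <- purrr::map2(pileups$bases, keep, function(b, k) b[k])
    out$quals <- purrr::map2(pileups$quals, keep, function(q, k) q[k])
    out$depth <- vapply(out$bases, length, integer(1L))
    out
  })
}

#' Genotype concordance against a reference genotype set
#'
#' Compares unfiltered calls to reference genotypes (truth or array) at
#' shared sites. Reports overall concordance, positive predictive value
#' (fraction of called variant sites that are true variant sites) and
#' the heterozygote undercall rate (fraction of true heterozygotes
#' called homozygous). Filtered and no-call sites are excluded from the
#' denominator; the no-call fraction is reported separately.
#'
#' @param calls Call tibble (from [call_sequence_only()] or
#'   [call_with_prior()]); must carry `position`, `ref`, `genotype`,
#'   `filter`.
#' @param reference_genotypes Tibble with `position` and `gt`.
#' @param depth_bins Optional numeric breaks; when given, a per-bin
#'   concordance table is attached as attribute `"stratified"`.
#'
#' @return A one-row tibble of class `concordance_report`: `n_compared`,
#'   `n_match`, `concordance`, `ppv`, `het_undercall_rate`,
#'   `no_call_rate`.
#' @export
genotype_concordance <- function(calls, reference_genotypes,
                                 depth_bins = NULL) {
  shared <- dplyr::inner_join(calls, reference_genotypes, by = "position")
  if (nrow(shared) == 0L) {
    abort("Calls and reference genotypes share no sites.")
  }
  usable <- shared$filter == "PASS" & !is.na(shared$genotype)
  cmp <- shared[usable, , drop = FALSE]
  if (nrow(cmp) == 0L) {
    abort("No unfiltered calls overlap the reference genotypes.")
  }
  match_vec <- cmp$genotype == cmp$gt
  hom_ref <- gt_string(cmp$ref, cmp$ref)
  called_var <- cmp$genotype != hom_ref
  true_var <- cmp$gt != hom_ref
  true_het <- gt_is_het(cmp$gt)
  report <- tibble(
    n_compared = nrow(cmp),
    n_match = sum(match_vec),
    concordance = mean(match_vec),
    ppv = if (any(called_var)) mean(true_var[called_var]) else NA_real_,
    het_undercall_rate = if (any(true_het)) {
      mean(!gt_is_het(cmp$genotype[true_het]))
    } else NA_real_,
    no_call_rate = 1 - nrow(cmp) / nrow(shared)
  )
  class(report) <- c("concordance_report", class(report))
  if (!is.null(depth_bins) && "depth" %in% names(cmp)) {
    strat <- cmp %>%
      mutate(depth_bin = cut(.data$depth, breaks = depth_bins,
                             include.lowest = TRUE)) %>%
      group_by(.data$depth_bin) %>%
      summarise(n_compared = n(),
                concordance = mean(.data$genotype == .data$gt),
                .groups = "drop")
    attr(report, "stratified") <- strat
  }
  report
}

#' Accuracy-versus-depth comparison across calling modes
#'
#' Downsamples a source pileup set to each target mean depth, calls
#' genotypes under each requested mode, and measures concordance with
#' the supplied truth — the synthetic analogue of comparing
#' sequence-only, frequency-prior and haplotype-prior calling across
#' read depths.
#'
#' @param pileups Source pileup tibble (full depth).
#' @param panel A [haplotype_panel()].
#' @param truth Reference genotypes: tibble with `position`, `gt` (e.g.
#'   `diploid_truth$genotypes` or an array subset).
#' @param modes Character vector of calling modes.
#' @param depths Numeric target mean depths (each at most the source
#'   mean depth).
#' @param replicates Downsampling replicates per depth.
#' @param seed Integer seed driving all replicate thinning.
#' @param config A [caller_config()].
#' @param params An [imputation_params()].
#'
#' @return A tibble of class `depth_curve`: one row per mode x depth x
#'   replicate with `concordance`, `het_undercall_rate`, `n_compared`
#'   and `realized_depth`.
#' @export
accuracy_vs_depth_curve <- function(pileups, panel, truth,
                                    modes = c("sequence_only", "freq_prior",
                                              "haplotype_prior"),
                                    depths = c(2, 4, 6, 8),
                                    replicates = 3L,
                                    seed = 1L,
                                    config = caller_config(),
                                    params = imputation_params()) {
  if (length(modes) == 0L || length(depths) == 0L) {
    abort("`modes` and `depths` must be non-empty.")
  }
  replicates <- check_count(replicates, "replicates")
  grid <- tidyr::expand_grid(depth = depths, replicate = seq_len(replicates))
  rows <- purrr::pmap(grid, function(depth, replicate) {
    thin_seed <- derive_seed(seed, replicate * 1000L + round(depth * 10))
    thinned <- downsample_pileups(pileups, depth, seed = thin_seed)
    purrr::map(modes, function(m) {
      calls <- call_with_prior(thinned, panel, mode = m, config = config,
                               params = params)
      rep <- genotype_concordance(calls, truth)
      tibble(
        mode = m, depth = depth, replicate = replicate,
        concordance = rep$concordance,
        het_undercall_rate = rep$het_undercall_rate,
        n_compared = rep$n_compared,
        realized_depth = mean(thinned$depth)
      )
    }) %>% bind_rows()
  })
  out <- bind_rows(rows)
  class(out) <- c("depth_curve", class(out))
  out
}

#' @describeIn accuracy_vs_depth_curve Mean and standard deviation of
#'   concordance per mode and depth.
#' @param x A `depth_curve`.
#' @param ... Unused.
#' @export
glance.depth_curve <- function(x, ...) {
  x %>%
    group_by(.data$mode, .data$depth) %>%
    summarise(
      mean_concordance = mean(.data$concordance),
      sd_concordance = stats::sd(.data$concordance),
      n = n(),
      .groups = "drop"
    )
}
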