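#' Linkage disequilibrium r-squared between two panel sites
#'
#' Computes the squared correlation of allele indicators across phased
#' panel haplotypes: `r2 = (p_ab - p_a p_b)^2 / (p_a(1-p_a) p_b(1-p_b))`
#' where `p_ab` is the frequency of haplotypes carrying the alternate
#' allele at both sites.
#'
#' @param panel A [haplotype_panel()].
#' @param site_a,site_b Site indices (columns) or, when
#'   `by = "position"`, base-pair positions.
#' @param by Interpret `site_a`/`site_b` as `"index"` (default) or
#'   `"position"`.
#'
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(panel, site_a, site_b, by = c("index", "position")) {
  by <- match.arg(by)
  if (by == "position") {
    site_a <- match(site_a, panel$positions)
    site_b <- match(site_b, panel$positions)
    if (anyNA(c(site_a, site_b))) abort("Positions not found in panel.")
  }
  x <- panel$haplotypes[, site_a]
  y <- panel$haplotypes[, site_b]
  pa <- mean(x)
  pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    abort("LD is undefined at a monomorphic site.")
  }
  pab <- mean(x == 1L & y == 1L)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Flanking high-LD marker-pair evidence
#'
#' Tests whether two positions (a novel variant and a disease marker)
#' are jointly flanked by at least one pair of panel markers in high
#' LD: a pair `(m1, m2)` with `m1 <=` the left position, `m2 >=` the
#' right position and `r2(m1, m2) >= r2_threshold`. The search
#' considers the `max_flank_markers` polymorphic panel sites nearest
#' each side.
#'
#' @param panel A [haplotype_panel()].
#' @param novel_pos,marker_pos Base-pair positions to be flanked.
#' @param r2_threshold Minimum r-squared (default 0.8).
#' @param max_flank_markers Number of candidate markers searched on each
#'   side (default 25).
#'
#' @return A list: `found` (logical) and `evidence` (tibble `m1`, `m2`,
#'   `r2` of all qualifying pairs found).
#' @export
has_flanking_high_ld_pair <- function(panel, novel_pos, marker_pos,
                                      r2_threshold = 0.8,
                                      max_flank_markers = 25L) {
  lo <- min(novel_pos, marker_pos)
  hi <- max(novel_pos, marker_pos)
  freq <- panel_allele_freq(panel)
  poly <- freq > 0 & freq < 1
  pos <- panel$positions
  left <- which(pos <= lo & poly)
  right <- which(pos >= hi & poly)
  left <- tail(left, max_flank_markers)
  right <- head(right, max_flank_markers)
  if (length(left) == 0L || length(right) == 0L) {
    return(list(found = FALSE,
                evidence = tibble(m1 = integer(), m2 = integer(),
                                  r2 = numeric())))
  }
  grid <- tidyr::expand_grid(i = left, j = right)
  r2 <- purrr::map2_dbl(grid$i, grid$j, function(i, j) ld_r2(panel, i, j))
  hit <- r2 >= r2_threshold
  list(
    found = any(hit),
    evidence = tibble(m1 = pos[grid$i[hit]], m2 = pos[grid$j[hit]],
                      r2 = r2[hit])
  )
}

#' Prioritize novel variants near heterozygous disease markers
#'
#' Retains called variants that are (i) novel (absent from the
#' known-variant catalog), (ii) strictly within `max_distance` bp of a
#' disease marker, (iii) whose nearest qualifying disease marker is
#' heterozygous in the individual, and (iv) jointly flanked with that
#' marker by at least one high-LD panel marker pair. Output is sorted
#' by consequence severity (stop_gained > essential_splice > splice >
#' non_synonymous > other).
#'
#' @param calls Call tibble with `position`, `ref`, `genotype`,
#'   `filter`, plus a `consequence` column (labels from the severity
#'   order above); an optional `deleterious` column is carried through.
#' @param annotations An `annotation_set` (disease markers and
#'   known-variant catalog).
#' @param panel A [haplotype_panel()] supplying marker haplotypes.
#' @param max_distance Proximity limit in bp (default 250000, strict).
#' @param r2_threshold Minimum flanking-pair r-squared (default 0.8).
#'
#' @return Tibble of candidate variants: `position`, `genotype`,
#'   `consequence`, `marker_position`, `marker_distance`, `n_ld_pairs`,
#'   `best_r2` (plus `deleterious` when supplied), severity-sorted.
#' @export
prioritize_novel_variants <- function(calls, annotations, panel,
                                      max_distance = 250000L,
                                      r2_threshold = 0.8) {
  severity <- c("stop_gained", "essential_splice", "splice",
                "non_synonymous", "other")
  if (!"consequence" %in% names(calls)) {
    abort("`calls` must carry a `consequence` column.")
  }
  markers <- annotations$disease_markers
  # marker genotypes in the individual, read off the call set
  mk <- left_join(markers, calls[, c("position", "genotype", "filter")],
                  by = "position")
  mk <- mk[!is.na(mk$genotype) & mk$filter == "PASS" &
             gt_is_het(mk$genotype), , drop = FALSE]
  hom_ref <- gt_string(calls$ref, calls$ref)
  variant <- !is.na(calls$genotype) & calls$filter == "PASS" &
    calls$genotype != hom_ref
  novel <- !(calls$position %in% annotations$known_variants)
  cand <- calls[variant & novel, , drop = FALSE]
  if (nrow(cand) == 0L || nrow(mk) == 0L) {
    return(tibble(position = integer(), genotype = character(),
                  consequence = character(), marker_position = integer(),
                  marker_distance = integer(), n_ld_pairs = integer(),
                  best_r2 = numeric()))
  }
  rows <- purrr::map(seq_len(nrow(cand)), function(i) {
    p <- cand$position[i]
    dist <- abs(mk$position - p)
    near <- which(dist < max_distance)
    if (length(near) == 0L) return(NULL)
    # try het markers in order of proximity until LD evidence holds
    for (j in near[order(dist[near])]) {
      ev <- has_flanking_high_ld_pair(panel, p, mk$position[j],
                                      r2_threshold)
      if (ev$found) {
        out <- tibble(
          position = p,
          genotype = cand$genotype[i],
          consequence = cand$consequence[i],
          marker_position = mk$position[j],
          marker_distance = as.integer(dist[j]),
          n_ld_pairs = nrow(ev$evidence),
          best_r2 = max(ev$evidence$r2)
        )
        if ("deleterious" %in% names(cand)) {
          out$deleterious <- cand$deleterious[i]
        }
        return(out)
      }
    }
    NULL
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out$consequence <- factor(out$consequence, levels = severity)
  arrange(out, .data$consequence, .data$position) %>%
    mutate(consequence = as.character(.data$consequence))
}

#' Contingency-table enrichment test
#'
#' Runs a 2x2 enrichment test: Fisher's exact test (one-sided upper
#' tail or two-sided) via the hypergeometric distribution, or the
#' Pearson chi-square statistic without continuity correction (df = 1).
#' The odds ratio is the sample cross-product ratio; 0.5 is added to
#' every cell when any cell is zero (flagged in `haldane`).
#'
#' @param table 2x2 matrix of non-negative integer counts; rows are the
#'   outcome split (e.g. deleterious / not), columns the groups.
#' @param method `"fisher_one_sided"`, `"fisher_two_sided"` or
#'   `"chi_square"`.
#'
#' @return One-row tibble: `method`, `statistic` (chi-square statistic,
#'   `NA` for Fisher), `p_value`, `odds_ratio`, `haldane`.
#' @export
enrichment_test <- function(table,
                            method = c("fisher_one_sided",
                                       "fisher_two_sided", "chi_square")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0)) {
    abort("`table` must be a 2x2 matrix of non-negative counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("All row and column margins must be positive.")
  }
  haldane <- any(table == 0)
  ot <- if (haldane) table + 0.5 else table
  odds_ratio <- (ot[1, 1] * ot[2, 2]) / (ot[1, 2] * ot[2, 1])
  if (method == "chi_square") {
    ht <- suppressWarnings(chisq.test(table, correct = FALSE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    alt <- if (method == "fisher_one_sided") "greater" else "two.sided"
    ht <- fisher.test(table, alternative = alt)
    stat <- NA_real_
    p <- ht$p.value
  }
  tibble(method = method, statistic = stat, p_value = p,
         odds_ratio = odds_ratio, haldane = haldane)
}
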