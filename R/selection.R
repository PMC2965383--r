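# Tajima (1989) normalization constants for sample size n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for a window of haplotypes
#'
#' Compares the two classical estimators of the population mutation
#' rate: mean pairwise diversity (pi) and the normalized count of
#' segregating sites (S / a1). Under neutrality the two agree; an
#' excess of rare variants (e.g. after a selective sweep) makes D
#' negative, an excess of intermediate-frequency variants (balancing
#' selection) makes it positive. Both summaries depend only on per-site
#' allele counts, so the matrix may hold any binary encoding of the
#' sampled chromosomes.
#'
#' @param haplotypes Binary matrix, `n_chromosomes` rows x sites
#'   columns.
#' @param n_chromosomes Sample size (>= 2); defaults to `nrow()`.
#'
#' @return A one-row tibble: `S`, `pi`, `D` (`NA` when `S` is 0).
#' @export
tajimas_d <- function(haplotypes, n_chromosomes = nrow(haplotypes)) {
  if (is.null(n_chromosomes) || n_chromosomes < 2L) {
    abort("`n_chromosomes` must be >= 2.")
  }
  haplotypes <- as.matrix(haplotypes)
  counts <- colSums(haplotypes)
  d_from_counts(counts, n_chromosomes)
}

# S, pi and D from per-site derived-allele counts.
d_from_counts <- function(counts, n) {
  seg <- counts > 0L & counts < n
  S <- sum(seg)
  pi <- sum(counts[seg] * (n - counts[seg])) / choose(n, 2)
  if (S == 0L) {
    return(tibble(S = 0L, pi = 0, D = NA_real_))
  }
  k <- tajima_constants(n)
  D <- (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  tibble(S = as.integer(S), pi = pi, D = D)
}

#' Sliding-window Tajima's D scan
#'
#' Tiles each chromosome with windows of `window_length` bp advancing by
#' `step` bp, starting at coordinate 1 (1-based inclusive bounds:
#' `[start, start + window_length - 1]`), and computes S, pi and
#' Tajima's D per window from the per-site alternate-allele counts
#' falling inside the bounds. Only full windows within the region are
#' emitted. Windows with no segregating site have undefined D.
#'
#' @param variants Tibble with `chromosome`, `position` (1-based) and
#'   `alt_count` (number of the `n_chromosomes` sampled chromosomes
#'   carrying the alternate allele); positions sorted per chromosome.
#' @param window_length Window size in bp (default 10000).
#' @param step Window step in bp (default 5000).
#' @param n_chromosomes Sample size (default 21).
#' @param region_length Optional named vector (or single value) of
#'   per-chromosome region lengths; defaults to the maximum observed
#'   position per chromosome.
#'
#' @return A tibble of class `window_scan`: `chromosome`, `start`,
#'   `end`, `n_sites`, `S`, `pi`, `D`.
#' @export
sliding_window_scan <- function(variants, window_length = 10000L,
                                step = 5000L, n_chromosomes = 21L,
                                region_length = NULL) {
  if (window_length <= 0 || step <= 0) {
    abort("`window_length` and `step` must be positive.")
  }
  if (n_chromosomes < 2L) abort("`n_chromosomes` must be >= 2.")
  chroms <- unique(variants$chromosome)
  out <- purrr::map(chroms, function(ch) {
    v <- variants[variants$chromosome == ch, , drop = FALSE]
    v <- arrange(v, .data$position)
    len <- if (is.null(region_length)) {
      max(v$position)
    } else if (!is.null(names(region_length))) {
      region_length[[ch]]
    } else {
      region_length[[1L]]
    }
    if (len < window_length) return(NULL)
    starts <- seq.int(1L, len - window_length + 1L, by = step)
    ends <- starts + window_length - 1L
    # inclusive bounds: sites with start <= position <= end
    lo <- findInterval(starts - 1L, v$position) + 1L
    hi <- findInterval(ends, v$position)
    stats <- purrr::map2(lo, hi, function(l, h) {
      if (h < l) return(tibble(S = 0L, pi = 0, D = NA_real_))
      d_from_counts(v$alt_count[l:h], n_chromosomes)
    }) %>% bind_rows()
    tibble(
      chromosome = ch,
      start = as.integer(starts),
      end = as.integer(ends),
      n_sites = as.integer(hi - lo + 1L)
    ) %>% dplyr::bind_cols(stats)
  })
  res <- bind_rows(out)
  class(res) <- c("window_scan", class(res))
  res
}

#' Merge outlier windows into maximal regions
#'
#' Selects windows whose D lies strictly beyond the cutoff (below a
#' negative cutoff, e.g. -2 for putative positive selection; above a
#' positive cutoff, e.g. +2 for balancing selection) and concatenates
#' overlapping or abutting qualifying windows into maximal regions.
#' Windows with undefined D never qualify.
#'
#' @param windows A window tibble from [sliding_window_scan()].
#' @param cutoff Signed threshold; negative selects `D < cutoff`,
#'   positive selects `D > cutoff`.
#'
#' @return Tibble `chromosome`, `start`, `end`, `n_windows`,
#'   `extreme_D` (the most extreme D among merged windows).
#' @export
merge_outlier_regions <- function(windows, cutoff = -2) {
  if (cutoff == 0) abort("`cutoff` must be nonzero (signed threshold).")
  qualifying <- if (cutoff < 0) {
    windows[!is.na(windows$D) & windows$D < cutoff, , drop = FALSE]
  } else {
    windows[!is.na(windows$D) & windows$D > cutoff, , drop = FALSE]
  }
  if (nrow(qualifying) == 0L) {
    return(tibble(chromosome = character(), start = integer(),
                  end = integer(), n_windows = integer(),
                  extreme_D = numeric()))
  }
  qualifying %>%
    group_by(.data$chromosome) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(region = cumsum(.data$start > dplyr::lag(
      cummax(.data$end), default = -1L
    ) + 1L)) %>%
    group_by(.data$chromosome, .data$region) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_windows = n(),
      extreme_D = if (cutoff < 0) min(.data$D) else max(.data$D),
      .groups = "drop"
    ) %>%
    select(-"region")
}

#' Average Tajima's D per gene
#'
#' Each gene receives the unweighted mean of D over all windows it
#' overlaps (1-based inclusive interval overlap) that have defined D;
#' genes overlapping no such window are flagged missing.
#'
#' @param genes Tibble with `gene_id`, `start`, `end` (and optionally
#'   `chromosome`; single-chromosome input may omit it).
#' @param windows Window tibble from [sliding_window_scan()].
#'
#' @return Tibble `gene_id`, `start`, `end`, `n_windows`, `mean_D`
#'   (`NA` when no overlapping window has defined D).
#' @export
gene_average_d <- function(genes, windows) {
  use_chrom <- "chromosome" %in% names(genes) &&
    "chromosome" %in% names(windows)
  rows <- purrr::pmap(genes, function(...) {
    g <- list(...)
    w <- windows
    if (use_chrom) w <- w[w$chromosome == g$chromosome, , drop = FALSE]
    ov <- w$start <= g$end & w$end >= g$start & !is.na(w$D)
    tibble(
      gene_id = g$gene_id,
      start = g$start,
      end = g$end,
      n_windows = sum(ov),
      mean_D = if (any(ov)) mean(w$D[ov]) else NA_real_
    )
  })
  bind_rows(rows)
}

#' Stratify gene-level D by paralog duplication age
#'
#' Joins per-gene mean Tajima's D with paralog-pair annotations,
#' excludes pairs whose gene starts lie closer than
#' `proximity_exclusion` bp (shared selective sweeps, not duplication
#' effects), and summarises D by duplication-age class. An omnibus
#' Kruskal-Wallis test compares the age classes together with the
#' background (genes outside retained pairs); a secondary test compares
#' each retained pair's greater-D member against the background
#' (Welch t-test).
#'
#' @param gene_stats Tibble from [gene_average_d()].
#' @param annotations An `annotation_set` (or a paralog-pair tibble with
#'   `gene_id_1`, `gene_id_2`, `age_class`).
#' @param proximity_exclusion Minimum start-to-start distance in bp for
#'   a pair to be retained (default 250000).
#' @param min_class_size Classes with fewer genes are dropped from the
#'   omnibus test with a warning (default 2).
#' @param greater_member_classes Age classes whose pairs enter the
#'   greater-D-member comparison; `NULL` (default) uses every retained
#'   pair. The youngest class is the scientifically interesting choice:
#'   it asks whether even the less-selected copy of a recent duplicate
#'   sits below the genome background.
#'
#' @return A list of class `paralog_comparison`: `class_summary`
#'   (tibble), `kruskal` (htest), `greater_member` (htest or NULL),
#'   `n_pairs_used`, `n_pairs_excluded`.
#' @export
paralog_age_comparison <- function(gene_stats, annotations,
                                   proximity_exclusion = 250000L,
                                   min_class_size = 2L,
                                   greater_member_classes = NULL) {
  pairs <- if (inherits(annotations, "annotation_set")) {
    annotations$paralog_pairs
  } else {
    annotations
  }
  s1 <- gene_stats$start[match(pairs$gene_id_1, gene_stats$gene_id)]
  s2 <- gene_stats$start[match(pairs$gene_id_2, gene_stats$gene_id)]
  keep <- !is.na(s1) & !is.na(s2) & abs(s1 - s2) >= proximity_exclusion
  used <- pairs[keep, , drop = FALSE]

  d_of <- function(ids) gene_stats$mean_D[match(ids, gene_stats$gene_id)]
  member <- tibble(
    gene_id = c(used$gene_id_1, used$gene_id_2),
    age_class = as.character(c(used$age_class, used$age_class))
  ) %>%
    mutate(D = d_of(.data$gene_id)) %>%
    filter(!is.na(.data$D))
  background_ids <- setdiff(gene_stats$gene_id, member$gene_id)
  background <- gene_stats$mean_D[match(background_ids,
                                        gene_stats$gene_id)]
  background <- background[!is.na(background)]

  class_summary <- member %>%
    group_by(.data$age_class) %>%
    summarise(n = n(), mean_D = mean(.data$D),
              median_D = stats::median(.data$D), .groups = "drop") %>%
    bind_rows(tibble(age_class = "background",
                     n = length(background),
                     mean_D = mean(background),
                     median_D = stats::median(background)))

  small <- class_summary$age_class[class_summary$n < min_class_size]
  if (length(small) > 0L) {
    warn(sprintf("Excluding classes with < %d genes from the omnibus test: %s",
                 min_class_size, paste(small, collapse = ", ")))
  }
  groups <- c(
    split(member$D, member$age_class),
    list(background = background)
  )
  groups <- groups[vapply(groups, length, integer(1L)) >= min_class_size]
  if (length(groups) < 2L) {
    abort("Need at least two groups for the Kruskal-Wallis test.")
  }
  kw <- kruskal.test(groups)

  greater <- NULL
  gm_pairs <- if (is.null(greater_member_classes)) used else
    used[as.character(used$age_class) %in% greater_member_classes, ,
         drop = FALSE]
  if (nrow(gm_pairs) > 0L) {
    d1 <- d_of(gm_pairs$gene_id_1)
    d2 <- d_of(gm_pairs$gene_id_2)
    gd <- pmax(d1, d2, na.rm = TRUE)
    gd <- gd[is.finite(gd)]
    if (length(gd) >= 2L && length(background) >= 2L) {
      greater <- t.test(gd, background)
    }
  }
  structure(
    list(
      class_summary = class_summary,
      kruskal = kw,
      greater_member = greater,
      member_d = member,
      n_pairs_used = nrow(used),
      n_pairs_excluded = sum(!keep)
    ),
    class = "paralog_comparison"
  )
}

#' @export
print.paralog_comparison <- function(x, ...) {
  cat(sprintf(
    "<paralog_comparison> %d pairs used (%d excluded by proximity)\n",
    x$n_pairs_used, x$n_pairs_excluded
  ))
  print(x$class_summary)
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, p = %.3g\n",
              unname(x$kruskal$statistic), x$kruskal$p.value))
  if (!is.null(x$greater_member)) {
    cat(sprintf("Greater-D members vs background: t = %.3f, p = %.3g\n",
                unname(x$greater_member$statistic),
                x$greater_member$p.value))
  }
  invisible(x)
}

#' @describeIn paralog_age_comparison Per-class summary as a tibble.
#' @param x A `paralog_comparison`.
#' @param ... Unused.
#' @export
tidy.paralog_comparison <- function(x, ...) x$class_summary

#' @describeIn paralog_age_comparison One-row test summary.
#' @export
glance.paralog_comparison <- function(x, ...) {
  tibble(
    kruskal_statistic = unname(x$kruskal$statistic),
    kruskal_p = x$kruskal$p.value,
    greater_member_t = if (is.null(x$greater_member)) NA_real_ else
      unname(x$greater_member$statistic),
    greater_member_p = if (is.null(x$greater_member)) NA_real_ else
      x$greater_member$p.value,
    n_pairs_used = x$n_pairs_used,
    n_pairs_excluded = x$n_pairs_excluded
  )
}

#' Per-site alternate-allele counts of a panel
#'
#' Convenience conversion from a [haplotype_panel()] to the variant
#' table consumed by [sliding_window_scan()].
#'
#' @param panel A [haplotype_panel()].
#' @return Tibble `chromosome`, `position`, `alt_count`.
#' @export
panel_to_variants <- function(panel) {
  tibble(
    chromosome = panel$chromosome,
    position = panel$positions,
    alt_count = as.integer(colSums(panel$haplotypes))
  )
}
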