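#' Parameters of the haplotype-copying prior engine
#'
#' The imputation engine models the two haplotypes of a diploid target
#' as hidden mosaics of reference-panel haplotypes (a two-chain
#' haplotype-copying HMM). Each chain's copied panel haplotype switches
#' between adjacent sites with probability
#' `1 - exp(-switch_rate * distance_bp)` (switching lands uniformly on
#' any panel haplotype), and the copied allele is mis-read with
#' probability `mutation_rate`. The chains are independent a priori and
#' coupled only through per-site genotype evidence.
#'
#' @param switch_rate Per-base-pair copy-switch intensity, in (0, 1).
#' @param mutation_rate Per-site copy-error probability, in (0, 1).
#' @param neighborhood Number of informative flanking sites used on each
#'   side of a target site (>= 1).
#' @param report_threshold Posterior required (strict `>`) before an
#'   imputed genotype is emitted (default 0.9).
#'
#' @return A list of class `imputation_params`.
#' @export
imputation_params <- function(switch_rate = 1e-6, mutation_rate = 1e-3,
                              neighborhood = 10L, report_threshold = 0.9) {
  check_prob(switch_rate, "switch_rate", min = 1e-300, max = 1 - 1e-12)
  check_prob(mutation_rate, "mutation_rate", min = 1e-300, max = 1 - 1e-12)
  neighborhood <- check_count(neighborhood, "neighborhood", min = 1L)
  check_prob(report_threshold, "report_threshold")
  structure(
    list(
      switch_rate = switch_rate,
      mutation_rate = mutation_rate,
      neighborhood = neighborhood,
      report_threshold = report_threshold
    ),
    class = "imputation_params"
  )
}

# P(copied allele = 1 | state), i.e. panel allele filtered through the
# copy-error rate.
copy_allele_prob <- function(panel_col, mu) {
  panel_col * (1 - mu) + (1 - panel_col) * mu
}

# One transition step of the two-chain copying HMM over distance d bp,
# applied to the joint state matrix F (N x N). Per chain the transition
# is T = (1 - rho) I + rho/N with rho = 1 - exp(-rate * d); jointly
# F' = T F T', which expands into row-mean, column-mean and grand-mean
# terms and so costs O(N^2).
pair_transition <- function(F, d, rate) {
  rho <- -expm1(-rate * d)
  cm <- colMeans(F)
  rm <- rowMeans(F)
  g <- mean(F)
  (1 - rho)^2 * F +
    (1 - rho) * rho * (rm + rep(cm, each = nrow(F))) +
    rho^2 * g
}

# Joint emission matrix at one site: E[k, l] = sum_g cond[g] *
# P(dosage g | states k, l), with per-chain alt-allele probabilities p.
pair_emission <- function(p, cond3) {
  q <- 1 - p
  cond3[1L] * outer(q, q) +
    cond3[2L] * (outer(p, q) + outer(q, p)) +
    cond3[3L] * outer(p, p)
}

# Genotype posterior (dosage 0/1/2) at `target` from soft per-site
# genotype evidence. `cond` is an S x 3 matrix of genotype probability
# rows (dosage order 0, 1, 2); rows of NA carry no evidence. The target
# site's own evidence is never used. Windowed forward-backward over the
# joint copied-haplotype state of the two chains.
pair_genotype_posterior <- function(panel, cond, target, params) {
  H <- panel$haplotypes
  pos <- panel$positions
  N <- nrow(H)
  mu <- params$mutation_rate
  informative <- which(!is.na(cond[, 1L]))
  informative <- informative[informative != target]
  left <- tail(informative[informative < target], params$neighborhood)
  right <- head(informative[informative > target], params$neighborhood)

  pass <- function(idx) {
    F <- matrix(1 / N^2, N, N)
    if (length(idx) == 0L) return(F)
    prev <- NULL
    for (j in idx) {
      if (!is.null(prev)) {
        F <- pair_transition(F, abs(pos[j] - pos[prev]),
                             params$switch_rate)
      }
      F <- F * pair_emission(copy_allele_prob(H[, j], mu), cond[j, ])
      s <- sum(F)
      if (s <= 0) return(matrix(1 / N^2, N, N))
      F <- F / s
      prev <- j
    }
    pair_transition(F, abs(pos[target] - pos[prev]), params$switch_rate)
  }

  P <- pass(left) * pass(rev(right))
  P <- P / sum(P)
  pt <- copy_allele_prob(H[, target], mu)
  qt <- 1 - pt
  g0 <- drop(qt %*% P %*% qt)
  g2 <- drop(pt %*% P %*% pt)
  g1 <- drop(pt %*% P %*% qt) + drop(qt %*% P %*% pt)
  out <- c(g0, g1, g2)
  out / sum(out)
}

# Genotype distribution over the site's panel-allele genotype strings
# from a dosage probability vector.
dosage_to_genotype_dist <- function(p3, ref, alt, position) {
  names(p3) <- c(gt_string(ref, ref), gt_string(ref, alt),
                 gt_string(alt, alt))
  genotype_dist(p3, "probability", position)
}

#' Haplotype-informed genotype prior at a target site
#'
#' Produces a genotype prior at one panel site from the genotype
#' probability distributions of surrounding sites and the phased panel.
#' A forward-backward pass over the joint hidden state of the two
#' copied panel haplotypes — independent chains coupled by the
#' per-site genotype evidence — yields the posterior genotype (dosage)
#' distribution at the target site before any of the target's own read
#' evidence is seen.
#'
#' @param target_index Site index (column of the panel) to impute.
#' @param neighbor_distributions List, one element per panel site, each
#'   either `NULL` (no evidence) or a probability-kind [genotype_dist()]
#'   over the site's 3 panel-allele genotypes (order ref/ref, ref/alt,
#'   alt/alt). The target site's own entry is ignored.
#' @param panel A [haplotype_panel()].
#' @param params An [imputation_params()].
#'
#' @return A probability-kind [genotype_dist()] over the target site's
#'   3 genotypes.
#' @export
impute_genotype_prior <- function(target_index, neighbor_distributions,
                                  panel, params = imputation_params()) {
  if (!inherits(panel, "haplotype_panel")) {
    abort("`panel` must be a haplotype_panel.")
  }
  target_index <- check_count(target_index, "target_index")
  if (target_index > n_sites(panel)) {
    abort("`target_index` is not a panel site.")
  }
  if (length(neighbor_distributions) != n_sites(panel)) {
    abort("`neighbor_distributions` must have one entry per panel site.")
  }
  cond <- matrix(NA_real_, n_sites(panel), 3L)
  for (j in seq_along(neighbor_distributions)) {
    d <- neighbor_distributions[[j]]
    if (!is.null(d)) cond[j, ] <- d$value / sum(d$value)
  }
  p3 <- pair_genotype_posterior(panel, cond, target_index, params)
  dosage_to_genotype_dist(p3, panel$ref[target_index],
                          panel$alt[target_index],
                          panel$positions[target_index])
}

#' Genotype-frequency (Hardy-Weinberg) prior at a panel site
#'
#' The prior used when only allele-frequency information is available:
#' the Hardy-Weinberg genotype distribution \{(1-p)^2, 2p(1-p), p^2\}
#' implied by the panel's alternate-allele frequency p at the site.
#'
#' @param target_index Site index (column of the panel).
#' @param panel A [haplotype_panel()].
#'
#' @return A probability-kind [genotype_dist()] over the site's 3
#'   genotypes.
#' @export
genotype_frequency_prior <- function(target_index, panel) {
  if (!inherits(panel, "haplotype_panel")) {
    abort("`panel` must be a haplotype_panel.")
  }
  target_index <- check_count(target_index, "target_index")
  if (target_index > n_sites(panel)) {
    abort("`target_index` is not a panel site.")
  }
  p <- panel_allele_freq(panel)[target_index]
  dosage_to_genotype_dist(c((1 - p)^2, 2 * p * (1 - p), p^2),
                          panel$ref[target_index],
                          panel$alt[target_index],
                          panel$positions[target_index])
}

#' Impute genotypes at untyped panel sites from typed genotypes
#'
#' Given hard genotypes at a typed subset of panel sites (an array-like
#' input), imputes every untyped panel site through the
#' haplotype-copying model and emits the most probable genotype wherever
#' its posterior strictly exceeds `params$report_threshold`. Typed sites
#' pass through unchanged and are flagged.
#'
#' @param typed_genotypes Tibble with `position` and `gt` (canonical
#'   genotype strings over the site's panel alleles); positions must be
#'   panel sites.
#' @param panel A [haplotype_panel()].
#' @param params An [imputation_params()].
#'
#' @return Tibble `position`, `gt`, `posterior`, `typed`, sorted by
#'   position: all typed sites plus the untyped sites whose posterior
#'   exceeds the reporting threshold.
#' @export
impute_untyped_sites <- function(typed_genotypes, panel,
                                 params = imputation_params()) {
  if (!inherits(panel, "haplotype_panel")) {
    abort("`panel` must be a haplotype_panel.")
  }
  if (is.null(typed_genotypes) || nrow(typed_genotypes) == 0L) {
    abort("`typed_genotypes` must contain at least one typed site.")
  }
  idx <- match(typed_genotypes$position, panel$positions)
  if (anyNA(idx)) abort("All typed positions must be panel sites.")
  S <- n_sites(panel)
  cond <- matrix(NA_real_, S, 3L)
  hom_ref <- gt_string(panel$ref[idx], panel$ref[idx])
  hom_alt <- gt_string(panel$alt[idx], panel$alt[idx])
  dosage <- ifelse(typed_genotypes$gt == hom_alt, 2L,
                   ifelse(typed_genotypes$gt == hom_ref, 0L, 1L))
  cond[idx, ] <- 0
  cond[cbind(idx, dosage + 1L)] <- 1
  untyped <- setdiff(seq_len(S), idx)
  rows <- purrr::map(untyped, function(t) {
    p3 <- pair_genotype_posterior(panel, cond, t, params)
    k <- which.max(p3)
    gt <- c(gt_string(panel$ref[t], panel$ref[t]),
            gt_string(panel$ref[t], panel$alt[t]),
            gt_string(panel$alt[t], panel$alt[t]))[k]
    tibble(position = panel$positions[t], gt = gt, posterior = p3[k],
           typed = FALSE)
  })
  imputed <- bind_rows(rows)
  imputed <- imputed[imputed$posterior > params$report_threshold, ,
                     drop = FALSE]
  typed_out <- tibble(
    position = typed_genotypes$position,
    gt = typed_genotypes$gt,
    posterior = NA_real_,
    typed = TRUE
  )
  arrange(bind_rows(typed_out, imputed), .data$position)
}
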