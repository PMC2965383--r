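#' Per-site genotype distributions
#'
#' A `genotype_dist` is a small tibble (`genotype`, `value`) carrying the
#' probabilities or likelihood ratios over a diploid genotype space at
#' one site: either the 10 unordered genotypes over \{A,C,G,T\} or the 3
#' genotypes over a site's two panel alleles. It is the currency passed
#' between the likelihood, prior and posterior stages.
#'
#' @param values Named non-negative numeric vector (names are canonical
#'   genotype strings such as `"AG"`).
#' @param kind `"likelihood_ratio"` (scaled so the maximum is 1) or
#'   `"probability"` (sums to 1).
#' @param position Optional 1-based site coordinate.
#'
#' @return A tibble of class `genotype_dist` with attributes `kind` and
#'   `position`.
#' @export
genotype_dist <- function(values, kind = c("probability", "likelihood_ratio"),
                          position = NA_integer_) {
  kind <- match.arg(kind)
  if (is.null(names(values)) || any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be a named, finite, non-negative vector.")
  }
  if (kind == "probability") {
    tot <- sum(values)
    if (tot <= 0) abort("Probability-kind distribution needs positive mass.")
    if (abs(tot - 1) > 1e-9) values <- values / tot
  } else {
    mx <- max(values)
    if (mx <= 0) abort("Likelihood ratios need at least one positive value.")
    values <- values / mx
  }
  out <- tibble(genotype = names(values), value = unname(values))
  class(out) <- c("genotype_dist", class(out))
  attr(out, "kind") <- kind
  attr(out, "position") <- position
  out
}

#' @export
print.genotype_dist <- function(x, ...) {
  cat(sprintf("<genotype_dist: %s at %s>\n", attr(x, "kind"),
              attr(x, "position")))
  NextMethod()
}

dist_kind <- function(x) attr(x, "kind")

# log P(observed base | true allele, error e): match -> 1 - e, else e/3.
# Diploid genotype emits each of its two alleles with probability 1/2.

# Per-site log-likelihoods over the 10 unordered genotypes.
site_loglik10 <- function(bases, quals) {
  ll <- setNames(numeric(10L), GT10)
  if (length(bases) == 0L) return(ll)
  a1 <- substr(GT10, 1L, 1L)
  a2 <- substr(GT10, 2L, 2L)
  for (q in unique(quals)) {
    e <- phred_to_error(q)
    # M[b, g] = P(read base b | genotype g)
    pmatch1 <- outer(BASES, a1, function(b, a) ifelse(b == a, 1 - e, e / 3))
    pmatch2 <- outer(BASES, a2, function(b, a) ifelse(b == a, 1 - e, e / 3))
    M <- 0.5 * pmatch1 + 0.5 * pmatch2
    cnt <- tabulate(match(bases[quals == q], BASES), 4L)
    ll <- ll + as.vector(cnt %*% log(M))
  }
  ll
}

# Per-site log-likelihoods over the 3 genotypes (ref/ref, ref/alt, alt/alt).
site_loglik3 <- function(bases, quals, ref, alt) {
  if (length(bases) == 0L) return(c(0, 0, 0))
  e <- phred_to_error(quals)
  is_ref <- bases == ref
  is_alt <- bases == alt
  p_rr <- ifelse(is_ref, 1 - e, e / 3)
  p_aa <- ifelse(is_alt, 1 - e, e / 3)
  p_ra <- 0.5 * p_rr + 0.5 * p_aa
  c(sum(log(p_rr)), sum(log(p_ra)), sum(log(p_aa)))
}

#' Genotype likelihood ratios at one site
#'
#' Computes, for each of the 10 unordered diploid genotypes, the
#' likelihood of the observed read bases: a product over reads of
#' P(base | genotype, error), where a heterozygote emits each of its two
#' alleles with probability 1/2 and the Phred-scaled base quality sets
#' the error probability (capped at 0.75). The result is scaled so the
#' most likely genotype has value 1. An empty pileup carries no
#' information: all ratios are 1.
#'
#' @param pileup A single-site pileup: a one-row tibble as produced by
#'   [simulate_pileups()], or a list with elements `position`, `ref`,
#'   `bases` (character vector) and `quals` (numeric vector).
#'
#' @return A [genotype_dist()] of kind `likelihood_ratio` over the 10
#'   genotypes.
#' @export
site_genotype_likelihoods <- function(pileup) {
  p <- as_site_pileup(pileup)
  ll <- site_loglik10(p$bases, p$quals)
  genotype_dist(exp(ll - max(ll)), "likelihood_ratio", p$position)
}

as_site_pileup <- function(pileup) {
  if (is_tibble(pileup) || is.data.frame(pileup)) {
    if (nrow(pileup) != 1L) abort("Expected a single-site pileup (one row).")
    pileup <- list(position = pileup$position[[1L]], ref = pileup$ref[[1L]],
                   bases = pileup$bases[[1L]], quals = pileup$quals[[1L]])
  }
  if (length(pileup$bases) != length(pileup$quals)) {
    abort("`bases` and `quals` must have equal length.")
  }
  pileup
}

#' Normalize likelihood ratios into conditional probabilities
#'
#' Divides each genotype's likelihood ratio by the sum over the whole
#' genotype space, giving a probability distribution (the "conditional"
#' used as the read-evidence factor in Bayesian combination).
#'
#' @param dist A [genotype_dist()] (any kind) with at least one positive
#'   value.
#'
#' @return A [genotype_dist()] of kind `probability`.
#' @export
likelihoods_to_conditionals <- function(dist) {
  if (!inherits(dist, "genotype_dist")) {
    abort("`dist` must be a genotype_dist.")
  }
  if (all(dist$value == 0)) {
    abort("All-zero distribution cannot be normalized.")
  }
  genotype_dist(setNames(dist$value, dist$genotype), "probability",
                attr(dist, "position"))
}

#' Caller configuration
#'
#' Bundles the thresholds of the sequence-only caller: the prior
#' heterozygosity `theta`, depth filters (diploid sites outside
#' `[min_depth, max_depth]` are excluded; haploid sites use
#' `haploid_min_depth`), the haploid calling rule threshold, the cap on
#' reported Phred-scaled call quality, and the seed used to break exact
#' posterior ties at random.
#'
#' @param theta Prior heterozygosity (default 0.001).
#' @param min_depth,max_depth Inclusive diploid depth bounds (4, 100).
#' @param haploid_min_depth Lower inclusive depth bound for haploid
#'   calling (2).
#' @param haploid_likelihood_threshold Normalized single-allele
#'   likelihood that must be exceeded to call a haploid variant (0.5).
#' @param consensus_quality_cutoff Cap applied to the reported
#'   Phred-scaled call quality (100); no call is removed.
#' @param tie_break_seed Seed for random resolution of exactly tied
#'   genotypes.
#'
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(theta = 0.001, min_depth = 4L, max_depth = 100L,
                          haploid_min_depth = 2L,
                          haploid_likelihood_threshold = 0.5,
                          consensus_quality_cutoff = 100,
                          tie_break_seed = 1L) {
  check_prob(theta, "theta", min = 1e-12, max = 1 - 1e-12)
  if (min_depth > max_depth) abort("`min_depth` must be <= `max_depth`.")
  structure(
    list(
      theta = theta,
      min_depth = as.integer(min_depth),
      max_depth = as.integer(max_depth),
      haploid_min_depth = as.integer(haploid_min_depth),
      haploid_likelihood_threshold = haploid_likelihood_threshold,
      consensus_quality_cutoff = consensus_quality_cutoff,
      tie_break_seed = as.integer(tie_break_seed)
    ),
    class = "caller_config"
  )
}

# Prior over the 10 genotypes given the reference base: mass theta split
# over the 3 reference-bearing heterozygotes, theta/2 over the 3
# non-reference homozygotes, theta^2 per non-reference heterozygote, and
# the remainder on the reference homozygote; renormalized.
theta_prior10 <- function(ref, theta) {
  a1 <- substr(GT10, 1L, 1L)
  a2 <- substr(GT10, 2L, 2L)
  het <- a1 != a2
  has_ref <- a1 == ref | a2 == ref
  pr <- numeric(10L)
  pr[het & has_ref] <- theta / 3
  pr[!het & !has_ref] <- theta / 6
  pr[het & !has_ref] <- theta^2
  pr[!het & has_ref] <- 1 - sum(pr)
  setNames(pr / sum(pr), GT10)
}

# Argmax with seeded random resolution of exact ties (relative 1e-12).
pick_map <- function(values, rng) {
  mx <- max(values)
  cand <- which(values >= mx * (1 - 1e-12))
  if (length(cand) == 1L) return(cand)
  cand[floor(rng() * length(cand)) + 1L]
}

# Phred-scaled call quality from a posterior probability, capped.
posterior_quality <- function(post, cap) {
  q <- -10 * log10(pmax(1 - post, 1e-100))
  pmin(round(q, 1L), cap)
}

# Small deterministic uniform stream so tie-breaking does not perturb
# (or depend on) the global RNG.
make_tie_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- 1
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}

#' Sequence-only genotype calling
#'
#' Calls genotypes from read pileups alone. Diploid mode: sites with
#' depth outside `[min_depth, max_depth]` are marked filtered; remaining
#' sites receive the maximum-a-posteriori genotype under the
#' theta-weighted prior, with exact ties broken at random under
#' `tie_break_seed`. Haploid mode: the four single-allele likelihoods
#' are normalized and a variant is called where a non-reference allele's
#' normalized likelihood exceeds the configured threshold; depth bounds
#' `[haploid_min_depth, max_depth]` apply.
#'
#' @param pileups Pileup tibble from [simulate_pileups()] (or
#'   [read_pileups()]).
#' @param config A [caller_config()].
#' @param ploidy `"diploid"` or `"haploid"`.
#'
#' @return A call tibble: `position`, `ref`, `alt`, `genotype`,
#'   `posterior`, `quality`, `depth`, `filter`, `mode`. Filtered or
#'   uncalled sites carry `NA` genotype and a reason in `filter`.
#' @export
call_sequence_only <- function(pileups, config = caller_config(),
                               ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(inherits(config, "caller_config"))
  n <- nrow(pileups)
  rng <- make_tie_rng(config$tie_break_seed)
  depth <- vapply(pileups$bases, length, integer(1L))
  genotype <- rep(NA_character_, n)
  posterior <- rep(NA_real_, n)
  filter <- rep("PASS", n)
  if (ploidy == "diploid") {
    filter[depth < config$min_depth] <- "LOW_DEPTH"
    filter[depth > config$max_depth] <- "HIGH_DEPTH"
    for (i in which(filter == "PASS")) {
      ll <- site_loglik10(pileups$bases[[i]], pileups$quals[[i]])
      prior <- theta_prior10(pileups$ref[[i]], config$theta)
      post <- exp(ll - max(ll)) * prior
      post <- post / sum(post)
      k <- pick_map(post, rng)
      genotype[i] <- GT10[k]
      posterior[i] <- post[k]
    }
  } else {
    filter[depth < config$haploid_min_depth] <- "LOW_DEPTH"
    filter[depth > config$max_depth] <- "HIGH_DEPTH"
    for (i in which(filter == "PASS")) {
      e <- phred_to_error(pileups$quals[[i]])
      lik <- vapply(BASES, function(a) {
        sum(log(ifelse(pileups$bases[[i]] == a, 1 - e, e / 3)))
      }, numeric(1L))
      lik <- exp(lik - max(lik))
      lik <- lik / sum(lik)
      k <- pick_map(lik, rng)
      if (lik[k] > config$haploid_likelihood_threshold) {
        genotype[i] <- BASES[k]
        posterior[i] <- lik[k]
      } else {
        filter[i] <- "NO_CALL"
      }
    }
  }
  finalize_calls(pileups, depth, genotype, posterior, filter,
                 mode = if (ploidy == "diploid") "sequence_only"
                        else "haploid", config)
}

# Shared assembly of the call tibble.
finalize_calls <- function(pileups, depth, genotype, posterior, filter,
                           mode, config) {
  ref <- as.character(pileups$ref)
  alt <- rep(NA_character_, length(ref))
  called <- !is.na(genotype)
  if (any(called)) {
    g <- genotype[called]
    a1 <- substr(g, 1L, 1L)
    a2 <- substr(g, 2L, 2L)
    a2[a2 == ""] <- a1[a2 == ""] # haploid single-allele genotypes
    r <- ref[called]
    alt_candidate <- ifelse(a1 != r, a1, ifelse(a2 != r, a2, NA_character_))
    alt[called] <- alt_candidate
  }
  tibble(
    position = pileups$position,
    ref = ref,
    alt = alt,
    genotype = genotype,
    posterior = posterior,
    quality = ifelse(is.na(posterior), NA_real_,
                     posterior_quality(posterior,
                                       config$consensus_quality_cutoff)),
    depth = as.integer(depth),
    filter = filter,
    mode = mode
  )
}
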