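# Independent oracle implementations used to freeze expected values.
# These deliberately take the slow, literal route (enumeration, explicit
# pairwise loops) so they stay independent of the package's vectorized
# code paths.

# Exhaustive enumeration over all copy-path pairs of the two-chain
# haplotype-copying model. `cond` is an S x 3 dosage-evidence matrix
# (NA rows = no evidence); returns the genotype (dosage) posterior at
# `target` using only the evidence sites.
enum_pair_prior <- function(panel, cond, target, params) {
  H <- panel$haplotypes
  pos <- panel$positions
  N <- nrow(H)
  mu <- params$mutation_rate
  sites <- sort(unique(c(which(!is.na(cond[, 1L])), target)))
  S <- length(sites)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), S)))
  path_prob <- function(pm) {
    pr <- rep(1 / N, nrow(pm))
    if (S > 1L) {
      for (s in 2:S) {
        d <- pos[sites[s]] - pos[sites[s - 1L]]
        rho <- 1 - exp(-params$switch_rate * d)
        stay <- (1 - rho) + rho / N
        move <- rho / N
        pr <- pr * ifelse(pm[, s] == pm[, s - 1L], stay, move)
      }
    }
    pr
  }
  cap <- function(allele) allele * (1 - mu) + (1 - allele) * mu
  W <- outer(path_prob(paths), path_prob(paths))
  for (s in seq_len(S)) {
    j <- sites[s]
    if (j == target || is.na(cond[j, 1L])) next
    pa <- cap(H[cbind(paths[, s], j)])
    E <- cond[j, 1L] * outer(1 - pa, 1 - pa) +
      cond[j, 2L] * (outer(pa, 1 - pa) + outer(1 - pa, pa)) +
      cond[j, 3L] * outer(pa, pa)
    W <- W * E
  }
  st <- which(sites == target)
  pt <- cap(H[cbind(paths[, st], target)])
  g <- c(
    sum(W * outer(1 - pt, 1 - pt)),
    sum(W * (outer(pt, 1 - pt) + outer(1 - pt, pt))),
    sum(W * outer(pt, pt))
  )
  g / sum(g)
}

# Straight-line Tajima's D: explicit pairwise Hamming distances and the
# 1989 normalization constants written out term by term.
oracle_tajimas_d <- function(mat, n = nrow(mat)) {
  seg <- apply(mat, 2, function(col) {
    s <- sum(col)
    s > 0 && s < n
  })
  S <- sum(seg)
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(pr) sum(mat[pr[1], ] != mat[pr[2], ]))
  pi_hat <- mean(diffs)
  if (S == 0) return(list(S = 0L, pi = pi_hat, D = NA_real_))
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = as.integer(S), pi = pi_hat, D = D)
}

# Fisher's exact p by explicit enumeration over all 2x2 tables with the
# observed margins, using log-binomial coefficients only.
enum_fisher_p <- function(tab, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  logp <- function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)
  }
  all_a <- lo:hi
  probs <- exp(vapply(all_a, logp, numeric(1)))
  obs <- tab[1, 1]
  if (alternative == "greater") {
    sum(probs[all_a >= obs])
  } else {
    p_obs <- exp(logp(obs))
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# Direct 10-genotype likelihood at a site by looping over reads and
# genotypes with scalar arithmetic.
oracle_lik10 <- function(bases, quals) {
  gts <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
  out <- numeric(10)
  for (g in seq_along(gts)) {
    a1 <- substr(gts[g], 1, 1)
    a2 <- substr(gts[g], 2, 2)
    lik <- 1
    for (r in seq_along(bases)) {
      e <- min(0.75, 10^(-quals[r] / 10))
      p1 <- if (bases[r] == a1) 1 - e else e / 3
      p2 <- if (bases[r] == a2) 1 - e else e / 3
      lik <- lik * (0.5 * p1 + 0.5 * p2)
    }
    out[g] <- lik
  }
  names(out) <- gts
  out
}
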