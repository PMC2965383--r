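#' Construct a phased haplotype reference panel
#'
#' A `haplotype_panel` holds a phased binary allele matrix over ordered,
#' biallelic sites: the LD backbone used for simulation, genotype priors
#' and r-squared computation.
#'
#' @param haplotypes Integer/numeric matrix (`n_haplotypes` x `n_sites`)
#'   with entries 0 (reference allele) or 1 (alternate allele).
#' @param positions Strictly increasing 1-based base-pair coordinates,
#'   one per site.
#' @param ref,alt Per-site allele symbols (single bases); `ref[i] != alt[i]`.
#' @param chromosome Chromosome label.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, positions, ref, alt,
                            chromosome = "chr1") {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% c(0, 1))) {
    abort("Panel matrix entries must be 0 or 1.")
  }
  storage.mode(haplotypes) <- "integer"
  n_sites <- ncol(haplotypes)
  if (length(positions) != n_sites) {
    abort("`positions` must have one entry per panel site.")
  }
  if (n_sites > 1L && any(diff(positions) <= 0)) {
    abort("`positions` must be strictly increasing.")
  }
  if (length(ref) != n_sites || length(alt) != n_sites || any(ref == alt)) {
    abort("`ref` and `alt` must be per-site allele symbols with ref != alt.")
  }
  structure(
    list(
      chromosome = as.character(chromosome)[1L],
      positions = as.integer(positions),
      ref = as.character(ref),
      alt = as.character(alt),
      haplotypes = haplotypes
    ),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d haplotypes x %d sites on %s [%d-%d]\n",
    n_haplotypes(x), n_sites(x), x$chromosome,
    min(x$positions), max(x$positions)
  ))
  invisible(x)
}

#' Panel dimensions
#'
#' @param panel A [haplotype_panel()].
#' @return Number of haplotypes (rows) or sites (columns).
#' @export
n_haplotypes <- function(panel) nrow(panel$haplotypes)

#' @rdname n_haplotypes
#' @export
n_sites <- function(panel) ncol(panel$haplotypes)

#' Alternate-allele frequencies of panel sites
#'
#' @param panel A [haplotype_panel()].
#' @return Numeric vector of per-site alternate-allele frequencies.
#' @export
panel_allele_freq <- function(panel) {
  colMeans(panel$haplotypes)
}

#' @describeIn haplotype_panel Long (one row per haplotype/site) view of
#'   the panel allele matrix.
#' @param x A `haplotype_panel`.
#' @param ... Unused.
#' @export
tidy.haplotype_panel <- function(x, ...) {
  tibble(
    chromosome = x$chromosome,
    haplotype = rep(seq_len(n_haplotypes(x)), times = n_sites(x)),
    position = rep(x$positions, each = n_haplotypes(x)),
    allele = as.integer(x$haplotypes)
  )
}

#' Simulate an LD-structured haplotype panel
#'
#' Generates a phased panel by a founder + mosaic-copy process. The
#' first `n_founders` haplotypes are drawn independently with per-site
#' alternate-allele probabilities sampled from a neutral-like 1/p
#' frequency spectrum (random polarity). Every subsequent haplotype
#' copies a random previously generated one, with a Poisson-distributed
#' number of switch points (at each switch the source haplotype is
#' re-drawn) and an independent per-site copy error ("mutation"). The
#' copying creates linkage disequilibrium that decays with inter-site
#' distance, tunable through `recombination_intensity`; the founder
#' standing variation balances the copy-mutation excess of rare alleles
#' so the site-frequency spectrum is approximately neutral. Sites that
#' end up monomorphic are repolarised by flipping one random haplotype
#' so every site is segregating.
#'
#' @param n_haplotypes Number of panel haplotypes (>= 4).
#' @param n_sites Number of biallelic sites (>= 2).
#' @param region_length Length of the simulated region in base pairs;
#'   site positions are drawn uniformly and sorted.
#' @param recombination_intensity Expected number of copy switches per
#'   haplotype across the region.
#' @param mutation_rate Per-site copy-error probability.
#' @param n_founders Number of independent founder haplotypes seeding
#'   the standing variation (capped at `n_haplotypes`).
#' @param seed Integer seed; identical seeds give identical panels.
#' @param chromosome Chromosome label.
#'
#' @return A [haplotype_panel()].
#' @export
simulate_panel <- function(n_haplotypes, n_sites,
                           region_length = n_sites * 1000L,
                           recombination_intensity = 1,
                           mutation_rate = 0.02,
                           n_founders = 8L,
                           seed = NULL,
                           chromosome = "chr1") {
  n_haplotypes <- check_count(n_haplotypes, "n_haplotypes", min = 4L)
  n_sites <- check_count(n_sites, "n_sites", min = 2L)
  region_length <- check_count(region_length, "region_length", min = n_sites)
  check_prob(mutation_rate, "mutation_rate")
  n_founders <- min(check_count(n_founders, "n_founders", min = 1L),
                    n_haplotypes)
  if (recombination_intensity < 0) {
    abort("`recombination_intensity` must be non-negative.")
  }
  with_seed(seed, {
    positions <- sort(sample.int(region_length, n_sites))
    ref_idx <- sample.int(4L, n_sites, replace = TRUE)
    alt_idx <- 1L + (ref_idx - 1L + sample.int(3L, n_sites, replace = TRUE)) %% 4L
    H <- matrix(0L, n_haplotypes, n_sites)
    # founder allele frequencies ~ 1/p on (eps, 1), random polarity
    eps <- 1 / (2 * n_haplotypes)
    pj <- eps^runif(n_sites)
    flip_pol <- runif(n_sites) < 0.5
    pj <- ifelse(flip_pol, 1 - pj, pj)
    for (i in seq_len(n_founders)) {
      H[i, ] <- as.integer(runif(n_sites) < pj)
    }
    if (n_haplotypes > n_founders) {
      for (i in (n_founders + 1L):n_haplotypes) {
        H[i, ] <- mosaic_copy(H[seq_len(i - 1L), , drop = FALSE],
                              recombination_intensity)$haplotype
        flip <- runif(n_sites) < mutation_rate
        H[i, flip] <- 1L - H[i, flip]
      }
    }
    mac <- colSums(H)
    mono <- which(mac == 0L | mac == n_haplotypes)
    if (length(mono) > 0L) {
      rows <- sample.int(n_haplotypes, length(mono), replace = TRUE)
      H[cbind(rows, mono)] <- 1L - H[cbind(rows, mono)]
    }
    haplotype_panel(H, positions, BASES[ref_idx], BASES[alt_idx], chromosome)
  })
}

# Copy one mosaic haplotype from the rows of `source`: Poisson(intensity)
# switch points at uniformly drawn site boundaries; a fresh source row is
# drawn on each segment. Returns the haplotype and the breakpoint indices
# (first site index of each new segment).
mosaic_copy <- function(source, intensity) {
  n_src <- nrow(source)
  n_sites <- ncol(source)
  n_switch <- rpois(1L, intensity)
  if (n_switch > 0L && n_sites > 1L) {
    breaks <- sort(sample(2:n_sites, min(n_switch, n_sites - 1L)))
  } else {
    breaks <- integer(0)
  }
  starts <- c(1L, breaks)
  ends <- c(breaks - 1L, n_sites)
  hap <- integer(n_sites)
  for (s in seq_along(starts)) {
    src <- sample.int(n_src, 1L)
    hap[starts[s]:ends[s]] <- source[src, starts[s]:ends[s]]
  }
  list(haplotype = hap, breakpoints = breaks)
}

#' Sample a diploid individual as a mosaic of panel haplotypes
#'
#' Each of the two target haplotypes is constructed by copying segments
#' of panel haplotypes, with a Poisson-distributed number of switch
#' points. With `recombination_intensity = 0` each target haplotype is an
#' exact copy of one panel row. Genotypes are derived directly from the
#' two haplotypes, so the returned object carries exact truth for
#' downstream evaluation.
#'
#' @param panel A [haplotype_panel()].
#' @param recombination_intensity Expected switches per target haplotype.
#' @param seed Integer seed.
#'
#' @return A `diploid_truth` object: list with `hap_a`, `hap_b` (binary
#'   allele vectors), `genotypes` (tibble: position, gt, dosage),
#'   `breakpoints_a`, `breakpoints_b` (site indices of copy switches),
#'   and the originating `panel`.
#' @export
sample_diploid <- function(panel, recombination_intensity = 1, seed = NULL) {
  if (!inherits(panel, "haplotype_panel") || n_sites(panel) == 0L) {
    abort("`panel` must be a non-empty haplotype_panel.")
  }
  if (recombination_intensity < 0) {
    abort("`recombination_intensity` must be non-negative.")
  }
  with_seed(seed, {
    a <- mosaic_copy(panel$haplotypes, recombination_intensity)
    b <- mosaic_copy(panel$haplotypes, recombination_intensity)
    dosage <- a$haplotype + b$haplotype
    allele_a <- ifelse(a$haplotype == 1L, panel$alt, panel$ref)
    allele_b <- ifelse(b$haplotype == 1L, panel$alt, panel$ref)
    structure(
      list(
        hap_a = a$haplotype,
        hap_b = b$haplotype,
        genotypes = tibble(
          position = panel$positions,
          gt = gt_string(allele_a, allele_b),
          dosage = as.integer(dosage)
        ),
        breakpoints_a = a$breakpoints,
        breakpoints_b = b$breakpoints,
        panel = panel
      ),
      class = "diploid_truth"
    )
  })
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat(sprintf(
    "<diploid_truth> %d sites, %d het (%d + %d copy switches)\n",
    nrow(x$genotypes), sum(x$genotypes$dosage == 1L),
    length(x$breakpoints_a), length(x$breakpoints_b)
  ))
  invisible(x)
}

#' Write / read a panel in hap+legend text format
#'
#' The legend file is whitespace-separated with columns `id`, `position`,
#' `allele0`, `allele1`; the hap file has one column per haplotype and
#' one row per site, entries 0/1.
#'
#' @param panel A [haplotype_panel()].
#' @param hap_file,legend_file Paths for the two text files.
#' @return `write_hap_legend()` returns the panel invisibly;
#'   `read_hap_legend()` returns a [haplotype_panel()].
#' @export
write_hap_legend <- function(panel, hap_file, legend_file) {
  legend <- data.frame(
    id = sprintf("%s_%d", panel$chromosome, panel$positions),
    position = panel$positions,
    allele0 = panel$ref,
    allele1 = panel$alt
  )
  utils::write.table(legend, legend_file, quote = FALSE, row.names = FALSE)
  utils::write.table(t(panel$haplotypes), hap_file, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(panel)
}

#' @rdname write_hap_legend
#' @param chromosome Chromosome label for the panel read back.
#' @export
read_hap_legend <- function(hap_file, legend_file, chromosome = "chr1") {
  legend <- utils::read.table(legend_file, header = TRUE,
                              colClasses = c("character", "integer",
                                             "character", "character"))
  hap <- as.matrix(utils::read.table(hap_file, header = FALSE))
  hap <- t(hap)
  dimnames(hap) <- NULL
  haplotype_panel(hap, legend$position, legend$allele0, legend$allele1,
                  chromosome)
}
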