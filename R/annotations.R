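#' Simulate gene models, paralog pairs and a disease-marker catalog
#'
#' Generates the annotation side of a study region with known ground
#' truth: non-overlapping gene intervals, paralog pairs tagged with a
#' duplication-age class and a proximity flag (gene starts closer than
#' `proximity_limit` base pairs), disease markers placed at panel sites
#' with phenotype labels, and a set of "known" variant positions
#' (catalog membership; everything else is novel).
#'
#' @param panel A [haplotype_panel()] defining the coordinate space.
#' @param n_genes Number of genes to place.
#' @param n_markers Number of disease markers (drawn from panel sites).
#' @param paralog_age_classes Ordered duplication-age labels, youngest
#'   first (e.g. species-specific ... vertebrate).
#' @param gene_length Gene interval length in base pairs.
#' @param paralog_fraction Fraction of genes entering paralog pairs.
#' @param known_fraction Fraction of panel sites in the known-variant set.
#' @param proximity_limit Distance between gene starts below which a
#'   paralog pair is flagged as proximal (default 250 kb).
#' @param seed Integer seed.
#'
#' @return An `annotation_set`: list of tibbles `genes` (gene_id, start,
#'   end), `paralog_pairs` (gene_id_1, gene_id_2, age_class, proximal),
#'   `disease_markers` (position, phenotype, known), and integer vector
#'   `known_variants` of positions.
#' @export
simulate_annotations <- function(panel, n_genes, n_markers,
                                 paralog_age_classes = c(
                                   "species_specific", "primate",
                                   "mammal", "vertebrate"
                                 ),
                                 gene_length = 10000L,
                                 paralog_fraction = 0.5,
                                 known_fraction = 0.7,
                                 proximity_limit = 250000L,
                                 seed = NULL) {
  if (!inherits(panel, "haplotype_panel")) {
    abort("`panel` must be a haplotype_panel.")
  }
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_markers <- check_count(n_markers, "n_markers", min = 0L)
  region_end <- max(panel$positions)
  if (n_genes * gene_length > region_end) {
    abort("Cannot pack the requested genes into the panel region.")
  }
  if (n_markers > n_sites(panel)) {
    abort("More markers requested than panel sites.")
  }
  with_seed(seed, {
    # place genes by spreading them over slots, jittering within slack
    slot <- floor(region_end / n_genes)
    jitter_max <- max(0L, slot - gene_length)
    starts <- (seq_len(n_genes) - 1L) * slot + 1L +
      floor(runif(n_genes, 0, jitter_max + 1))
    genes <- tibble(
      gene_id = sprintf("G%03d", seq_len(n_genes)),
      start = as.integer(starts),
      end = as.integer(starts + gene_length - 1L)
    )
    n_paired <- 2L * floor(paralog_fraction * n_genes / 2)
    if (n_paired >= 2L) {
      chosen <- sample(genes$gene_id, n_paired)
      g1 <- chosen[seq(1L, n_paired, by = 2L)]
      g2 <- chosen[seq(2L, n_paired, by = 2L)]
      age <- sample(paralog_age_classes, n_paired / 2L, replace = TRUE)
      s1 <- genes$start[match(g1, genes$gene_id)]
      s2 <- genes$start[match(g2, genes$gene_id)]
      pairs <- tibble(
        gene_id_1 = g1, gene_id_2 = g2,
        age_class = factor(age, levels = paralog_age_classes),
        proximal = abs(s1 - s2) < proximity_limit
      )
    } else {
      pairs <- tibble(
        gene_id_1 = character(), gene_id_2 = character(),
        age_class = factor(character(), levels = paralog_age_classes),
        proximal = logical()
      )
    }
    marker_pos <- sort(sample(panel$positions, n_markers))
    markers <- tibble(
      position = marker_pos,
      phenotype = sprintf("trait_%02d", seq_len(n_markers)),
      known = TRUE
    )
    known <- sort(sample(panel$positions,
                         floor(known_fraction * n_sites(panel))))
    known <- sort(union(known, marker_pos))
    structure(
      list(
        genes = genes,
        paralog_pairs = pairs,
        disease_markers = markers,
        known_variants = as.integer(known)
      ),
      class = "annotation_set"
    )
  })
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d genes, %d paralog pairs, %d disease markers, %d known variants\n",
    nrow(x$genes), nrow(x$paralog_pairs), nrow(x$disease_markers),
    length(x$known_variants)
  ))
  invisible(x)
}
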