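# Small fixtures built in code.

# Hand-built 6-haplotype panel whose rows are mutually distinguishable
# within any 3-site window; used where tests need unambiguous copying.
fixture_panel <- function() {
  H <- rbind(
    c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L),
    c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L),
    c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
    c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L),
    c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L),
    c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)
  )
  haplotype_panel(
    H,
    positions = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L, 7000L, 8000L),
    ref = rep("A", 8L),
    alt = rep("G", 8L)
  )
}

# Evidence matrix asserting the exact dosages of two chosen panel rows,
# with the target site masked.
certain_evidence <- function(panel, row_a, row_b, target) {
  dosage <- panel$haplotypes[row_a, ] + panel$haplotypes[row_b, ]
  cond <- matrix(0, n_sites(panel), 3L)
  cond[cbind(seq_len(n_sites(panel)), dosage + 1L)] <- 1
  cond[target, ] <- NA_real_
  cond
}

# One-row pileup tibble from explicit reads.
make_pileup <- function(position, ref, bases, quals = rep(20L, length(bases))) {
  tibble::tibble(
    position = as.integer(position),
    ref = ref,
    depth = length(bases),
    bases = list(as.character(bases)),
    quals = list(as.integer(quals))
  )
}

pileup_table <- function(...) dplyr::bind_rows(...)
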