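# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# The 10 unordered diploid genotypes over {A,C,G,T}, lexicographic.
GT10 <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

# Canonical genotype string: two allele symbols, sorted.
gt_string <- function(a1, a2) {
  swap <- a1 > a2
  paste0(ifelse(swap, a2, a1), ifelse(swap, a1, a2))
}

gt_is_het <- function(gt) substr(gt, 1L, 1L) != substr(gt, 2L, 2L)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying within
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 2654435L + index * 97L) %% 2147483629)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name, min = 0, max = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", name, min, max))
  }
  as.double(x)
}

# Phred score -> base error probability, capped at 0.75.
phred_to_error <- function(q) pmin(0.75, 10^(-q / 10))
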