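#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("geometric_mean() requires strictly positive finite values")
  }
  exp(mean(log(x)))
}

# Derive a child RNG seed from a root seed and a stream label, so each
# generator draws from its own stream and adding one does not perturb others.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483587)
}

# Coerce a counts input (matrix with rownames, or data frame with a `gene`
# column and one numeric column per sample) to a named integer-ish matrix.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) abort("count matrix must have gene rownames")
    return(counts)
  }
  if (is.data.frame(counts)) {
    if (!"gene" %in% names(counts)) {
      abort("counts data frame must contain a `gene` column")
    }
    genes <- counts$gene
    m <- as.matrix(counts[setdiff(names(counts), c("gene", "transcript"))])
    rownames(m) <- genes
    return(m)
  }
  abort("counts must be a matrix or a data frame with a `gene` column")
}

# Wide gene x sample matrix back to a tibble with a `gene` column.
matrix_to_tibble <- function(m) {
  bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

check_probability <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
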