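#' Gene-wise trait correlation signature
#'
#' Spearman correlation between a per-sample trait (e.g. the ABCD variant
#' frequency, or Adarb1 qPCR) and every gene's normalized expression,
#' Benjamini-Hochberg adjusted across genes. Genes with adjusted p at or
#' below `fdr_cut` form the positive / negative signature according to the
#' sign of rho. P-values are exact (permutation distribution) for n <= 9
#' without ties and asymptotic otherwise.
#'
#' @param study an [expression_study()] or a normalized gene-by-sample
#'   matrix.
#' @param trait numeric trait, one value per sample (non-constant).
#' @param trait_name label stored with the signature.
#' @param fdr_cut signature cut on adjusted p (default 0.1).
#' @return a `trait_signature` tibble: `gene`, `rho`, `p_value`,
#'   `p_adjusted`, `sign` (`"positive"`, `"negative"` or `"none"`), with the
#'   trait name and cut as attributes.
#' @export
correlate_trait <- function(study, trait, trait_name = "trait", fdr_cut = 0.1) {
  v <- if (inherits(study, "expression_study")) {
    if (is.null(study$normalized)) study <- normalize_study(study)
    study$normalized
  } else {
    as_count_matrix(study)
  }
  if (length(trait) != ncol(v)) abort("trait must have one value per sample")
  if (anyNA(trait) || sd(trait) == 0) abort("trait must be non-constant and complete")
  if (ncol(v) < 4) abort("need at least 4 samples")
  use_exact <- ncol(v) <= 9
  stats <- apply(v, 1, function(g) {
    ct <- suppressWarnings(
      cor.test(g, trait, method = "spearman", exact = use_exact)
    )
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  res <- tibble(
    gene = rownames(v),
    rho = unname(stats["rho", ]),
    p_value = unname(stats["p", ]),
    p_adjusted = unname(p.adjust(stats["p", ], method = "BH"))
  ) |>
    mutate(sign = dplyr::case_when(
      .data$p_adjusted <= fdr_cut & .data$rho > 0 ~ "positive",
      .data$p_adjusted <= fdr_cut & .data$rho < 0 ~ "negative",
      .default = "none"
    ))
  class(res) <- c("trait_signature", class(res))
  attr(res, "trait_name") <- trait_name
  attr(res, "fdr_cut") <- fdr_cut
  res
}

#' Extract the signed gene sets of a signature
#'
#' @param signature a `trait_signature` from [correlate_trait()].
#' @return named list with `positive` and `negative` gene vectors.
#' @export
signature_sets <- function(signature) {
  list(
    positive = signature$gene[signature$sign == "positive"],
    negative = signature$gene[signature$sign == "negative"]
  )
}

#' @method glance trait_signature
#' @export
glance.trait_signature <- function(x, ...) {
  tibble(
    trait = attr(x, "trait_name") %||% "trait",
    n_genes = nrow(x),
    n_positive = sum(x$sign == "positive"),
    n_negative = sum(x$sign == "negative"),
    fdr_cut = attr(x, "fdr_cut") %||% NA_real_
  )
}

#' Shared gene universe between two studies
#'
#' Case-normalized intersection of the gene symbols detected in two studies;
#' cross-species overlap tests are run against this shared universe.
#'
#' @param genes_a,genes_b character vectors of gene symbols.
#' @return character vector of shared (upper-cased) symbols.
#' @export
shared_universe <- function(genes_a, genes_b) {
  u <- intersect(unique(toupper(genes_a)), unique(toupper(genes_b)))
  if (length(u) == 0) abort("the two gene lists share no symbols")
  sort(u)
}

#' Fisher exact overlap of two gene sets on a shared universe
#'
#' Builds the 2x2 contingency table of membership (both sets restricted to
#' the universe) and performs a two-sided Fisher exact test, reporting the
#' conditional-MLE odds ratio with its exact 95% CI.
#'
#' @param set_a,set_b character gene sets.
#' @param universe character universe containing both sets.
#' @return a tibble: `universe_size`, `size_a`, `size_b`, `intersection`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) abort("empty universe")
  a <- unique(toupper(set_a)); b <- unique(toupper(set_b))
  if (!all(a %in% universe) || !all(b %in% universe)) {
    warn("genes outside the universe are dropped from the overlap test")
    a <- intersect(a, universe); b <- intersect(b, universe)
  }
  n11 <- length(intersect(a, b))
  n10 <- length(a) - n11
  n01 <- length(b) - n11
  n00 <- length(universe) - n11 - n10 - n01
  ft <- fisher.test(matrix(c(n11, n10, n01, n00), 2, 2))
  tibble(
    universe_size = length(universe),
    size_a = length(a), size_b = length(b), intersection = n11,
    odds_ratio = unname(ft$estimate),
    ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
    p_value = ft$p.value
  )
}
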