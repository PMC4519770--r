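#' Enumerate the admissible three-node causal networks
#'
#' Over the nodes treatment (T), gene (G) and Adarb1 (A), the treatment is
#' parentless (it is the experimental intervention), T may or may not point
#' at G, T may or may not point at A, and G and A may be unlinked or linked
#' in either direction: 2 x 2 x 3 = 12 admissible DAGs, returned in a fixed
#' canonical order.
#'
#' @return tibble with one row per DAG: `dag_id`, `t_gene`, `t_adarb1`
#'   (logical edge indicators for T->G and T->A), `gene_adarb1` (`"none"`,
#'   `"gene->adarb1"` or `"adarb1->gene"`), `label` (human-readable edge
#'   list).
#' @export
enumerate_dags <- function() {
  grid <- tidyr::expand_grid(
    t_gene = c(FALSE, TRUE),
    t_adarb1 = c(FALSE, TRUE),
    gene_adarb1 = c("none", "gene->adarb1", "adarb1->gene")
  )
  grid |>
    mutate(
      dag_id = seq_len(nrow(grid)),
      label = pmap_chr_edges(.data$t_gene, .data$t_adarb1, .data$gene_adarb1)
    ) |>
    select("dag_id", "t_gene", "t_adarb1", "gene_adarb1", "label")
}

pmap_chr_edges <- function(t_gene, t_adarb1, gene_adarb1) {
  mapply(function(tg, ta, ga) {
    e <- c(if (tg) "T->G", if (ta) "T->A",
           switch(ga, none = NULL, `gene->adarb1` = "G->A", `adarb1->gene` = "A->G"))
    if (length(e) == 0) "(empty)" else paste(e, collapse = ", ")
  }, t_gene, t_adarb1, gene_adarb1, USE.NAMES = FALSE)
}

# log multivariate gamma
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# Log marginal likelihood of a data block under a conjugate
# normal-inverse-Wishart prior centered on supplied moments.
# The prior family is subset-consistent (kappa0 shared, nu0 = q + 1 + kappa0,
# Lambda0 = kappa0 * diag(v0)), so family-ratio node scores are
# score-equivalent across Markov-equivalent DAGs by construction.
log_m_niw <- function(Y, mu0, v0, kappa0) {
  Y <- as.matrix(Y)
  n <- nrow(Y); q <- ncol(Y)
  if (q == 0 || n == 0) return(0)
  v0 <- pmax(v0, 1e-10)
  nu0 <- q + 1 + kappa0
  lambda0 <- kappa0 * diag(v0, q)
  kn <- kappa0 + n
  nun <- nu0 + n
  ybar <- colMeans(Y)
  S <- crossprod(sweep(Y, 2, ybar))
  d <- ybar - mu0
  lambdan <- lambda0 + S + (kappa0 * n / kn) * tcrossprod(d)
  ld0 <- determinant(lambda0, logarithm = TRUE)$modulus
  ldn <- determinant(lambdan, logarithm = TRUE)$modulus
  as.numeric(
    -(n * q / 2) * log(pi) + (q / 2) * (log(kappa0) - log(kn)) +
      (nu0 / 2) * ld0 - (nun / 2) * ldn +
      lmvgamma(nun / 2, q) - lmvgamma(nu0 / 2, q)
  )
}

# Per-gene building blocks for the 12 DAG scores. `X` is an n x 2 matrix with
# columns gene, adarb1; `strata` is the list of per-level sample indices.
dag_score_terms <- function(X, strata, kappa0) {
  mu0 <- colMeans(X)
  v0 <- apply(X, 2, var)
  ms <- function(vars, idx) log_m_niw(X[idx, vars, drop = FALSE],
                                      mu0[vars], v0[vars], kappa0)
  all_idx <- seq_len(nrow(X))
  strat <- function(vars) sum(vapply(strata, function(i) ms(vars, i), numeric(1)))
  list(
    g_pool = ms(1, all_idx), a_pool = ms(2, all_idx), ga_pool = ms(1:2, all_idx),
    g_strat = strat(1), a_strat = strat(2), ga_strat = strat(1:2)
  )
}

# Assemble the 12 scores from the term list plus the treatment-node score.
dag_scores_from_terms <- function(tm, l_t, dags = enumerate_dags()) {
  g_node <- function(tg, ga) {
    if (ga == "adarb1->gene") {
      if (tg) tm$ga_strat - tm$a_strat else tm$ga_pool - tm$a_pool
    } else {
      if (tg) tm$g_strat else tm$g_pool
    }
  }
  a_node <- function(ta, ga) {
    if (ga == "gene->adarb1") {
      if (ta) tm$ga_strat - tm$g_strat else tm$ga_pool - tm$g_pool
    } else {
      if (ta) tm$a_strat else tm$a_pool
    }
  }
  vapply(seq_len(nrow(dags)), function(i) {
    l_t + g_node(dags$t_gene[i], dags$gene_adarb1[i]) +
      a_node(dags$t_adarb1[i], dags$gene_adarb1[i])
  }, numeric(1))
}

#' Score one candidate network
#'
#' Log marginal likelihood of a three-node DAG under a conditional-Gaussian
#' Bayesian model: the binary treatment node gets a Beta(1,1)-Bernoulli
#' marginal; each continuous node given its parents gets a conjugate
#' normal-inverse-Wishart marginal (empirical-Bayes prior centered on the
#' data moments, `prior_strength` pseudo-observations), stratified by
#' treatment where T is a parent. The score factorizes over nodes, and
#' Markov-equivalent DAGs score identically, so edge direction between gene
#' and Adarb1 is only resolved through treatment-induced asymmetry.
#'
#' @param dag one row of [enumerate_dags()].
#' @param treatment two-level factor (or binary) per sample.
#' @param gene,adarb1 numeric per-sample values (normalized expression;
#'   log-scale qPCR).
#' @param prior_strength pseudo-observation count of the prior (default 1).
#' @return log marginal likelihood (numeric scalar).
#' @export
score_network <- function(dag, treatment, gene, adarb1, prior_strength = 1) {
  treatment <- droplevels(as.factor(treatment))
  n <- length(treatment)
  if (length(gene) != n || length(adarb1) != n) {
    abort("treatment, gene and adarb1 must have equal length")
  }
  if (nlevels(treatment) != 2) abort("both treatment levels must be present")
  strata <- split(seq_len(n), treatment)
  if ((dag$t_gene || dag$t_adarb1) && any(lengths(strata) < 3)) {
    abort("need >= 3 samples per treatment level when T parents a continuous node")
  }
  X <- cbind(gene = gene, adarb1 = adarb1)
  if (any(apply(X, 2, var) < 1e-10)) {
    warn("a continuous node is (near-)constant; its variance is floored")
  }
  tab <- table(treatment)
  l_t <- lbeta(1 + tab[1], 1 + tab[2]) - lbeta(1, 1)
  tm <- dag_score_terms(X, strata, prior_strength)
  dags1 <- tibble(t_gene = dag$t_gene, t_adarb1 = dag$t_adarb1,
                  gene_adarb1 = dag$gene_adarb1)
  dag_scores_from_terms(tm, as.numeric(l_t), dags1)
}

#' Score all 12 networks for one gene
#'
#' @inheritParams score_network
#' @return tibble of the 12 DAGs with a `log_score` column, in canonical
#'   order.
#' @export
score_all_networks <- function(treatment, gene, adarb1, prior_strength = 1) {
  dags <- enumerate_dags()
  treatment <- droplevels(as.factor(treatment))
  if (nlevels(treatment) != 2) abort("both treatment levels must be present")
  strata <- split(seq_along(treatment), treatment)
  if (any(lengths(strata) < 3)) {
    abort("need >= 3 samples per treatment level")
  }
  X <- cbind(gene = gene, adarb1 = adarb1)
  tab <- table(treatment)
  l_t <- as.numeric(lbeta(1 + tab[1], 1 + tab[2]) - lbeta(1, 1))
  tm <- dag_score_terms(X, strata, prior_strength)
  dags$log_score <- dag_scores_from_terms(tm, l_t, dags)
  dags
}

#' Classify a gene from its network scores
#'
#' Ranks the 12 scores (ties broken by canonical DAG order) and applies the
#' four-way rule: if the runner-up's relative score
#' `exp(log_score_2 - log_score_1)` exceeds `ambiguity` the gene is
#' `ambiguous`; otherwise `upstream` if the top DAG has a gene->Adarb1 edge,
#' `downstream` if it has an Adarb1->gene edge, and `independent` otherwise.
#'
#' @param scores tibble from [score_all_networks()] (needs `dag_id`,
#'   `gene_adarb1`, `label`, `log_score`).
#' @param ambiguity relative-score threshold (default 0.9, on the likelihood
#'   scale, not the log scale).
#' @return one-row tibble: `category`, `top_dag`, `log_score`,
#'   `relative_score`.
#' @export
classify_gene <- function(scores, ambiguity = 0.9) {
  if (nrow(scores) != 12) abort("expected scores for all 12 candidate DAGs")
  ord <- order(-scores$log_score, scores$dag_id)
  top <- scores[ord[1], ]
  rel <- exp(scores$log_score[ord[2]] - scores$log_score[ord[1]])
  category <- if (rel > ambiguity) {
    "ambiguous"
  } else if (top$gene_adarb1 == "gene->adarb1") {
    "upstream"
  } else if (top$gene_adarb1 == "adarb1->gene") {
    "downstream"
  } else {
    "independent"
  }
  tibble(category = category, top_dag = top$label,
         log_score = top$log_score, relative_score = rel)
}

#' Classify every gene relative to Adarb1
#'
#' Runs the three-node network procedure gene by gene: normalized expression
#' of the gene, the per-sample Adarb1 qPCR value (log2-transformed) and the
#' treatment label are scored under the 12 admissible DAGs and the gene is
#' classified as upstream, downstream, independent or ambiguous.
#'
#' @param study an [expression_study()] whose metadata includes
#'   `adarb1_qpcr`.
#' @param genes genes to classify (default: all rows of the normalized
#'   matrix).
#' @param prior_strength prior pseudo-observations (default 1).
#' @param ambiguity relative-score threshold (default 0.9).
#' @return a `bna_result` tibble: `gene`, `category`, `top_dag`,
#'   `log_score`, `relative_score`; `glance()` gives the category tallies.
#' @export
classify_all <- function(study, genes = NULL, prior_strength = 1,
                         ambiguity = 0.9) {
  stopifnot(inherits(study, "expression_study"))
  if (!"adarb1_qpcr" %in% names(study$metadata) ||
      anyNA(study$metadata$adarb1_qpcr)) {
    abort("study metadata must provide `adarb1_qpcr` for every sample")
  }
  if (is.null(study$normalized)) study <- normalize_study(study)
  genes <- genes %||% rownames(study$normalized)
  treatment <- droplevels(study$metadata$group)
  adarb1 <- log2(study$metadata$adarb1_qpcr)
  strata <- split(seq_along(treatment), treatment)
  if (any(lengths(strata) < 3)) abort("need >= 3 samples per treatment level")
  dags <- enumerate_dags()
  tab <- table(treatment)
  l_t <- as.numeric(lbeta(1 + tab[1], 1 + tab[2]) - lbeta(1, 1))
  res <- purrr::map_dfr(genes, function(g) {
    tm <- dag_score_terms(cbind(gene = study$normalized[g, ], adarb1 = adarb1),
                          strata, prior_strength)
    dags$log_score <- dag_scores_from_terms(tm, l_t, dags)
    classify_gene(dags, ambiguity) |> mutate(gene = g, .before = 1)
  })
  class(res) <- c("bna_result", class(res))
  attr(res, "ambiguity") <- ambiguity
  res
}

#' @method glance bna_result
#' @export
glance.bna_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    upstream = sum(x$category == "upstream"),
    downstream = sum(x$category == "downstream"),
    independent = sum(x$category == "independent"),
    ambiguous = sum(x$category == "ambiguous"),
    ambiguity = attr(x, "ambiguity") %||% 0.9
  )
}

#' Intersect a classification with a trait signature
#'
#' Restricts the upstream and downstream genes to those whose expression is
#' significantly correlated with the trait, split by correlation sign.
#'
#' @param classification a `bna_result` from [classify_all()].
#' @param signature a `trait_signature` from [correlate_trait()].
#' @return named list of four character vectors: `upstream_positive`,
#'   `upstream_negative`, `downstream_positive`, `downstream_negative`.
#' @export
intersect_with_signature <- function(classification, signature) {
  sets <- signature_sets(signature)
  pick <- function(cat, sgn) {
    intersect(classification$gene[classification$category == cat], sets[[sgn]])
  }
  list(
    upstream_positive = pick("upstream", "positive"),
    upstream_negative = pick("upstream", "negative"),
    downstream_positive = pick("downstream", "positive"),
    downstream_negative = pick("downstream", "negative")
  )
}
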