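#' WGCNA palette used for module colors, largest module first.
module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
    "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
    "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white")
}

#' Choose the soft-threshold power
#'
#' Raises absolute Pearson correlations to each candidate power beta and
#' measures how close the resulting weighted network is to scale-free: node
#' connectivities k are binned, and R^2 of the linear fit of log10 p(k) on
#' log10 k is reported. The chosen beta is the smallest one reaching
#' `r2_target` (default 0.8), falling back to the best-fitting candidate.
#'
#' @param expr genes-by-samples numeric matrix (>= 30 genes), or a
#'   pre-computed gene correlation matrix (detected by symmetry).
#' @param candidate_betas candidate powers.
#' @param n_bins connectivity bins for the degree distribution.
#' @param r2_target scale-free fit target.
#' @return list with `beta` (chosen power) and `fit` (tibble: `beta`, `r2`,
#'   `slope`, `mean_k`).
#' @export
pick_beta <- function(expr, candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                      n_bins = 10, r2_target = 0.8) {
  cm <- as_cor_matrix(expr, min_genes = 30)
  a0 <- abs(cm); diag(a0) <- 0
  if (all(a0 == 0)) abort("all correlations are zero; no network to fit")
  fit <- purrr::map_dfr(candidate_betas, function(b) {
    k <- rowSums(a0^b)
    sf <- scale_free_fit(k, n_bins)
    tibble(beta = b, r2 = sf$r2, slope = sf$slope, mean_k = mean(k))
  })
  ok <- fit$beta[fit$r2 >= r2_target]
  beta <- if (length(ok)) min(ok) else fit$beta[which.max(fit$r2)]
  list(beta = beta, fit = fit)
}

# R^2 of log10 p(k) ~ log10 k over equal-width connectivity bins.
scale_free_fit <- function(k, n_bins = 10) {
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0 & !is.na(mk) & mk > 0
  if (sum(keep) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  f <- lm(log10(pk[keep]) ~ log10(mk[keep]))
  list(r2 = summary(f)$r.squared, slope = unname(coef(f)[2]))
}

as_cor_matrix <- function(expr, min_genes = 2) {
  m <- if (is.data.frame(expr)) as_count_matrix(expr) else expr
  is_cor <- nrow(m) == ncol(m) && isTRUE(all.equal(unname(m), unname(t(m)))) &&
    all(abs(m) <= 1 + 1e-12)
  cm <- if (is_cor) m else stats::cor(t(m))
  if (nrow(cm) < min_genes) {
    abort(sprintf("need at least %d genes", min_genes))
  }
  cm
}

#' Topological overlap matrix
#'
#' Transforms an adjacency matrix into the (unsigned) topological overlap
#' matrix: `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' which credits gene pairs for shared network neighbors as well as direct
#' adjacency. The diagonal is set to 1; `1 - TOM` is the clustering
#' dissimilarity.
#'
#' @param adjacency symmetric matrix with entries in `[0, 1]`.
#' @return symmetric TOM matrix with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isTRUE(all.equal(unname(a), unname(t(a))))) {
    abort("adjacency must be symmetric")
  }
  if (any(a < 0 | a > 1)) abort("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height (default 0.99 of the maximum merge height). Branches smaller than
#' `min_module_size`, and branches whose mean within-branch topological
#' overlap falls below `min_module_tom` (poorly connected genes), are sent
#' to the grey (unassigned) module. Surviving modules are colored by
#' decreasing size following the WGCNA convention (turquoise, blue,
#' brown, ...).
#'
#' @param tom TOM matrix from [topological_overlap()] (gene dimnames used).
#' @param min_module_size smallest reportable module (default 20).
#' @param cut_height tree-cut height; `NULL` for 0.99 x max merge height.
#' @param min_module_tom minimum mean within-module TOM for a branch to
#'   count as a module (default 0.1); below it genes are unconnected noise.
#' @return tibble `gene`, `module` (color label; `"grey"` = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_height = NULL,
                           min_module_tom = 0.1) {
  genes <- rownames(tom) %||% sprintf("g%03d", seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size) {
    return(tibble(gene = genes, module = "grey"))
  }
  h <- hclust(as.dist(1 - tom), method = "average")
  cut_height <- cut_height %||% (0.99 * max(h$height))
  cl <- cutree(h, h = cut_height)
  sizes <- table(cl)
  cohesive <- vapply(names(sizes), function(id) {
    idx <- which(cl == id)
    if (length(idx) < 2) return(0)
    sub <- tom[idx, idx]
    mean(sub[lower.tri(sub)])
  }, numeric(1))
  big <- names(sizes)[sizes >= min_module_size & cohesive >= min_module_tom]
  # deterministic color order: by decreasing size, ties by first gene index
  first_idx <- vapply(big, function(id) min(which(cl == id)), integer(1))
  big <- big[order(-sizes[big], first_idx)]
  cols <- setNames(rep("grey", length(sizes)), names(sizes))
  cols[big] <- module_colors()[seq_along(big)]
  tibble(gene = genes, module = unname(cols[as.character(cl)]))
}

#' Build a weighted co-expression network
#'
#' Convenience wrapper running [pick_beta()], adjacency, topological overlap
#' and [detect_modules()] on a set of genes (typically the DE genes).
#'
#' @param expr genes-by-samples matrix of normalized values.
#' @param candidate_betas passed to [pick_beta()].
#' @param min_module_size passed to [detect_modules()].
#' @param cut_height passed to [detect_modules()].
#' @return an object of class `coexpression_network`: `beta`, `fit`,
#'   `adjacency`, `tom`, `modules` (tibble).
#' @export
coexpression_network <- function(expr, candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                                 min_module_size = 20, cut_height = NULL) {
  cm <- as_cor_matrix(expr, min_genes = 30)
  pb <- pick_beta(cm, candidate_betas)
  adj <- abs(cm)^pb$beta
  tom <- topological_overlap(adj)
  mods <- detect_modules(tom, min_module_size, cut_height)
  structure(
    list(beta = pb$beta, fit = pb$fit, adjacency = adj, tom = tom,
         modules = mods),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("<coexpression_network> ", nrow(x$tom), " genes, beta = ", x$beta, "\n",
      sep = "")
  print(table(x$modules$module))
  invisible(x)
}

#' @method tidy coexpression_network
#' @export
tidy.coexpression_network <- function(x, ...) x$modules

#' @method glance coexpression_network
#' @export
glance.coexpression_network <- function(x, ...) {
  nm <- setdiff(unique(x$modules$module), "grey")
  tibble(
    n_genes = nrow(x$modules), beta = x$beta,
    n_modules = length(nm),
    n_grey = sum(x$modules$module == "grey"),
    scale_free_r2 = x$fit$r2[x$fit$beta == x$beta]
  )
}

#' Hypergeometric module enrichment
#'
#' One-sided hypergeometric upper-tail test of the overlap between each
#' module and each gene set, Bonferroni-corrected over all module-set pairs.
#' Grey (unassigned) genes are not tested as a module; empty modules are
#' skipped with a message.
#'
#' @param modules tibble `gene`, `module` (from [detect_modules()]).
#' @param gene_sets named list of character gene sets (subsets of the
#'   universe).
#' @param universe character vector of testable genes.
#' @return tibble `module`, `set`, `module_size`, `set_size`, `overlap`,
#'   `p_value`, `p_bonferroni`.
#' @export
module_enrichment <- function(modules, gene_sets, universe) {
  if (is.null(names(gene_sets))) abort("gene_sets must be a named list")
  universe <- unique(universe)
  bad <- names(gene_sets)[!vapply(gene_sets, function(s) all(s %in% universe), logical(1))]
  if (length(bad)) {
    abort(sprintf("gene set(s) not contained in the universe: %s",
                  paste(bad, collapse = ", ")))
  }
  mods <- setdiff(unique(modules$module), "grey")
  rows <- list()
  for (mo in mods) {
    mg <- intersect(modules$gene[modules$module == mo], universe)
    if (length(mg) == 0) {
      message("module ", mo, " has no genes in the universe; skipped")
      next
    }
    for (se in names(gene_sets)) {
      s <- unique(gene_sets[[se]])
      ov <- length(intersect(mg, s))
      p <- phyper(ov - 1, length(s), length(universe) - length(s),
                  length(mg), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        module = mo, set = se, module_size = length(mg),
        set_size = length(s), overlap = ov, p_value = p
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out)) out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
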