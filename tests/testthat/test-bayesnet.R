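test_that("exactly the 12 admissible DAGs are enumerated, all acyclic", {
  dags <- enumerate_dags()
  expect_equal(nrow(dags), 12)
  expect_equal(nrow(dplyr::distinct(dags[, c("t_gene", "t_adarb1", "gene_adarb1")])),
               12)
  expect_equal(sum(!dags$t_adarb1), 6)   # dropping the T->A factor halves the set
  # independent cycle check: T is parentless, so the only possible cycle is
  # G<->A, excluded by construction
  for (i in seq_len(12)) {
    edges <- c(dags$gene_adarb1[i])
    expect_false(all(c("gene->adarb1", "adarb1->gene") %in% edges))
  }
})

test_that("Markov-equivalent DAGs score identically on pure Gaussian data", {
  set.seed(51)
  trt <- factor(rep(c("a", "b"), each = 15))
  for (rep in 1:5) {
    g <- rnorm(30)
    a <- 0.5 * g + rnorm(30)
    sc <- score_all_networks(trt, g, a)
    # no treatment edges: G->A vs A->G
    free <- sc[!sc$t_gene & !sc$t_adarb1 & sc$gene_adarb1 != "none", ]
    expect_lt(abs(diff(free$log_score)), 1e-8)
    # fully shielded triple: T->G,T->A,G->A vs T->G,T->A,A->G
    full <- sc[sc$t_gene & sc$t_adarb1 & sc$gene_adarb1 != "none", ]
    expect_lt(abs(diff(full$log_score)), 1e-8)
  }
})

test_that("the empty DAG score is the sum of the marginal node scores", {
  set.seed(3)
  trt <- factor(rep(c("a", "b"), each = 10))
  g <- rnorm(20); a <- rnorm(20)
  dags <- enumerate_dags()
  empty <- dags[!dags$t_gene & !dags$t_adarb1 & dags$gene_adarb1 == "none", ]
  total <- score_network(empty, trt, g, a)
  l_t <- lbeta(11, 11) - lbeta(1, 1)
  mu <- c(mean(g), mean(a)); v <- c(var(g), var(a))
  m_g <- editnet:::log_m_niw(cbind(g), mu[1], v[1], 1)
  m_a <- editnet:::log_m_niw(cbind(a), mu[2], v[2], 1)
  expect_equal(total, as.numeric(l_t) + m_g + m_a, tolerance = 1e-10)
})

test_that("scores are invariant to sample order and to affine rescaling", {
  set.seed(7)
  trt <- factor(rep(c("a", "b"), each = 20))
  g <- rnorm(40) + (trt == "b"); a <- 0.7 * g + rnorm(40)
  sc <- score_all_networks(trt, g, a)
  perm <- sample(40)
  sc_perm <- score_all_networks(trt[perm], g[perm], a[perm])
  expect_equal(sc$log_score, sc_perm$log_score, tolerance = 1e-9)
  # affine rescaling shifts all scores by a common constant (Jacobian):
  # score differences, hence classification, are invariant
  sc_scaled <- score_all_networks(trt, 10 * g + 3, a)
  d <- sc_scaled$log_score - sc$log_score
  expect_lt(diff(range(d)), 1e-8)
  expect_equal(classify_gene(sc_scaled)$category, classify_gene(sc)$category)
})

test_that("the generating chain DAG wins on data simulated from it", {
  set.seed(61)
  wins <- replicate(10, {
    t <- rep(c(0, 1), each = 100)
    g <- 1.5 * t + rnorm(200)
    a <- 0.9 * g + rnorm(200, sd = 0.6)
    sc <- score_all_networks(factor(t), g, a)
    sc$label[which.max(sc$log_score)]
  })
  expect_gt(mean(wins == "T->G, G->A"), 0.5)
})

test_that("classification follows the four-way rule on any score vector", {
  dags <- enumerate_dags()
  rule_oracle <- function(scores, ambiguity = 0.9) {
    o <- order(-scores, seq_along(scores))
    if (exp(scores[o[2]] - scores[o[1]]) > ambiguity) return("ambiguous")
    switch(dags$gene_adarb1[o[1]],
           `gene->adarb1` = "upstream",
           `adarb1->gene` = "downstream",
           none = "independent")
  }
  set.seed(71)
  for (i in 1:200) {
    s <- rnorm(12, sd = sample(c(0.01, 0.1, 1, 10), 1))
    dd <- dags; dd$log_score <- s
    expect_equal(classify_gene(dd)$category, rule_oracle(s))
  }
  # exact tie at the top is ambiguous
  dd <- dags; dd$log_score <- c(rep(0, 2), seq(-1, -10, length.out = 10))
  expect_equal(classify_gene(dd)$category, "ambiguous")
  expect_equal(classify_gene(dd)$relative_score, 1)
  # clear upstream and independent cases
  dd$log_score <- rep(-10, 12)
  dd$log_score[dd$gene_adarb1 == "gene->adarb1" & dd$t_gene & !dd$t_adarb1] <- 0
  res <- classify_gene(dd)
  expect_equal(res$category, "upstream")
  dd$log_score <- rep(-10, 12)
  dd$log_score[dd$gene_adarb1 == "none" & !dd$t_gene & !dd$t_adarb1] <- 0
  expect_equal(classify_gene(dd)$category, "independent")
})

test_that("planted causal categories are recovered well above chance", {
  runs <- lapply(1:3, function(s) {
    st <- sim_expression_study(
      n_genes = 120, n_per_group = 100,
      upstream_genes = sprintf("g%04d", 1:4),
      downstream_genes = sprintf("g%04d", 5:24),
      seed = s
    )
    cls <- classify_all(st)
    tr <- st$truth
    list(up = cls$category[match(tr$upstream, cls$gene)],
         dn = cls$category[match(tr$downstream, cls$gene)])
  })
  up <- unlist(lapply(runs, `[[`, "up"))
  dn <- unlist(lapply(runs, `[[`, "dn"))
  expect_gt(mean(up == "upstream"), 0.6)
  expect_gt(mean(dn == "downstream"), 0.8)
  # upstream/downstream confusion below the four-way chance level
  expect_lt(mean(up == "downstream"), 0.25)
  expect_lt(mean(dn == "upstream"), 0.25)
  # planted-category accuracy far above 25% chance
  acc <- mean(c(up == "upstream", dn == "downstream"))
  expect_gt(acc, 0.5)
})

test_that("permuting the hub values destroys directional calls", {
  st <- sim_expression_study(
    n_genes = 60, n_per_group = 50,
    upstream_genes = sprintf("g%04d", 1:4),
    downstream_genes = sprintf("g%04d", 5:14),
    seed = 23
  )
  cls <- classify_all(st)
  directional <- sum(cls$category %in% c("upstream", "downstream"))
  set.seed(1)
  st_perm <- st
  st_perm$metadata$adarb1_qpcr <- sample(st$metadata$adarb1_qpcr)
  cls_perm <- classify_all(st_perm)
  directional_perm <- sum(cls_perm$category %in% c("upstream", "downstream"))
  expect_lt(directional_perm, directional / 2)
  expect_equal(mean(cls_perm$category[match(st$truth$downstream, cls_perm$gene)]
                    == "downstream"), 0, tolerance = 0.15)
})

test_that("classification intersects with signatures by category and sign", {
  cls <- tibble::tibble(
    gene = sprintf("g%02d", 1:8),
    category = c("upstream", "upstream", "downstream", "downstream",
                 "independent", "ambiguous", "upstream", "downstream")
  )
  sig <- tibble::tibble(
    gene = sprintf("g%02d", 1:8),
    rho = c(0.9, -0.8, 0.7, -0.6, 0.9, 0.9, 0, 0.5),
    p_value = 0.001, p_adjusted = 0.01,
    sign = c("positive", "negative", "positive", "negative", "positive",
             "positive", "none", "none")
  )
  class(sig) <- c("trait_signature", class(sig))
  sets <- intersect_with_signature(cls, sig)
  expect_equal(sets$upstream_positive, "g01")
  expect_equal(sets$upstream_negative, "g02")
  expect_equal(sets$downstream_positive, "g03")
  expect_equal(sets$downstream_negative, "g04")

  empty_sig <- sig; empty_sig$sign <- "none"
  sets0 <- intersect_with_signature(cls, empty_sig)
  expect_true(all(lengths(sets0) == 0))
})

test_that("classify_all requires hub metadata and balanced strata", {
  st <- sim_expression_study(n_genes = 20, n_per_group = 4, seed = 2)
  st$metadata$adarb1_qpcr <- NULL
  expect_error(classify_all(st), "adarb1_qpcr")
  st2 <- sim_expression_study(n_genes = 20, n_per_group = 2, seed = 2)
  expect_error(classify_all(st2), "3 samples")
})
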