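region <- htr2c_region()

test_that("variant calling assigns definitional reads", {
  calls <- call_variants(
    c(region$reference_sequence,
      edited_read(c("A", "B", "C", "D")),
      edited_read(c("A", "B", "D"))),
    region
  )
  expect_equal(calls$variant, c("NONE", "ABCD", "ABD"))
  expect_true(all(calls$status == "assigned"))
})

test_that("non-A/G at a site rejects the read", {
  bad <- region$reference_sequence
  pos <- region$site_offsets[["D"]] + 1L
  substring(bad, pos, pos) <- "T"
  calls <- call_variants(bad, region)
  expect_equal(calls$status, "site_ambiguous")
  expect_true(is.na(calls$variant))
})

test_that("calling is strand-symmetric", {
  reads <- vapply(list("NONE", c("A", "B"), c("A", "B", "C", "D"), "E"),
                  function(s) edited_read(setdiff(s, "NONE")), character(1))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  expect_equal(call_variants(reads, region)$variant,
               call_variants(rc, region)$variant)
})

test_that("mismatches outside sites are capped, inside anchors reject", {
  r <- region$reference_sequence
  # positions inside the aligned window, outside sites and anchors
  substring(r, 26, 26) <- "G"; substring(r, 28, 28) <- "A"  # 2 mismatches: OK
  expect_equal(call_variants(r, region)$status, "assigned")
  substring(r, 30, 30) <- "A"                               # 3rd mismatch
  expect_equal(call_variants(r, region)$status, "too_many_mismatches")
  # corrupting the anchor flank makes the read unanchorable
  r2 <- region$reference_sequence
  substring(r2, region$site_offsets[["A"]] - 3, region$site_offsets[["A"]] - 3) <- "G"
  expect_equal(call_variants(r2, region)$status, "unanchored")
})

test_that("tabulation matches a hand count and zero-fills all 32 variants", {
  reads <- c(rep(edited_read(c("A", "B")), 3),
             rep(edited_read(c("A", "B", "D")), 2),
             rep(region$reference_sequence, 2))
  tab <- tabulate_variants(call_variants(reads, region), region)
  expect_equal(nrow(tab), 32)
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-9)
  f <- setNames(tab$frequency, tab$variant)
  expect_equal(unname(f["AB"]), 3 / 7)
  expect_equal(unname(f["ABD"]), 2 / 7)
  expect_equal(unname(f["NONE"]), 2 / 7)
  expect_equal(sum(f[setdiff(names(f), c("AB", "ABD", "NONE"))]), 0)
})

test_that("tabulation errors on samples without assignable reads", {
  calls <- call_variants("GGGGGGGG", region)
  expect_error(tabulate_variants(calls, region), "no assignable reads")
})

test_that("site efficiencies are the subset sums of variant frequencies", {
  tab <- tibble::tibble(sample = "s", variant = c("NONE"),
                        count = 10L, frequency = 1)
  eff <- site_efficiencies(tab, region)
  expect_equal(eff$efficiency, rep(0, 5))

  tab2 <- tibble::tibble(sample = "s", variant = c("ABCD", "AB"),
                         count = c(5L, 5L), frequency = c(0.5, 0.5))
  eff2 <- setNames(site_efficiencies(tab2, region)$efficiency,
                   site_efficiencies(tab2, region)$site)
  expect_equal(unname(eff2[c("A", "B", "C", "D", "E")]),
               c(1, 1, 0.5, 0.5, 0))

  # random table vs brute-force subset-sum oracle over all 32 variants
  set.seed(7)
  p <- as.numeric(stats::rmultinom(1, 1000, rep(1, 32))) / 1000
  tab3 <- tibble::tibble(sample = "s", variant = enumerate_variants(region),
                         count = 0L, frequency = p)
  eff3 <- site_efficiencies(tab3, region)
  for (s in c("A", "B", "C", "D", "E")) {
    oracle <- sum(p[vapply(tab3$variant, function(v) s %in% variant_sites(v),
                           logical(1))])
    expect_equal(eff3$efficiency[eff3$site == s], oracle, tolerance = 1e-12)
  }
})

test_that("variant PCA matches an eigen-decomposition oracle", {
  set.seed(11)
  n <- 8
  m <- matrix(runif(n * 32), n, 32)
  m <- m / rowSums(m)
  tab <- tibble::tibble(
    sample = rep(sprintf("s%d", 1:n), each = 32),
    variant = rep(enumerate_variants(region), n),
    count = 1L,
    frequency = as.vector(t(m))
  )
  p <- pca_variants(tab)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  # oracle: eigenvectors of the covariance of the centered matrix
  xc <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(xc))
  scores_oracle <- xc %*% eig$vectors
  scores <- as.matrix(p$scores[, paste0("PC", 1:(n - 1))])
  for (j in 1:3) {
    expect_equal(abs(unname(scores[, j])), abs(unname(scores_oracle[, j])),
                 tolerance = 1e-8)
  }
  ev <- eig$values[eig$values > 1e-12]
  expect_equal(unname(p$variance_fraction[1:3]), (ev / sum(ev))[1:3],
               tolerance = 1e-8)
})

test_that("PCA fixes component signs and rejects degenerate input", {
  tab <- tibble::tibble(
    sample = rep(c("a", "b", "c"), each = 32),
    variant = rep(enumerate_variants(region), 3),
    count = 1L, frequency = rep(1 / 32, 96)
  )
  expect_error(pca_variants(tab), "constant")
})

test_that("two samples put all variance on PC1", {
  set.seed(2)
  f1 <- runif(32); f1 <- f1 / sum(f1)
  f2 <- runif(32); f2 <- f2 / sum(f2)
  tab <- tibble::tibble(sample = rep(c("a", "b"), each = 32),
                        variant = rep(enumerate_variants(region), 2),
                        count = 1L, frequency = c(f1, f2))
  p <- pca_variants(tab)
  expect_equal(unname(p$variance_fraction[1]), 1, tolerance = 1e-9)
})

test_that("group comparison uses the exact rank-sum distribution", {
  meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:16),
                         group = rep(c("control", "SCI"), each = 8))
  # complete separation: exact two-sided p = 2 / choose(16, 8)
  vals <- tibble::tibble(
    sample = rep(meta$sample_id, each = 1),
    site = "A",
    efficiency = c(1:8 / 100, 9:16 / 100)
  )
  res <- compare_groups(vals, meta)
  expect_equal(res$p_value, 2 / choose(16, 8), tolerance = 1e-12)

  # identical group values give p = 1
  vals2 <- vals
  vals2$efficiency <- rep(0.5, 16)
  expect_equal(compare_groups(vals2, meta)$p_value, 1)

  expect_error(
    compare_groups(vals, meta[c(1, 9:16), ]),
    "at least 2 samples"
  )
})

test_that("rank-sum p-values are calibrated under label permutation", {
  set.seed(13)
  x <- rnorm(16)
  meta0 <- tibble::tibble(sample_id = sprintf("s%02d", 1:16), group = NA)
  ps <- replicate(200, {
    meta0$group <- sample(rep(c("a", "b"), each = 8))
    vals <- tibble::tibble(sample = meta0$sample_id, site = "A", efficiency = x)
    compare_groups(vals, meta0)$p_value
  })
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.62)
})
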