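region <- htr2c_region()

test_that("degenerate mixtures produce the expected reads", {
  r0 <- sim_amplicon_reads(region, c(NONE = 1), n_reads = 20, seed = 1)
  expect_true(all(r0$sequence == region$reference_sequence))

  r1 <- sim_amplicon_reads(region, c(ABCD = 1), n_reads = 20, seed = 1)
  at <- function(seqs, site) {
    pos <- region$site_offsets[[site]] + 1L
    substring(seqs, pos, pos)
  }
  expect_true(all(at(r1$sequence, "A") == "G"))
  expect_true(all(at(r1$sequence, "B") == "G"))
  expect_true(all(at(r1$sequence, "C") == "G"))
  expect_true(all(at(r1$sequence, "D") == "G"))
  expect_true(all(at(r1$sequence, "E") == "A"))
})

test_that("invalid mixtures and parameters are rejected", {
  expect_error(sim_amplicon_reads(region, c(ABD = 0.6, AB = 0.5), 10), "sum to 1")
  expect_error(sim_amplicon_reads(region, c(XYZ = 1), 10), "labels")
  expect_error(sim_amplicon_reads(region, c(NONE = 1), -1), ">= 0")
  expect_error(sim_amplicon_reads(region, c(NONE = 1), 10,
                                  per_base_error_rate = 0.7), "per_base_error_rate")
})

test_that("read simulation is reproducible and stream-isolated", {
  a <- sim_amplicon_reads(region, c(ABD = 0.5, NONE = 0.5), 200,
                          per_base_error_rate = 0.01, seed = 42)
  b <- sim_amplicon_reads(region, c(ABD = 0.5, NONE = 0.5), 200,
                          per_base_error_rate = 0.01, seed = 42)
  expect_identical(a, b)
  c <- sim_amplicon_reads(region, c(ABD = 0.5, NONE = 0.5), 200,
                          per_base_error_rate = 0.01, seed = 43)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("truth sidecar partitions the reads and matches the mixture", {
  p <- results_mixture(region)
  reads <- sim_amplicon_reads(region, p, n_reads = 20000, seed = 3)
  expect_equal(nrow(reads), 20000)
  tt <- table(factor(reads$variant_truth, levels = names(p)))
  expect_equal(sum(tt), 20000)
  chi <- suppressWarnings(stats::chisq.test(tt, p = p))
  expect_gt(chi$p.value, 1e-4)
})

test_that("tabulated frequencies recover the simulation mixture", {
  p <- results_mixture(region)
  reads <- sim_amplicon_reads(region, p, n_reads = 50000, seed = 8)
  tab <- tabulate_variants(call_variants(reads, region), region)
  f <- setNames(tab$frequency, tab$variant)
  for (v in c("ABD", "ABCD", "AB", "NONE")) {
    se <- sqrt(p[v] * (1 - p[v]) / 50000)
    expect_lt(abs(f[v] - p[v]), 3 * se)
  }
})

test_that("FASTQ round-trips reads", {
  reads <- sim_amplicon_reads(region, c(ABD = 1), 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$read_id, reads$read_id)
})

test_that("null expression study yields no differential expression", {
  st <- sim_expression_study(n_genes = 400, n_per_group = 8, seed = 5)
  de <- differential_expression(st)
  expect_lt(sum(de$de), 0.01 * nrow(de))
})

test_that("an overwhelming planted effect is flagged with correct sign", {
  st <- sim_expression_study(
    n_genes = 200, n_per_group = 50,
    treatment_effects = c(g0007 = 3), seed = 6
  )
  de <- differential_expression(st)
  hit <- de[de$gene == "g0007", ]
  expect_true(hit$de)
  expect_equal(hit$direction, "up")
  expect_gt(hit$fold_change, 4)
})

test_that("expression study validates planted sets and exports the hub twice", {
  expect_error(
    sim_expression_study(n_genes = 100, upstream_genes = "g0001",
                         downstream_genes = "g0001"),
    "disjoint"
  )
  expect_error(
    sim_expression_study(n_genes = 10, upstream_genes = "g0099"),
    "within"
  )
  st <- sim_expression_study(n_genes = 300, n_per_group = 20,
                             upstream_genes = sprintf("g%04d", 1:4), seed = 2)
  expect_true(all(st$counts >= 0))
  expect_true(all(st$counts == round(st$counts)))
  expect_true("Adarb1" %in% rownames(st$counts))
  # qPCR metadata is the hub's log-linked measurement: strongly correlated
  # with the hub count row
  v <- vst_transform(st$counts)
  expect_gt(cor(v["Adarb1", ], log2(st$metadata$adarb1_qpcr)), 0.8)
  # causal sets partition the gene universe
  tr <- st$truth
  expect_equal(sort(c(tr$upstream, tr$downstream, tr$independent)),
               sprintf("g%04d", 1:300))
})

test_that("expression study is byte-reproducible under a fixed seed", {
  a <- sim_expression_study(n_genes = 50, n_per_group = 4, seed = 9)
  b <- sim_expression_study(n_genes = 50, n_per_group = 4, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
})

test_that("digest mixtures interpolate between pure profiles", {
  full <- sim_digest_mixture(1)
  expect_setequal(full$length, c(220, 170))
  none <- sim_digest_mixture(0)
  expect_setequal(none$length, c(220, 51, 119))
  half <- sim_digest_mixture(0.5)
  m <- setNames(half$molar_abundance, half$length)
  expect_equal(unname(m["170"]), unname(m["119"]))
  expect_error(sim_digest_mixture(1.2), "fraction_edited")
})

test_that("the editing estimator closes the loop with the digest simulator", {
  for (f in c(0, 0.1, 0.37, 0.5, 0.9, 1)) {
    expect_equal(estimate_editing(sim_digest_mixture(f)), f, tolerance = 1e-12)
  }
  # approximately unbiased under multiplicative molarity noise
  est <- vapply(1:60, function(s) {
    estimate_editing(sim_digest_mixture(0.6, noise_cv = 0.1, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6), 0.02)
})
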