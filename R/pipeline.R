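#' Default pipeline configuration
#'
#' All stage parameters for an end-to-end synthetic run, with the study
#' thresholds used throughout: DE fold-change gates 1.2 / 0.8 at FDR 0.05,
#' signature FDR 0.1, network ambiguity 0.9. Editing mixtures default to the
#' reported variant spectrum (ABD ~36%, ABCD ~18%, AB ~14%, unedited ~3%)
#' for controls, with the injury group shifted along the ABCD/AB axis.
#'
#' @param seed root seed; every stage derives its own stream from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  n_genes <- 2000
  upstream <- sprintf("g%04d", 1:4)
  downstream <- sprintf("g%04d", 5:44)
  trt_genes <- sprintf("g%04d", 101:220)
  blocks <- list(
    list(genes = sprintf("g%04d", 101:150), cor = 0.7),
    list(genes = sprintf("g%04d", 151:200), cor = 0.7)
  )
  list(
    seed = seed,
    amplicon = list(
      n_reads_per_sample = 5000,
      per_base_error_rate = 0.001,
      control_probs = c(ABD = 0.36, ABCD = 0.18, AB = 0.14, ABC = 0.08,
                        A = 0.06, NONE = 0.03),
      sci_probs = c(ABD = 0.36, ABCD = 0.12, AB = 0.20, ABC = 0.08,
                    A = 0.06, NONE = 0.03)
    ),
    digest = list(control_fraction = 0.8, sci_fraction = 0.6, noise_cv = 0.05),
    expression = list(
      n_genes = n_genes, n_per_group = 8, dispersion = 0.05,
      treatment_effects = setNames(
        rep(c(1.5, -1.5), length.out = length(trt_genes)), trt_genes
      ),
      upstream_genes = upstream, downstream_genes = downstream,
      upstream_coefficients = 0.8, downstream_coefficients = c(0.8, -0.8),
      hub_treatment_effect = -1.8, hub_noise_sd = 0.3, module_blocks = blocks
    ),
    de = list(fc_hi = 1.2, fc_lo = 0.8, fdr = 0.05),
    signature = list(fdr_cut = 0.1),
    wgcna = list(min_module_size = 20, min_de_genes = 30, fallback_top_n = 100),
    bna = list(prior_strength = 1, ambiguity = 0.9)
  )
}

# Fill the remaining probability mass uniformly over unnamed variants.
complete_mixture <- function(named, region = htr2c_region()) {
  labels <- enumerate_variants(region)
  rest <- setdiff(labels, names(named))
  p <- setNames(rep((1 - sum(named)) / length(rest), length(rest)), rest)
  c(named, p)[labels]
}

#' Write a pipeline configuration to YAML
#'
#' Named numeric vectors (variant mixtures, treatment effects) are written
#' as YAML maps so their names survive the round trip.
#'
#' @param config configuration list (see [default_config()]).
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(listify(config), path)
  invisible(path)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in dependency order: synthetic data generation (amplicon reads,
#' expression study, digest profiles), editing quantification (variant
#' tables, site efficiencies, PCA, group comparison), Kv1.1 editing
#' estimation, differential expression, trait signatures (ABCD and Adarb1)
#' with their overlap, co-expression modules on the DE genes, and the
#' per-gene three-node network classification. Writes stage TSV/JSON outputs
#' and a manifest (versions, seed, parameters, checksums) into `out_dir`.
#' Reruns with the same config are byte-identical.
#'
#' @param config configuration list from [default_config()], or the path to
#'   a YAML/JSON file containing one.
#' @param out_dir output directory (created if missing).
#' @return invisible list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- modifyList(default_config(), config)
  # YAML/JSON deserialize named numeric vectors as lists; flatten them back
  for (f in c("control_probs", "sci_probs")) {
    cfg$amplicon[[f]] <- unlist(cfg$amplicon[[f]])
  }
  cfg$expression$treatment_effects <- unlist(cfg$expression$treatment_effects)
  for (f in c("upstream_genes", "downstream_genes")) {
    cfg$expression[[f]] <- unlist(cfg$expression[[f]])
  }
  cfg$expression$module_blocks <- lapply(cfg$expression$module_blocks, function(b) {
    list(genes = unlist(b$genes), cor = b$cor)
  })
  stopifnot(cfg$de$fc_hi > 1, cfg$de$fc_lo < 1, cfg$de$fdr > 0, cfg$de$fdr < 1,
            cfg$signature$fdr_cut > 0, cfg$signature$fdr_cut < 1,
            cfg$bna$ambiguity > 0, cfg$bna$ambiguity <= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  region <- htr2c_region()
  outputs <- character(0)
  emit <- function(x, file) {
    p <- file.path(out_dir, file)
    if (is.data.frame(x)) write_tsv_file(x, p) else
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, p)
    p
  }

  # --- simulate ------------------------------------------------------------
  sim <- stage("synthetic_data", {
    ex <- do.call(sim_expression_study,
                  c(cfg$expression, list(seed = derive_seed(cfg$seed, "expr"))))
    meta <- ex$metadata
    reads <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
      probs <- if (meta$group[i] == "SCI") cfg$amplicon$sci_probs else
        cfg$amplicon$control_probs
      sim_amplicon_reads(region, complete_mixture(probs, region),
                         n_reads = cfg$amplicon$n_reads_per_sample,
                         per_base_error_rate = cfg$amplicon$per_base_error_rate,
                         seed = derive_seed(cfg$seed, paste0("amplicon", i))) |>
        mutate(sample = meta$sample_id[i])
    })
    digests <- purrr::map(seq_len(nrow(meta)), function(i) {
      f <- if (meta$group[i] == "SCI") cfg$digest$sci_fraction else
        cfg$digest$control_fraction
      sim_digest_mixture(f, noise_cv = cfg$digest$noise_cv,
                         seed = derive_seed(cfg$seed, paste0("digest", i)))
    })
    emit(matrix_to_tibble(ex$counts), "counts.tsv")
    emit(meta, "metadata.tsv")
    emit(ex$truth[c("upstream", "downstream", "treatment_effects")], "truth.json")
    list(study = ex, reads = reads, digests = digests)
  })

  # --- editing quantification ----------------------------------------------
  editing <- stage("editing_amplicon", {
    calls <- call_variants(sim$reads, region)
    vt <- tabulate_variants(calls, region)
    se <- site_efficiencies(vt, region)
    pca <- pca_variants(vt, sim$study$metadata)
    cmp_v <- compare_groups(vt, sim$study$metadata)
    cmp_s <- compare_groups(se, sim$study$metadata)
    emit(vt, "variant_table.tsv")
    emit(se, "site_efficiencies.tsv")
    emit(tidy(pca), "pca_scores.tsv")
    emit(cmp_v, "compare_variants.tsv")
    emit(cmp_s, "compare_sites.tsv")
    list(variant_table = vt, site_eff = se, pca = pca)
  })

  kcna1 <- stage("restriction_assay", {
    est <- tibble(
      sample = sim$study$metadata$sample_id,
      editing_fraction = map_dbl(sim$digests, estimate_editing)
    )
    emit(est, "kcna1_editing.tsv")
    est
  })

  # --- differential expression ---------------------------------------------
  de <- stage("expression_de", {
    study <- normalize_study(sim$study)
    de <- differential_expression(study, cfg$de$fc_hi, cfg$de$fc_lo, cfg$de$fdr)
    emit(de, "de_table.tsv")
    list(study = study, de = de)
  })

  # --- trait signatures ----------------------------------------------------
  signatures <- stage("trait_association", {
    abcd <- editing$variant_table |>
      filter(.data$variant == "ABCD") |>
      arrange(match(.data$sample, de$study$metadata$sample_id)) |>
      pull("frequency")
    sig_abcd <- correlate_trait(de$study, abcd, "ABCD",
                                fdr_cut = cfg$signature$fdr_cut)
    sig_adarb1 <- correlate_trait(de$study, log2(de$study$metadata$adarb1_qpcr),
                                  "Adarb1", fdr_cut = cfg$signature$fdr_cut)
    universe <- rownames(de$study$normalized)
    ovl <- bind_rows(
      positive = overlap_test(signature_sets(sig_abcd)$positive,
                              signature_sets(sig_adarb1)$positive, universe),
      negative = overlap_test(signature_sets(sig_abcd)$negative,
                              signature_sets(sig_adarb1)$negative, universe),
      .id = "sign"
    )
    emit(sig_abcd, "signature_abcd.tsv")
    emit(sig_adarb1, "signature_adarb1.tsv")
    emit(ovl, "signature_overlap.tsv")
    list(abcd = sig_abcd, adarb1 = sig_adarb1, overlap = ovl)
  })

  # --- co-expression modules ------------------------------------------------
  wgcna <- stage("coexpression", {
    de_genes <- de$de$gene[de$de$de]
    genes <- if (length(de_genes) >= cfg$wgcna$min_de_genes) de_genes else {
      vv <- apply(de$study$normalized, 1, var)
      names(sort(vv, decreasing = TRUE))[seq_len(cfg$wgcna$fallback_top_n)]
    }
    net <- coexpression_network(de$study$normalized[genes, , drop = FALSE],
                                min_module_size = cfg$wgcna$min_module_size)
    emit(net$modules, "modules.tsv")
    emit(net$fit, "scale_free_fit.tsv")
    net
  })

  # --- Bayesian network classification -------------------------------------
  bna <- stage("bayesnet", {
    cls <- classify_all(de$study, prior_strength = cfg$bna$prior_strength,
                        ambiguity = cfg$bna$ambiguity)
    emit(cls, "bna_classification.tsv")
    emit(as.list(glance(cls)), "bna_tallies.json")
    cls
  })

  manifest <- list(
    package = "editnet",
    version = as.character(utils::packageVersion("editnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = cfg[c("amplicon", "digest", "de", "signature", "wgcna", "bna")],
    files = as.list(setNames(unname(tools::md5sum(outputs)), basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, editing = editing, kcna1 = kcna1, de = de,
                 signatures = signatures, wgcna = wgcna, bna = bna,
                 manifest = manifest))
}
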