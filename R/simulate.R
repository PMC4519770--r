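#' Simulate amplicon sequencing reads over an editing region
#'
#' Draws reads from a multinomial mixture over the region's editing variants
#' and applies uniform per-base substitution errors. Each read is the
#' reference sequence with G substituted at the edited sites of its drawn
#' variant; the drawn variant is recorded as ground truth.
#'
#' @param region an [editing_region()].
#' @param variant_probabilities named numeric vector of mixture weights over
#'   variant labels (unnamed variants have probability 0); must sum to 1
#'   within 1e-9.
#' @param n_reads number of reads to draw.
#' @param per_base_error_rate substitution probability per base, in
#'   `[0, 0.5)`; errors are uniform over the 3 alternative bases (no indels —
#'   this emulates an amplicon assay, not shotgun sequencing).
#' @param read_length read length in nt; defaults to the full reference.
#'   Reads are reference prefixes and must span the outer sites plus anchor
#'   flanks (single-end reads spanning the region are assumed).
#' @param seed integer seed; the generator draws from its own stream derived
#'   from it.
#' @return tibble `read_id`, `sequence`, `variant_truth`.
#' @examples
#' reads <- sim_amplicon_reads(htr2c_region(), c(ABD = 0.5, NONE = 0.5),
#'                             n_reads = 100, seed = 1)
#' @export
sim_amplicon_reads <- function(region = htr2c_region(), variant_probabilities,
                               n_reads, per_base_error_rate = 0,
                               read_length = NULL, seed = 1) {
  labels <- enumerate_variants(region)
  p <- variant_probabilities
  if (is.null(names(p)) || !all(names(p) %in% labels)) {
    abort("variant_probabilities must be named with valid variant labels")
  }
  if (anyDuplicated(names(p))) abort("duplicated variant labels in probabilities")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("variant probabilities must be non-negative and sum to 1 (within 1e-9)")
  }
  if (n_reads < 0) abort("n_reads must be >= 0")
  check_probability(per_base_error_rate, "per_base_error_rate", 0, 0.5 - 1e-12)
  ref <- region$reference_sequence
  read_length <- read_length %||% nchar(ref)
  span_end <- max(region$site_offsets) + region$flank_width + 1L
  if (read_length < span_end) {
    abort("read_length must span the outer editing site plus the anchor flank")
  }

  templates <- vapply(labels, function(v) {
    s <- ref
    for (site in variant_sites(v)) {
      pos <- region$site_offsets[[site]] + 1L
      substring(s, pos, pos) <- "G"
    }
    substring(s, 1L, read_length)
  }, character(1))

  set.seed(derive_seed(seed, "amplicon_reads"))
  drawn <- if (n_reads > 0) {
    sample(names(p), n_reads, replace = TRUE, prob = p)
  } else character(0)
  seqs <- unname(templates[drawn])

  if (per_base_error_rate > 0 && n_reads > 0) {
    bases <- c("A", "C", "G", "T")
    alts <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                  c("A", "C", "T"), c("A", "C", "G"))
    for (j in seq_len(read_length)) {
      hit <- which(runif(n_reads) < per_base_error_rate)
      if (length(hit)) {
        cur <- substring(seqs[hit], j, j)
        new <- alts[cbind(match(cur, bases), sample.int(3L, length(hit), replace = TRUE))]
        substring(seqs[hit], j, j) <- new
      }
    }
  }
  tibble(
    read_id = sprintf("read%07d", seq_len(n_reads)),
    sequence = seqs,
    variant_truth = drawn
  )
}

#' Write / read amplicon reads as FASTQ
#'
#' Sanger (Phred+33) FASTQ with a constant quality of "I" (Q40).
#'
#' @param reads tibble with `read_id` and `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), sequence = unname(as.character(x)))
}

#' Simulate an expression study with planted causal structure
#'
#' Generates a negative-binomial (gamma-Poisson) gene-by-sample count matrix
#' for a two-group design, with planted treatment effects, correlated
#' co-expression blocks, and a causal hub emulating *Adarb1*: upstream genes
#' drive the hub's latent log2 level (linear combination plus Gaussian
#' noise), and each downstream gene's latent mean is a linear function of
#' the hub. The hub is exported both as a count row (`"Adarb1"`) and, through
#' a log link plus noise, as a per-sample simulated qPCR value — mirroring a
#' dual RNA-seq/qPCR measurement.
#'
#' @param n_genes number of background genes (hub row added on top).
#' @param n_per_group samples per group (groups `control` and `SCI`).
#' @param library_size_range range of expected per-sample totals; depth
#'   factors are drawn uniformly from it.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param treatment_effects named numeric vector, gene -> log2 fold change
#'   (SCI vs control).
#' @param upstream_genes,downstream_genes,independent_genes disjoint gene-id
#'   sets defining the planted causal role relative to the hub;
#'   `independent_genes` defaults to all remaining genes.
#' @param upstream_coefficients,downstream_coefficients per-gene linear
#'   effect sizes (recycled if length 1).
#' @param hub_treatment_effect direct log2 fold change of the hub under
#'   treatment (default -1: the editing enzyme is down-regulated after
#'   injury).
#' @param hub_noise_sd SD of the hub's own Gaussian noise (log2 scale).
#' @param module_blocks list of `list(genes = <ids>, cor = <within-block
#'   correlation>)` blocks imposed on the latent log2 scale.
#' @param latent_sd per-gene biological SD on the log2 scale.
#' @param qpcr_noise_sd SD of the measurement noise on the log2 qPCR scale.
#' @param seed integer seed (own stream).
#' @return an [expression_study()] whose `truth` element records every
#'   planted label (causal sets, treatment effects, blocks, hub latent).
#' @export
sim_expression_study <- function(n_genes = 2000, n_per_group = 8,
                                 library_size_range = c(5e5, 1.5e6),
                                 dispersion = 0.05,
                                 treatment_effects = NULL,
                                 upstream_genes = character(0),
                                 downstream_genes = character(0),
                                 independent_genes = NULL,
                                 upstream_coefficients = 0.8,
                                 downstream_coefficients = c(0.8, -0.8),
                                 hub_treatment_effect = -1.8,
                                 hub_noise_sd = 0.3,
                                 module_blocks = list(),
                                 latent_sd = 0.6,
                                 qpcr_noise_sd = 0.2,
                                 seed = 1) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  for (set in list(upstream_genes, downstream_genes, independent_genes,
                   names(treatment_effects))) {
    if (!is.null(set) && !all(set %in% genes)) {
      abort("gene ids must be within 1..n_genes (g0001, g0002, ...)")
    }
  }
  independent_genes <- independent_genes %||%
    setdiff(genes, c(upstream_genes, downstream_genes))
  sets <- list(upstream_genes, downstream_genes, independent_genes)
  if (anyDuplicated(unlist(sets))) {
    abort("upstream, downstream and independent gene sets must be disjoint")
  }
  n_samples <- 2L * n_per_group
  trt <- rep(c(0, 1), each = n_per_group)
  samples <- sprintf("s%02d", seq_len(n_samples))

  set.seed(derive_seed(seed, "expression_study"))
  base <- runif(n_genes, 2, 9)                      # log2 baseline abundance
  names(base) <- genes
  lfc <- setNames(numeric(n_genes), genes)
  if (!is.null(treatment_effects)) lfc[names(treatment_effects)] <- treatment_effects

  eps <- matrix(rnorm(n_genes * n_samples, sd = latent_sd), n_genes, n_samples,
                dimnames = list(genes, samples))
  for (blk in module_blocks) {
    if (!all(blk$genes %in% genes)) abort("module block genes out of range")
    rho <- blk$cor
    f <- rnorm(n_samples)
    eps[blk$genes, ] <- latent_sd *
      (sqrt(rho) * matrix(f, length(blk$genes), n_samples, byrow = TRUE) +
         sqrt(1 - rho) * matrix(rnorm(length(blk$genes) * n_samples),
                                length(blk$genes), n_samples))
  }
  z <- base + outer(lfc, trt) + eps                  # latent log2 expression

  up_w <- rep_len(upstream_coefficients, length(upstream_genes))
  hub_base <- 6
  hub <- hub_base + hub_treatment_effect * trt + rnorm(n_samples, sd = hub_noise_sd)
  if (length(upstream_genes)) {
    hub <- hub + colSums((z[upstream_genes, , drop = FALSE] -
                            base[upstream_genes]) * up_w)
  }
  dn_c <- rep_len(downstream_coefficients, length(downstream_genes))
  if (length(downstream_genes)) {
    z[downstream_genes, ] <- z[downstream_genes, ] +
      outer(dn_c, hub - hub_base - hub_treatment_effect * mean(trt))
  }

  zz <- rbind(z, Adarb1 = hub)
  depth <- runif(n_samples, library_size_range[1], library_size_range[2]) /
    sum(2^c(base, hub_base))
  mu <- sweep(2^zz, 2, depth, `*`)
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / max(dispersion, 1e-8)),
    nrow(mu), ncol(mu), dimnames = list(rownames(zz), samples)
  )
  qpcr <- 2^(hub + rnorm(n_samples, sd = qpcr_noise_sd))
  metadata <- tibble(
    sample_id = samples,
    group = factor(ifelse(trt == 1, "SCI", "control"),
                   levels = c("control", "SCI")),
    adarb1_qpcr = qpcr
  )
  truth <- list(
    upstream = upstream_genes, downstream = downstream_genes,
    independent = independent_genes,
    treatment_effects = lfc[lfc != 0],
    module_blocks = module_blocks,
    hub_log2 = setNames(hub, samples)
  )
  expression_study(counts, metadata, truth = truth)
}

#' Simulate an MfeI digest profile of an edited/unedited amplicon mixture
#'
#' Digests the edited and unedited forms of the Kv1.1 amplicon and mixes
#' their fragment profiles in molar proportion to the edited fraction.
#' Fragments of equal length co-migrate and are aggregated.
#'
#' @param fraction_edited edited fraction of molecules, in `[0, 1]`.
#' @param n_molecules total molar amount distributed over the two forms.
#' @param noise_cv optional coefficient of variation of multiplicative
#'   (mean-1 lognormal) molarity noise; 0 gives a noise-free profile.
#' @param seed integer seed (used only when `noise_cv > 0`).
#' @return a digest profile tibble: `length`, `molar_abundance`.
#' @export
sim_digest_mixture <- function(fraction_edited, n_molecules = 1e4,
                               noise_cv = 0, seed = 1) {
  check_probability(fraction_edited, "fraction_edited")
  profs <- list(
    digest_amplicon(kcna1_amplicon(edited = FALSE)) |>
      mutate(w = (1 - fraction_edited) * n_molecules),
    digest_amplicon(kcna1_amplicon(edited = TRUE)) |>
      mutate(w = fraction_edited * n_molecules)
  )
  out <- bind_rows(profs) |>
    mutate(molar_abundance = .data$molar_abundance * .data$w) |>
    group_by(length = .data$length) |>
    summarise(molar_abundance = sum(.data$molar_abundance), .groups = "drop") |>
    filter(.data$molar_abundance > 0)
  if (noise_cv > 0) {
    set.seed(derive_seed(seed, "digest_mixture"))
    s <- sqrt(log(1 + noise_cv^2))
    out$molar_abundance <- out$molar_abundance *
      exp(rnorm(nrow(out), sd = s) - s^2 / 2)
  }
  out
}
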