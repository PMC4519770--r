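#' Call editing variants from amplicon reads
#'
#' Assigns each read to one of the `2^k` combinatorial editing variants of an
#' editing region. Reads are anchored to the reference by exact match of two
#' flanks (default 8 nt) immediately outside the outermost sites, trying the
#' read as given and then its reverse complement. At each site offset an A is
#' read as unedited and a G as edited; any other base at a site rejects the
#' read, as do more than `max_mismatches` mismatches outside the sites or a
#' failure to anchor.
#'
#' @param reads a character vector of read sequences, or a data frame with a
#'   `sequence` column (extra columns such as `read_id` and `sample` are
#'   carried through).
#' @param region an [editing_region()].
#' @param max_mismatches maximum tolerated non-site mismatches within the
#'   aligned window (default 2).
#' @return a tibble with one row per read: input columns plus `variant`
#'   (label or `NA` when rejected) and `status` (`"assigned"`,
#'   `"unanchored"`, `"site_ambiguous"` or `"too_many_mismatches"`).
#' @export
call_variants <- function(reads, region = htr2c_region(), max_mismatches = 2L) {
  if (is.character(reads)) reads <- tibble(sequence = reads)
  if (!is.data.frame(reads) || !"sequence" %in% names(reads)) {
    abort("reads must be a character vector or data frame with a `sequence` column")
  }
  seqs <- toupper(reads$sequence)
  ref <- region$reference_sequence
  offs <- region$site_offsets
  fw <- region$flank_width
  span <- range(offs)
  win_start <- span[1] - fw + 1L        # 1-based window bounds on the reference
  win_end <- span[2] + fw + 1L
  anchor_up <- substring(ref, win_start, win_start + fw - 1L)
  anchor_dn <- substring(ref, win_end - fw + 1L, win_end)

  ref_win <- substring(ref, win_start, win_end)
  win_len <- nchar(ref_win)
  site_pos_win <- offs - win_start + 2L                     # 1-based within window
  ref_chars <- strsplit(ref_win, "")[[1]]

  # Anchor each read: position of the upstream flank, forward then revcomp.
  anchor <- function(s) {
    p <- regexpr(anchor_up, s, fixed = TRUE)
    ok <- p > 0 & (p + win_len - 1L) <= nchar(s)
    if (any(ok)) {
      dn <- substring(s, p + win_len - fw, p + win_len - 1L)
      ok <- ok & dn == anchor_dn
    }
    ifelse(ok, p, NA_integer_)
  }
  pos_f <- anchor(seqs)
  need_rc <- is.na(pos_f)
  rc <- character(length(seqs))
  if (any(need_rc)) {
    rc[need_rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[need_rc]))
    )
    pos_r <- rep(NA_integer_, length(seqs))
    pos_r[need_rc] <- anchor(rc[need_rc])
  } else {
    pos_r <- rep(NA_integer_, length(seqs))
  }
  oriented <- ifelse(need_rc, rc, seqs)
  pos <- ifelse(need_rc, pos_r, pos_f)

  status <- rep("unanchored", length(seqs))
  variant <- rep(NA_character_, length(seqs))
  ok <- !is.na(pos)
  if (any(ok)) {
    win <- substring(oriented[ok], pos[ok], pos[ok] + win_len - 1L)
    mism <- integer(sum(ok))
    site_base <- matrix("", nrow = sum(ok), ncol = length(offs),
                        dimnames = list(NULL, names(offs)))
    for (j in seq_len(win_len)) {
      bj <- substring(win, j, j)
      si <- match(j, site_pos_win)
      if (!is.na(si)) {
        site_base[, si] <- bj
      } else {
        mism <- mism + (bj != ref_chars[j])
      }
    }
    site_ok <- rowSums(site_base != "A" & site_base != "G") == 0
    mm_ok <- mism <= max_mismatches
    st <- ifelse(!site_ok, "site_ambiguous",
                 ifelse(!mm_ok, "too_many_mismatches", "assigned"))
    status[ok] <- st
    assigned <- which(ok)[st == "assigned"]
    if (length(assigned)) {
      edited <- site_base[st == "assigned", , drop = FALSE] == "G"
      ord <- site_display_order(region)
      lab <- apply(edited[, ord, drop = FALSE], 1, function(e) {
        if (!any(e)) "NONE" else paste(ord[e], collapse = "")
      })
      variant[assigned] <- lab
    }
  }
  reads$variant <- variant
  reads$status <- status
  as_tibble(reads)
}

#' Tabulate the combinatorial variant spectrum
#'
#' Counts assigned reads over all `2^k` variant labels (zero-filled) per
#' sample and converts counts to relative frequencies: the frequency of a
#' variant is the number of reads assigned to it divided by the total number
#' of assigned reads in that sample.
#'
#' @param calls output of [call_variants()]; an optional `sample` column
#'   splits the tabulation per sample (a single implicit sample otherwise).
#' @param region an [editing_region()].
#' @return a tibble with columns `sample`, `variant`, `count`, `frequency`
#'   (2^k rows per sample) and attribute `read_summary`, a tibble of
#'   `n_assigned` / `n_rejected` per sample.
#' @export
tabulate_variants <- function(calls, region = htr2c_region()) {
  if (!"sample" %in% names(calls)) calls$sample <- "sample1"
  labels <- enumerate_variants(region)
  summ <- calls |>
    group_by(sample = .data$sample) |>
    summarise(n_assigned = sum(.data$status == "assigned"),
              n_rejected = sum(.data$status != "assigned"),
              .groups = "drop")
  empty <- summ$sample[summ$n_assigned == 0]
  if (length(empty)) {
    abort(sprintf("no assignable reads in sample(s): %s",
                  paste(empty, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(sample = summ$sample,
                             variant = factor(labels, levels = labels))
  tab <- calls |>
    filter(.data$status == "assigned") |>
    count(sample = .data$sample,
          variant = factor(.data$variant, levels = labels),
          name = "count") |>
    right_join0(grid) |>
    group_by(.data$sample) |>
    mutate(frequency = .data$count / sum(.data$count)) |>
    ungroup() |>
    mutate(variant = as.character(.data$variant)) |>
    arrange(.data$sample)
  attr(tab, "read_summary") <- summ
  tab
}

# right join that zero-fills `count`
right_join0 <- function(x, grid) {
  out <- left_join(grid, x, by = c("sample", "variant"))
  out$count[is.na(out$count)] <- 0L
  out
}

#' Per-site editing efficiencies
#'
#' The editing efficiency of a site is the summed frequency of all variants
#' edited at that site (for five sites, the 16 variants containing it).
#'
#' @param variant_table output of [tabulate_variants()].
#' @param region an [editing_region()].
#' @return a tibble `sample`, `site`, `efficiency`.
#' @export
site_efficiencies <- function(variant_table, region = htr2c_region()) {
  sites <- names(region$site_offsets)
  purrr::map_dfr(sites, function(s) {
    sel <- vapply(variant_table$variant, function(v) s %in% variant_sites(v),
                  logical(1))
    variant_table |>
      mutate(.member = sel) |>
      group_by(.data$sample) |>
      summarise(efficiency = sum(.data$frequency * .data$.member),
                .groups = "drop") |>
      mutate(site = s, .after = "sample")
  }) |>
    arrange(.data$sample, .data$site)
}

#' Principal component analysis of variant spectra
#'
#' Centered (unscaled) PCA of the samples-by-variants frequency matrix. The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive, making scores reproducible across platforms.
#'
#' @param variant_table output of [tabulate_variants()] covering >= 3 samples.
#' @param metadata optional tibble with `sample_id` (or `sample`) and `group`
#'   columns, carried into the scores for plotting.
#' @return an object of class `variant_pca` with elements `scores` (tibble),
#'   `loadings` (matrix), `variance_fraction` (numeric).
#' @export
pca_variants <- function(variant_table, metadata = NULL) {
  wide <- variant_table |>
    select("sample", "variant", "frequency") |>
    tidyr::pivot_wider(names_from = "variant", values_from = "frequency")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample
  if (nrow(m) < 2) abort("PCA needs at least 2 samples")
  if (all(abs(sweep(m, 2, colMeans(m))) < 1e-12)) {
    abort("variant frequencies are constant across samples; PCA undefined")
  }
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  vf <- p$sdev^2 / sum(p$sdev^2)
  scores <- bind_cols(tibble(sample = rownames(m)), as_tibble(p$x))
  if (!is.null(metadata)) {
    meta <- as_tibble(metadata)
    key <- if ("sample_id" %in% names(meta)) "sample_id" else "sample"
    scores <- left_join(scores, rename(meta, sample = all_of(key)), by = "sample")
  }
  structure(
    list(scores = scores, loadings = p$rotation,
         variance_fraction = setNames(vf, colnames(p$x))),
    class = "variant_pca"
  )
}

#' @export
print.variant_pca <- function(x, ...) {
  cat("<variant_pca> ", nrow(x$scores), " samples\n", sep = "")
  vf <- round(100 * x$variance_fraction[seq_len(min(3, length(x$variance_fraction)))], 1)
  cat("  variance explained:", paste(sprintf("%s %.1f%%", names(vf), vf), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy variant_pca
#' @export
tidy.variant_pca <- function(x, ...) x$scores

#' @method glance variant_pca
#' @export
glance.variant_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$variance_fraction),
    pc1_variance = unname(x$variance_fraction[1]),
    pc2_variance = unname(x$variance_fraction[2])
  )
}

#' Compare editing quantities between two groups
#'
#' Two-sided exact Mann-Whitney (Wilcoxon rank-sum) test per variant
#' frequency or per site efficiency, with Benjamini-Hochberg adjustment
#' across the tested quantities. With n = 8 animals per group the exact null
#' distribution over C(16,8) labelings is enumerated by the test.
#'
#' @param values a tibble from [tabulate_variants()] (columns `variant`,
#'   `frequency`) or [site_efficiencies()] (columns `site`, `efficiency`).
#' @param metadata tibble with `sample_id` (or `sample`) and `group`; exactly
#'   two groups, each with >= 2 samples.
#' @return a tibble per quantity: `quantity`, group means, `statistic`
#'   (Mann-Whitney U), `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(values, metadata) {
  qcol <- if ("variant" %in% names(values)) "variant" else if ("site" %in% names(values)) "site" else
    abort("values must come from tabulate_variants() or site_efficiencies()")
  vcol <- if (qcol == "variant") "frequency" else "efficiency"
  meta <- as_tibble(metadata)
  if ("sample_id" %in% names(meta)) meta <- rename(meta, sample = "sample_id")
  dat <- inner_join(values, meta[, c("sample", "group")], by = "sample")
  gl <- sort(unique(as.character(dat$group)))
  if (length(gl) != 2) abort("exactly two groups are required")
  sizes <- dat |> distinct(.data$sample, .data$group) |> count(.data$group)
  if (any(sizes$n < 2)) abort("each group needs at least 2 samples")
  res <- dat |>
    group_by(quantity = .data[[qcol]]) |>
    summarise(
      mean_1 = mean(.data[[vcol]][.data$group == gl[1]]),
      mean_2 = mean(.data[[vcol]][.data$group == gl[2]]),
      statistic = {
        x <- .data[[vcol]][.data$group == gl[1]]
        y <- .data[[vcol]][.data$group == gl[2]]
        suppressWarnings(wilcox.test(x, y, exact = TRUE)$statistic)
      },
      p_value = {
        x <- .data[[vcol]][.data$group == gl[1]]
        y <- .data[[vcol]][.data$group == gl[2]]
        if (all(c(x, y) == c(x, y)[1])) 1 else
          suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
      },
      .groups = "drop"
    ) |>
    mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"))
  names(res)[names(res) == "mean_1"] <- paste0("mean_", gl[1])
  names(res)[names(res) == "mean_2"] <- paste0("mean_", gl[2])
  res
}
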