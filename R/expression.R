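#' Bundle a count matrix with sample metadata
#'
#' @param counts gene-by-sample matrix of non-negative integer counts (gene
#'   rownames), or a data frame with a `gene` column.
#' @param metadata tibble with `sample_id`, `group` (two levels; the first is
#'   the control/reference) and optionally `adarb1_qpcr` (positive reals).
#' @param truth optional list of planted ground truth (from the simulator).
#' @return an object of class `expression_study` with elements `counts`,
#'   `metadata`, `truth` and, once [normalize_study()] has run, `normalized`
#'   and `size_factors`.
#' @export
expression_study <- function(counts, metadata, truth = NULL) {
  counts <- as_count_matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(counts))) {
    warn("duplicated gene ids in counts; filter_genes() can resolve them")
  }
  metadata <- as_tibble(metadata)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort("metadata needs `sample_id` and `group` columns")
  }
  if (!setequal(metadata$sample_id, colnames(counts))) {
    abort("metadata must cover exactly the samples in the count matrix")
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  if (!is.factor(metadata$group)) {
    # reference (first) level: "control" when present, else radix order,
    # independent of the session locale
    lv <- sort(unique(as.character(metadata$group)), method = "radix")
    ctrl <- lv[tolower(lv) %in% c("control", "ctrl", "sham")]
    metadata$group <- factor(metadata$group,
                             levels = c(ctrl, setdiff(lv, ctrl)))
  }
  structure(
    list(counts = counts, metadata = metadata, truth = truth,
         normalized = NULL, size_factors = NULL),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  print(table(x$metadata$group))
  if (!is.null(x$truth)) {
    cat("  planted truth: ", length(x$truth$upstream), " upstream, ",
        length(x$truth$downstream), " downstream genes\n", sep = "")
  }
  invisible(x)
}

#' Filter count rows
#'
#' Drops rows with no reads in any sample. When several rows (transcripts)
#' share a gene symbol, only the one whose normalized signal has the highest
#' standard deviation across samples is retained, so each symbol appears
#' once.
#'
#' @param counts gene-by-sample count matrix or data frame (see
#'   [expression_study()]); row/`gene` names may repeat for multi-transcript
#'   genes.
#' @return a filtered object of the same kind as the input.
#' @export
filter_genes <- function(counts) {
  was_df <- is.data.frame(counts)
  m <- as_count_matrix(counts)
  keep <- rowSums(m) > 0
  if (!any(keep)) abort("no genes left after removing all-zero rows")
  m <- m[keep, , drop = FALSE]
  if (anyDuplicated(rownames(m))) {
    v <- vst_transform(m)
    sds <- apply(v, 1, sd)
    ord <- order(rownames(m), -sds)
    first <- !duplicated(rownames(m)[ord])
    sel <- sort(ord[first])
    m <- m[sel, , drop = FALSE]
  }
  if (was_df) matrix_to_tibble(m) else m
}

#' Median-of-ratios size factors
#'
#' DESeq-style library-size normalization: each sample's factor is the
#' median across genes of its counts divided by the gene-wise geometric mean,
#' computed over genes expressed in every sample, then rescaled to geometric
#' mean 1.
#'
#' @param counts count matrix or data frame.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) abort("no gene is expressed in all samples; cannot normalize")
  lg <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(exp(lg - ref), 2, median)
  sf / geometric_mean(sf)
}

#' Variance-stabilizing transform of counts
#'
#' Monotone log-family surrogate: `log2(count / size_factor + pseudocount)`.
#' On negative-binomial data the transformed per-gene SD is approximately
#' independent of the mean, which is the property downstream correlation and
#' testing steps rely on.
#'
#' @param counts count matrix or data frame.
#' @param sf size factors; computed by [size_factors()] when `NULL`.
#' @param pseudocount added before the log (default 1).
#' @return matrix (or tibble, matching the input) of normalized values.
#' @export
vst_transform <- function(counts, sf = NULL, pseudocount = 1) {
  was_df <- is.data.frame(counts)
  m <- as_count_matrix(counts)
  sf <- sf %||% size_factors(m)
  if (any(sf <= 0)) abort("size factors must be positive")
  v <- log2(sweep(m, 2, sf, `/`) + pseudocount)
  if (was_df) matrix_to_tibble(v) else v
}

#' Attach normalization to a study
#'
#' @param study an [expression_study()].
#' @return the study with `size_factors` and `normalized` filled.
#' @export
normalize_study <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  study$size_factors <- size_factors(study$counts)
  study$normalized <- vst_transform(study$counts, study$size_factors)
  study
}

#' Differential expression with fold-change and FDR gates
#'
#' Per-gene Welch t-test on variance-stabilized values between the two
#' groups, Benjamini-Hochberg adjustment genome-wide, and a double
#' threshold for the DE call: linear fold change (treated vs control, on
#' size-factor-scaled counts) above `fc_hi` or below `fc_lo`, and adjusted
#' p below `fdr`.
#'
#' @param study an [expression_study()] (normalized on the fly if needed).
#' @param fc_hi,fc_lo fold-change gates (defaults 1.2 and 0.8).
#' @param fdr adjusted-p gate (default 0.05).
#' @return a `de_result` tibble: `gene`, `mean_control`, `mean_treated`,
#'   `fold_change`, `log2_fc`, `p_value`, `p_adjusted`, `direction`, `de`.
#' @export
differential_expression <- function(study, fc_hi = 1.2, fc_lo = 0.8,
                                    fdr = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$normalized)) study <- normalize_study(study)
  grp <- study$metadata$group
  if (nlevels(droplevels(grp)) != 2) abort("exactly two groups are required")
  ctrl <- levels(grp)[1]
  is_t <- grp != ctrl
  if (sum(is_t) < 2 || sum(!is_t) < 2) abort("each group needs >= 2 samples")

  v <- study$normalized
  welch <- welch_rows(v[, is_t, drop = FALSE], v[, !is_t, drop = FALSE])
  scaled <- sweep(study$counts, 2, study$size_factors, `/`)
  mean_t <- rowMeans(scaled[, is_t, drop = FALSE])
  mean_c <- rowMeans(scaled[, !is_t, drop = FALSE])
  fc <- mean_t / mean_c
  res <- tibble(
    gene = rownames(v),
    mean_control = unname(mean_c),
    mean_treated = unname(mean_t),
    fold_change = unname(fc),
    log2_fc = unname(log2(fc)),
    p_value = unname(welch$p),
    p_adjusted = unname(p.adjust(welch$p, method = "BH")),
  ) |>
    mutate(
      direction = ifelse(.data$fold_change >= 1, "up", "down"),
      de = (.data$fold_change > fc_hi | .data$fold_change < fc_lo) &
        .data$p_adjusted < fdr
    )
  class(res) <- c("de_result", class(res))
  attr(res, "thresholds") <- c(fc_hi = fc_hi, fc_lo = fc_lo, fdr = fdr)
  res
}

# Row-wise Welch t-test (two-sided); constant identical rows get p = 1.
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(mx[se2 == 0] == my[se2 == 0], 1, 0)
  list(t = t, df = df, p = p)
}

#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_genes = nrow(x), n_de = sum(x$de),
    n_up = sum(x$de & x$direction == "up"),
    n_down = sum(x$de & x$direction == "down"),
    fc_hi = th[["fc_hi"]], fc_lo = th[["fc_lo"]], fdr = th[["fdr"]]
  )
}

#' Normalize qPCR targets to endogenous controls
#'
#' Divides each sample's target value by the geometric mean of its
#' endogenous control genes (three controls in the standard assay).
#'
#' @param target positive numeric vector, one value per sample.
#' @param controls matrix/data frame of positive control values, samples in
#'   rows, one column per control gene.
#' @return numeric vector of normalized target values.
#' @export
qpcr_normalize <- function(target, controls) {
  controls <- as.matrix(controls)
  if (length(target) != nrow(controls)) {
    abort("target and controls must cover the same samples")
  }
  if (any(target <= 0) || any(controls <= 0)) {
    abort("qPCR values must be strictly positive")
  }
  target / exp(rowMeans(log(controls)))
}
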