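#' Define an RNA-editing region
#'
#' An editing region is the coordinate system for all variant calls: a
#' reference amplicon sequence (sense strand, DNA alphabet, inosine read as
#' G), the 0-based offsets of the editing sites within it, and the codon
#' structure of the recoded residues.
#'
#' The 5-HT2CR editing region carries five adenosines (sites A, B, E, C, D in
#' transcript order) within a 15-nt window; sites A and B fall in the
#' residue-156 codon, E and C in the residue-158 codon, and D in the
#' residue-160 codon, so combinatorial editing yields 32 mRNA variants that
#' collapse onto 24 protein isoforms.
#'
#' @param reference_sequence reference amplicon (character, A/C/G/T).
#' @param site_offsets named integer vector of 0-based offsets into
#'   `reference_sequence`; names are site labels in transcript order
#'   (e.g. A, B, E, C, D). The reference base at every offset must be A.
#' @param codon_map named list: residue index -> `list(start = <0-based codon
#'   start>, sites = <site labels inside the codon>)`.
#' @param flank_width width (nt) of the exact-match anchor flanks used to
#'   align reads (default 8).
#' @return an object of class `editing_region`.
#' @seealso [htr2c_region()] for the standard 5-HT2CR fixture.
#' @export
editing_region <- function(reference_sequence, site_offsets, codon_map = list(),
                           flank_width = 8L) {
  reference_sequence <- toupper(reference_sequence)
  stopifnot(is.character(reference_sequence), length(reference_sequence) == 1)
  if (grepl("[^ACGT]", reference_sequence)) {
    abort("reference_sequence must contain only A/C/G/T")
  }
  if (length(site_offsets) > 0) {
    if (is.null(names(site_offsets)) || anyDuplicated(names(site_offsets))) {
      abort("site_offsets must have unique names (site labels)")
    }
    site_offsets <- vapply(site_offsets, as.integer, integer(1))
    if (is.unsorted(site_offsets, strictly = TRUE)) {
      abort("site offsets must be strictly increasing in transcript order")
    }
    bases <- substring(reference_sequence, site_offsets + 1, site_offsets + 1)
    if (any(bases != "A")) {
      abort(sprintf(
        "reference base at site(s) %s is not A",
        paste(names(site_offsets)[bases != "A"], collapse = ", ")
      ))
    }
    span <- range(site_offsets)
    if (length(site_offsets) > 1 && diff(span) + 1L > 15L) {
      warn("editing sites span more than 15 nt; the 5-HT2CR sites are closer")
    }
    if (span[1] < flank_width ||
        span[2] + flank_width >= nchar(reference_sequence)) {
      abort("reference must extend at least `flank_width` nt beyond the outer sites")
    }
  } else {
    site_offsets <- integer(0)
  }
  for (res in names(codon_map)) {
    cm <- codon_map[[res]]
    if (!all(c("start", "sites") %in% names(cm))) {
      abort("each codon_map entry needs `start` and `sites`")
    }
    if (!all(cm$sites %in% names(site_offsets))) {
      abort(sprintf("codon_map residue %s names unknown sites", res))
    }
    inside <- site_offsets[cm$sites] - cm$start
    if (any(inside < 0 | inside > 2)) {
      abort(sprintf("site(s) of residue %s fall outside its codon", res))
    }
  }
  structure(
    list(
      reference_sequence = reference_sequence,
      site_offsets = site_offsets,
      codon_map = codon_map,
      flank_width = as.integer(flank_width)
    ),
    class = "editing_region"
  )
}

#' @export
print.editing_region <- function(x, ...) {
  cat("<editing_region>\n")
  cat("  reference:", nchar(x$reference_sequence), "nt\n")
  cat("  sites:", paste(sprintf("%s@%d", names(x$site_offsets), x$site_offsets),
                        collapse = " "), "(0-based)\n")
  if (length(x$codon_map)) {
    cat("  codons:", paste(names(x$codon_map), collapse = ", "), "\n")
  }
  invisible(x)
}

#' The 5-HT2CR editing region fixture
#'
#' A synthetic amplicon built around the genuine codon structure of the
#' rat 5-HT2CR editing window: residues 156-160 read ATA-CGT-AAT-CCT-ATT
#' (Ile-Arg-Asn-Pro-Ile), with site A and B at positions 1 and 3 of the
#' residue-156 codon, E and C at positions 1 and 2 of the residue-158 codon,
#' and D at position 1 of the residue-160 codon. The 24-nt flanks on either
#' side are invented (synthetic) anchor sequence, not genomic.
#'
#' @return an [editing_region()].
#' @examples
#' region <- htr2c_region()
#' length(enumerate_variants(region))  # 32
#' @export
htr2c_region <- function() {
  left  <- "CCTGTCCGTGGAGAGGATCGCTAT"
  core  <- "ATACGTAATCCTATT"
  right <- "GGCCGTTCATGGTCAACAAGCGGC"
  off <- nchar(left)
  editing_region(
    reference_sequence = paste0(left, core, right),
    site_offsets = c(A = off, B = off + 2L, E = off + 6L,
                     C = off + 7L, D = off + 12L),
    codon_map = list(
      `156` = list(start = off,       sites = c("A", "B")),
      `158` = list(start = off + 6L,  sites = c("E", "C")),
      `160` = list(start = off + 12L, sites = "D")
    )
  )
}

# Canonical display order of site letters in variant names.
site_display_order <- function(region) {
  sort(names(region$site_offsets))
}

#' Canonical variant label for a set of edited sites
#'
#' Labels concatenate site letters in A, B, C, D, E display order; the empty
#' set is `"NONE"`.
#'
#' @param sites character vector of edited-site labels (possibly empty).
#' @param region an [editing_region()].
#' @return a single label string.
#' @export
variant_label <- function(sites, region = htr2c_region()) {
  ord <- site_display_order(region)
  if (!all(sites %in% ord)) abort("unknown site label")
  if (length(sites) == 0) return("NONE")
  paste(ord[ord %in% sites], collapse = "")
}

#' Edited sites of a variant label
#'
#' @param label a variant label such as `"ABD"` or `"NONE"`.
#' @return character vector of site letters (empty for `"NONE"`).
#' @export
variant_sites <- function(label) {
  if (identical(label, "NONE")) return(character(0))
  strsplit(label, "")[[1]]
}

#' Enumerate all combinatorial editing variants
#'
#' Every subset of the region's editing sites is a distinct mRNA variant;
#' with the five 5-HT2CR sites this gives the 32 variants reported for the
#' receptor. Labels are canonical ([variant_label()]), ordered by number of
#' edited sites then alphabetically.
#'
#' @param region an [editing_region()].
#' @return character vector of `2^k` variant labels.
#' @export
enumerate_variants <- function(region = htr2c_region()) {
  letters_ord <- site_display_order(region)
  k <- length(letters_ord)
  subsets <- unlist(lapply(0:k, function(m) {
    if (m == 0) return(list(character(0)))
    cols <- utils::combn(letters_ord, m, simplify = FALSE)
    cols
  }), recursive = FALSE)
  vapply(subsets, variant_label, character(1), region = region)
}

#' Enumerate receptor protein isoforms
#'
#' Translates every editing variant through the region's codon map (edited A
#' read as G, standard genetic code) and collapses variants onto amino-acid
#' isoforms. For 5-HT2CR the 32 variants encode 24 isoforms because sites
#' A/B and E/C share codons: e.g. the unedited variant gives INI, AB gives
#' VNI, and both ACD and ABCD give VSV.
#'
#' @param region an [editing_region()] with a populated `codon_map`.
#' @return a tibble with one row per variant: `variant`, `isoform`
#'   (amino-acid string in residue order).
#' @export
enumerate_isoforms <- function(region = htr2c_region()) {
  if (length(region$codon_map) == 0) abort("region has no codon_map")
  covered <- unlist(lapply(region$codon_map, `[[`, "sites"))
  missing <- setdiff(names(region$site_offsets), covered)
  if (length(missing)) {
    abort(sprintf("codon_map does not cover site(s) %s",
                  paste(missing, collapse = ", ")))
  }
  gc <- Biostrings::GENETIC_CODE
  residues <- names(region$codon_map)[order(as.integer(names(region$codon_map)))]
  variants <- enumerate_variants(region)
  iso <- vapply(variants, function(v) {
    edited <- variant_sites(v)
    aa <- vapply(residues, function(res) {
      cm <- region$codon_map[[res]]
      codon <- substring(region$reference_sequence, cm$start + 1, cm$start + 3)
      for (s in intersect(cm$sites, edited)) {
        pos <- region$site_offsets[[s]] - cm$start + 1L
        substring(codon, pos, pos) <- "G"
      }
      unname(gc[[codon]])
    }, character(1))
    paste(aa, collapse = "")
  }, character(1))
  tibble(variant = variants, isoform = unname(iso))
}
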