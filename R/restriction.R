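#' Construct the Kv1.1 (Kcna1) editing-assay amplicon
#'
#' Builds a synthetic 390-nt amplicon reproducing the MfeI digest arithmetic
#' of the Kv1.1 editing assay: a constitutive CAATTG site cut 220 nt into the
#' amplicon and a second, editing-dependent CAATTG site 51 nt further along.
#' The I/V editing event replaces the site's first adenosine with G, which
#' destroys the recognition site, so the unedited form digests to
#' 220 + 51 + 119 nt and the edited form to 220 + 170 nt. The background
#' sequence is synthetic (an ACGT repeat), not the genomic Kcna1 sequence;
#' only the fragment arithmetic is biological.
#'
#' @param edited if `TRUE`, the editing-site A is replaced by G.
#' @return an object of class `amplicon`: `sequence`, `length`,
#'   `site_offsets` (0-based CAATTG starts), `editing_offset`.
#' @examples
#' digest_amplicon(kcna1_amplicon(edited = FALSE))$length  # 220 51 119
#' @export
kcna1_amplicon <- function(edited = FALSE) {
  len <- 390L
  const_cut <- 220L   # fragment boundary after the constitutive site
  edit_cut <- 271L    # boundary after the editing-dependent site (51 nt apart)
  site <- "CAATTG"    # MfeI recognition site, cut C^AATTG
  seq <- substring(strrep("ACGT", ceiling(len / 4)), 1, len)
  put <- function(s, at0) {                    # at0: 0-based site start
    paste0(substring(s, 1, at0), site, substring(s, at0 + 7, nchar(s)))
  }
  seq <- put(seq, const_cut - 1L)
  seq <- put(seq, edit_cut - 1L)
  editing_offset <- edit_cut                    # 0-based: first A of CAATTG
  if (edited) {
    substring(seq, editing_offset + 1, editing_offset + 1) <- "G"
  }
  structure(
    list(sequence = seq, length = nchar(seq),
         site_offsets = if (edited) const_cut - 1L else c(const_cut - 1L, edit_cut - 1L),
         editing_offset = editing_offset, edited = edited),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat("<amplicon> ", x$length, " nt, ",
      length(x$site_offsets), " recognition site(s)",
      if (isTRUE(x$edited)) ", edited" else "", "\n", sep = "")
  invisible(x)
}

#' Digest a sequence with a restriction enzyme
#'
#' Cuts at every exact occurrence of the recognition sequence, at the stated
#' offset within the site (MfeI cuts C^AATTG, offset 1). Zero matches yield a
#' single full-length fragment. Fragment lengths always sum to the input
#' length.
#'
#' @param amplicon an `amplicon` object, or a character sequence.
#' @param recognition_sequence recognition site (default MfeI `CAATTG`).
#' @param cut_offset cut position within the site (0-based; default 1).
#' @return a digest profile tibble: `fragment` (order along the amplicon),
#'   `length`, `molar_abundance` (unit for a single-species digest).
#' @export
digest_amplicon <- function(amplicon, recognition_sequence = "CAATTG",
                            cut_offset = 1L) {
  seq <- if (inherits(amplicon, "amplicon")) amplicon$sequence else toupper(amplicon)
  if (!nzchar(recognition_sequence)) abort("recognition sequence must be non-empty")
  hits <- Biostrings::matchPattern(Biostrings::DNAString(recognition_sequence),
                                   Biostrings::DNAString(seq))
  cuts <- sort(Biostrings::start(hits) - 1L + cut_offset)   # 0-based cut coords
  cuts <- cuts[cuts > 0 & cuts < nchar(seq)]
  lens <- diff(c(0L, cuts, nchar(seq)))
  tibble(fragment = seq_along(lens), length = lens, molar_abundance = 1)
}

#' Estimate Kv1.1 editing efficiency from a digest profile
#'
#' The edited fraction is the molar ratio of the edited-diagnostic fragment
#' (~170 nt) to the sum of the edited- and unedited-diagnostic fragments
#' (~170 nt and ~119 nt). Diagnostic fragments are matched with a +/-2 nt
#' length tolerance (the assay's reported sizes vary by 1 nt). The shared
#' 220-nt fragment co-migrates in both forms and is not used.
#'
#' @param profile digest profile tibble with `length` and an abundance column.
#' @param edited_length,unedited_length diagnostic fragment lengths.
#' @param tolerance matching tolerance in nt.
#' @param units `"molar"` if abundances are molar; `"mass"` if they are mass
#'   units (e.g. Bioanalyzer ng), in which case each is divided by fragment
#'   length before forming the ratio.
#' @return estimated editing fraction in `[0, 1]`.
#' @export
estimate_editing <- function(profile, edited_length = 170, unedited_length = 119,
                             tolerance = 2, units = c("molar", "mass")) {
  units <- match.arg(units)
  ab_col <- intersect(c("molar_abundance", "abundance"), names(profile))[1]
  if (is.na(ab_col)) abort("profile needs a `molar_abundance` or `abundance` column")
  ab <- profile[[ab_col]]
  if (any(ab < 0)) abort("abundances must be non-negative")
  if (units == "mass") ab <- ab / profile$length
  m_e <- sum(ab[abs(profile$length - edited_length) <= tolerance])
  m_u <- sum(ab[abs(profile$length - unedited_length) <= tolerance])
  if (m_e + m_u == 0) {
    abort("neither diagnostic fragment (~170 nt or ~119 nt) present in profile")
  }
  m_e / (m_e + m_u)
}
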