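# Restriction enzyme definitions and cut-site search.

# Built-in enzymes commonly used for 3C libraries. cut_offset is the cut
# position within the recognition motif on the top strand (0-based).
.BUILTIN_ENZYMES <- list(
  DpnII   = list(name = "DpnII",   motif = "GATC",   cut_offset = 0L),
  HindIII = list(name = "HindIII", motif = "AAGCTT", cut_offset = 1L),
  NlaIII  = list(name = "NlaIII",  motif = "CATG",   cut_offset = 4L)
)

#' Restriction enzyme specification
#'
#' Builds an enzyme object from a built-in name (`"DpnII"`, `"HindIII"`,
#' `"NlaIII"`) or from a custom recognition motif and cut offset. The motif is
#' matched literally on the top strand; the cut offset gives the 0-based cut
#' position within the motif. Custom motifs may contain IUPAC ambiguity codes,
#' which are expanded during matching; built-ins are plain ACGT.
#'
#' @param name enzyme name. For `"custom"` supply `motif` and `cut_offset`.
#' @param motif recognition sequence (uppercase DNA; IUPAC allowed for custom).
#' @param cut_offset integer in `[0, nchar(motif)]`.
#' @return an object of class `cifi_enzyme` with fields `name`, `motif`,
#'   `cut_offset`.
#' @examples
#' restriction_enzyme("DpnII")
#' restriction_enzyme("custom", motif = "GANTC", cut_offset = 1)
#' @export
restriction_enzyme <- function(name, motif = NULL, cut_offset = NULL) {
  if (name %in% names(.BUILTIN_ENZYMES)) {
    e <- .BUILTIN_ENZYMES[[name]]
  } else {
    if (is.null(motif) || is.null(cut_offset))
      stop("unknown enzyme '", name, "': supply motif and cut_offset for a custom enzyme")
    motif <- toupper(motif)
    if (nchar(motif) == 0L) stop("motif must be non-empty")
    if (grepl("[^ACGTRYSWKMBDHVN]", motif))
      stop("motif contains characters outside the IUPAC DNA alphabet")
    cut_offset <- as.integer(cut_offset)
    if (cut_offset < 0L || cut_offset > nchar(motif))
      stop("cut_offset must lie in [0, nchar(motif)]")
    e <- list(name = name, motif = motif, cut_offset = cut_offset)
  }
  structure(e, class = "cifi_enzyme")
}

#' @export
print.cifi_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s, cut at +%d>\n", x$name, x$motif, x$cut_offset))
  invisible(x)
}

as_enzyme <- function(enzyme) {
  if (inherits(enzyme, "cifi_enzyme")) return(enzyme)
  if (is.character(enzyme) && length(enzyme) == 1L) return(restriction_enzyme(enzyme))
  stop("enzyme must be a cifi_enzyme object or a built-in enzyme name")
}

#' Find restriction cut sites in a sequence
#'
#' Scans the top strand for the enzyme's recognition motif and returns the
#' 0-based cut positions (motif start + cut offset). Overlapping motif
#' occurrences each contribute a site. Cuts falling exactly at position 0 or
#' at the sequence end are suppressed (they do not split anything). Matching
#' is case-insensitive; `N` never matches any motif base.
#'
#' @param sequence a single DNA string (A,C,G,T,N; case-insensitive).
#' @param enzyme a [restriction_enzyme()] object or built-in name.
#' @return strictly increasing integer vector of 0-based cut positions.
#' @examples
#' find_cut_sites("GGGATCCC", "DpnII")   # 2
#' find_cut_sites("TTAAGCTTGG", "HindIII") # 3
#' @export
find_cut_sites <- function(sequence, enzyme) {
  enzyme <- as_enzyme(enzyme)
  s <- check_dna(sequence)
  L <- nchar(s)
  if (L < nchar(enzyme$motif)) return(integer(0))
  # "subject" keeps subject letters literal (N never matches) while letting
  # IUPAC codes in a custom motif expand.
  fixed <- if (grepl("[^ACGT]", enzyme$motif)) "subject" else TRUE
  hits <- Biostrings::matchPattern(enzyme$motif, Biostrings::DNAString(s),
                                   fixed = fixed)
  starts0 <- Biostrings::start(hits) - 1L  # 0-based motif starts
  if (!isTRUE(fixed) && length(starts0)) {
    # an N in the subject must never satisfy a motif position, even where the
    # expanded motif itself carries an N code
    has_n <- vapply(starts0, function(p)
      grepl("N", substring(s, p + 1L, p + nchar(enzyme$motif)), fixed = TRUE),
      logical(1))
    starts0 <- starts0[!has_n]
  }
  cuts <- starts0 + enzyme$cut_offset
  cuts <- cuts[cuts > 0L & cuts < L]
  sort(unique(as.integer(cuts)))
}
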