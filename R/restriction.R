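# In-silico restriction digestion.
#
# Restriction sites are only defined on standard four-letter DNA: the
# transliteration workflow is validated by checking that AluI/PspOMI sites
# are destroyed by deamination (C->T) and regenerated by Z->C conversion, so
# callers must transliterate expanded-alphabet sequences first.

#' Restriction enzyme definition
#'
#' @param name identifier.
#' @param recognition recognition motif over \{A,C,G,T\}.
#' @param cut_offset top-strand cut position within the site, `0` to
#'   `nchar(recognition)`.
#' @return object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("AluI", "AGCT", 2)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) == 0L) stop("empty recognition motif", call. = FALSE)
  .check_alphabet(.chars(recognition), allow = c("A", "C", "G", "T"),
                  what = sprintf("recognition motif of %s", name))
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("`cut_offset` must lie within the recognition motif", call. = FALSE)
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' The two enzymes used to assay transliteration
#'
#' AluI (AG^CT) and PspOMI (G^GGCCC), with cut offsets from the standard
#' REBASE definitions.
#'
#' @return named list of [restriction_enzyme] objects.
#' @export
restriction_presets <- function() {
  list(AluI   = restriction_enzyme("AluI", "AGCT", 2L),
       PspOMI = restriction_enzyme("PspOMI", "GGGCCC", 1L))
}

.standard_only <- function(s, what) {
  ch <- .chars(s)
  bad <- setdiff(unique(ch), c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop(sprintf(paste("non-standard letter(s) %s in %s:",
                       "restriction sites are undefined on the expanded",
                       "alphabet; transliterate first"),
                 paste(sQuote(bad), collapse = ", "), what),
         call. = FALSE)
  }
  ch
}

#' Scan a four-letter sequence for restriction sites
#'
#' Exact motif occurrences, overlaps allowed, sorted by position.  Positions
#' are reported 1-based.
#'
#' @param s sequence over \{A,C,G,T\} ([expanded_seq] or string).
#' @param enzymes a [restriction_enzyme] or list of them (default: the
#'   [restriction_presets()] pair).
#' @return data frame with columns `enzyme` and `start` (1-based).
#' @examples
#' find_sites("GGGCCC")
#' @export
find_sites <- function(s, enzymes = restriction_presets()) {
  str <- .seq_string(s)
  ch <- .standard_only(str, what = "sequence")
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  hits <- lapply(enzymes, function(e) {
    k <- nchar(e$recognition)
    n <- length(ch)
    if (n < k) return(integer(0L))
    motif <- .chars(e$recognition)
    # overlap-safe scan: compare k shifted views of the character vector
    ok <- rep(TRUE, n - k + 1L)
    for (j in seq_len(k)) {
      ok <- ok & (ch[j:(n - k + j)] == motif[j])
    }
    which(ok)
  })
  out <- data.frame(
    enzyme = rep(vapply(enzymes, `[[`, "", "name"), lengths(hits)),
    start = unlist(hits, use.names = FALSE),
    stringsAsFactors = FALSE)
  out[order(out$start, out$enzyme), , drop = FALSE]
}

#' Fragment lengths from an in-silico digest
#'
#' Cuts the top strand at `start + cut_offset - 1` for every site of one
#' enzyme and returns fragment lengths.  Fragments always sum to the
#' sequence length; a sequence without sites returns its own length.
#'
#' @inheritParams find_sites
#' @param enzyme a single [restriction_enzyme].
#' @return integer vector of fragment lengths.
#' @examples
#' digest_lengths("AAAGCTTT", restriction_presets()$AluI)  # 4, 4
#' @export
digest_lengths <- function(s, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  str <- .seq_string(s)
  .standard_only(str, what = "sequence")
  n <- nchar(str)
  sites <- find_sites(str, enzyme)
  cuts <- sites$start - 1L + enzyme$cut_offset   # 0-based cut coordinates
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  diff(c(0L, cuts, n))
}
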