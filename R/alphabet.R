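# Expanded-alphabet primitives.
#
# The working alphabet is {A,C,G,T,Z,P,U,N}: the four standard bases, the
# AEGIS Z:P pair, U as the transient product of cytidine deamination, and N
# for randomised template positions.  N is legal only in template
# definitions; U only in post-deamination intermediates.

XNA_LETTERS <- c("A", "C", "G", "T", "Z", "P", "U", "N")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                 Z = "P", P = "Z", U = "A", N = "N")

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.check_alphabet <- function(chars, allow = XNA_LETTERS, what = "sequence") {
  bad <- setdiff(unique(chars), allow)
  if (length(bad) > 0L) {
    stop(sprintf("illegal character(s) %s in %s (allowed: %s)",
                 paste(sQuote(bad), collapse = ", "), what,
                 paste(allow, collapse = "")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Complement an expanded-alphabet base
#'
#' Watson-Crick complementation extended to the AEGIS pair: A<->T, C<->G and
#' Z<->P.  U (the deamination product of C) behaves as T and complements to
#' A; N complements to N.  The map is an involution on \{A,C,G,T,Z,P,N\}
#' (but not on U, whose complement-of-complement is T).
#'
#' @param b character vector of single bases.
#' @return character vector of complemented bases.
#' @examples
#' complement_base(c("A", "Z", "P"))
#' @export
complement_base <- function(b) {
  if (!is.character(b) || any(nchar(b) != 1L)) {
    stop("`b` must be a character vector of single bases", call. = FALSE)
  }
  .check_alphabet(b, what = "base")
  unname(.COMPLEMENT[b])
}

.rc_string <- function(x, what = "sequence") {
  ch <- .chars(x)
  .check_alphabet(ch, what = what)
  paste(rev(unname(.COMPLEMENT[ch])), collapse = "")
}

#' Reverse complement of an expanded-alphabet sequence
#'
#' Reverses the sequence and complements base-wise (Z<->P included).  For an
#' [expanded_seq] the strand flag is flipped; a plain string returns a
#' string.  Used to place antisense-arm reads into sense coordinates.
#'
#' @param s an [expanded_seq] or a single character string.
#' @return object of the same type as `s`.
#' @examples
#' reverse_complement("GGGCCC")  # palindrome
#' @export
reverse_complement <- function(s) {
  if (is_expanded_seq(s)) {
    expanded_seq(s$name, .rc_string(s$bases, what = sprintf("sequence '%s'", s$name)),
                 strand = if (s$strand == "sense") "antisense" else "sense",
                 note = s$note)
  } else if (is.character(s) && length(s) == 1L) {
    .rc_string(toupper(s))
  } else {
    stop("`s` must be an expanded_seq or a single string", call. = FALSE)
  }
}

#' Named sequence over the expanded alphabet
#'
#' Light container for a named single strand over \{A,C,G,T,Z,P,U,N\}.
#' Lowercase input is upper-cased; any character outside the alphabet is
#' rejected.  `strand` records whether the record is in sense or antisense
#' orientation with respect to its template.
#'
#' @param name identifier.
#' @param bases single string over the expanded alphabet.
#' @param strand `"sense"` or `"antisense"`.
#' @param note free-text annotation.
#' @return object of class `expanded_seq` with fields `name`, `bases`,
#'   `strand`, `note`.
#' @examples
#' zz <- expanded_seq("toy", "ACGTZP")
#' reverse_complement(zz)
#' @export
expanded_seq <- function(name, bases, strand = c("sense", "antisense"),
                         note = "") {
  strand <- match.arg(strand)
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    stop("`bases` must be a single string", call. = FALSE)
  }
  bases <- toupper(bases)
  if (nchar(bases) > 0L) {
    .check_alphabet(.chars(bases), what = sprintf("sequence '%s'", name))
  }
  structure(list(name = as.character(name), bases = bases,
                 strand = strand, note = as.character(note)),
            class = "expanded_seq")
}

#' @rdname expanded_seq
#' @param x object to test or print.
#' @export
is_expanded_seq <- function(x) inherits(x, "expanded_seq")

#' @export
print.expanded_seq <- function(x, ...) {
  cat(sprintf("<expanded_seq> %s (%s, %d nt)\n", x$name, x$strand,
              nchar(x$bases)))
  cat(" ", x$bases, "\n", sep = "")
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.character.expanded_seq <- function(x, ...) x$bases

# Coerce expanded_seq or string to a plain uppercase string.
.seq_string <- function(s) {
  if (is_expanded_seq(s)) s$bases else toupper(as.character(s))
}
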