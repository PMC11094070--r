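# Template FASTA and read FASTQ input/output.
#
# Templates are FASTA over the expanded alphabet (Z/P/N permitted, U
# rejected -- U only ever exists as a post-deamination intermediate).
# Reads are standard 4-line FASTQ over {A,C,G,T,N}.

#' Read expanded-alphabet templates from FASTA
#'
#' A FASTA dialect permitting the AEGIS letters Z and P and (for randomised
#' templates) N.  Lowercase letters are upper-cased; U is rejected because
#' templates cannot contain the deamination intermediate.
#'
#' @param path FASTA file.
#' @return list of [expanded_seq] (all sense strand).
#' @export
read_templates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       seqonly = FALSE),
    error = function(e) stop(sprintf("malformed FASTA in '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  out <- lapply(seq_along(recs), function(i) {
    nm <- attr(recs[[i]], "name")
    if (is.null(nm)) nm <- names(recs)[i]
    bases <- toupper(as.character(recs[[i]]))
    if (grepl("U", bases, fixed = TRUE)) {
      stop(sprintf("template '%s' contains U; U is only legal in %s",
                   nm, "post-deamination intermediates"),
           call. = FALSE)
    }
    expanded_seq(nm, bases)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write expanded-alphabet templates to FASTA
#'
#' @param seqs list of [expanded_seq] (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_templates <- function(seqs, path) {
  if (is_expanded_seq(seqs)) seqs <- list(seqs)
  seqinr::write.fasta(
    sequences = lapply(seqs, function(s) s$bases),
    names = vapply(seqs, `[[`, "", "name"),
    file.out = path, as.string = TRUE, nbchar = 80L)
  invisible(path)
}

#' The amplicon templates shipped with the package
#'
#' The seven study templates: the standard control `Nat` (71 nt, carrying
#' one AluI and one PspOMI site), `ZZ` (Nat with three C positions replaced
#' by Z, destroying the sites until Z is transliterated back to C), the
#' six-letter `ZP-1` and `ZP-2`, and the randomised-context `C-Ran`,
#' `Z-Ran`, `P-Ran` (`NNNxNNN` cassettes).  All share constant primer
#' flanks; see [primer_flanks()].
#'
#' @return named list of [expanded_seq].
#' @examples
#' nchar(aegis_templates()$Nat$bases)  # 71
#' @export
aegis_templates <- function() {
  read_templates(system.file("extdata", "aegis_templates.fasta",
                             package = "esega", mustWork = TRUE))
}

#' Constant primer-flank lengths of the shipped templates
#'
#' The shipped templates share a 24-nt forward and a 26-nt reverse constant
#' flank (the primer regions).  Composition and fidelity statistics exclude
#' these positions.
#'
#' @return list with integers `fwd` and `rev`.
#' @export
primer_flanks <- function() list(fwd = 24L, rev = 26L)

#' Read a FASTQ file
#'
#' Standard 4-line records.  Sequence letters are restricted to
#' \{A,C,G,T,N\} (upper-cased); base and quality strings must have equal
#' length.  Errors report the offending line number.
#'
#' @param path FASTQ file.
#' @return data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(lines)), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  at <- function(k) lines[seq.int(k, by = 4L, length.out = n)]
  ids <- at(1L); seqs <- toupper(at(2L)); seps <- at(3L); quals <- at(4L)
  bad <- which(substr(ids, 1L, 1L) != "@")
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ '%s': header at line %d does not start with '@'",
                 path, (bad[1L] - 1L) * 4L + 1L), call. = FALSE)
  }
  bad <- which(substr(seps, 1L, 1L) != "+")
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ '%s': separator at line %d does not start with '+'",
                 path, (bad[1L] - 1L) * 4L + 3L), call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ '%s': base/quality length mismatch at line %d",
                 path, (bad[1L] - 1L) * 4L + 2L), call. = FALSE)
  }
  .check_alphabet(unique(.chars(paste(seqs, collapse = ""))),
                  allow = c("A", "C", "G", "T", "N"), what = path)
  data.frame(id = sub("^@", "", ids), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data frame with columns `id`, `sequence`, `quality` (as
#'   returned by [read_fastq()] or [generate_reads()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("base/quality length mismatch", call. = FALSE)
  }
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$sequence,
                             "+", reads$quality)),
             path)
  invisible(path)
}
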