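# Amplicon read processing: pair merging, barcode filtering, anchored
# alignment and pileups.
#
# The amplicons are fixed-length with constant primer flanks and the
# simulator emits substitutions only, so gapped alignment is replaced by
# ungapped minimal-mismatch placement against the expected (transliterated)
# scaffold; a permissive mismatch threshold absorbs the many legitimate
# base changes deamination introduces.

#' Merge a read pair by overlap
#'
#' `r2` is taken as the reverse-strand mate: it is reverse-complemented and
#' overlaps of at least `min_overlap` against the tail of `r1` are scored
#' by mismatch count.  The best (lowest-mismatch, ties to the longest)
#' overlap is accepted if its mismatch fraction is within
#' `max_mismatch_frac`; disagreeing overlap bases are resolved toward the
#' higher-quality call.  Rejection is a value, not an error.
#'
#' @param r1,r2 lists (or one-row data frames) with `sequence` and
#'   `quality`.
#' @param min_overlap minimum acceptable overlap length.
#' @param max_mismatch_frac maximum mismatch fraction within the overlap.
#' @return list with `status` (`"merged"` or `"rejected"`); when merged,
#'   `sequence`, `quality`, `overlap`, `mismatches`; when rejected,
#'   `reason`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1) {
  s1 <- toupper(as.character(r1$sequence)[1L])
  q1 <- as.character(r1$quality)[1L]
  s2 <- .rc_string(toupper(as.character(r2$sequence)[1L]))
  q2 <- paste(rev(.chars(as.character(r2$quality)[1L])), collapse = "")
  n1 <- nchar(s1); n2 <- nchar(s2)
  max_o <- min(n1, n2)
  if (max_o < min_overlap) {
    return(list(status = "rejected", reason = "reads shorter than min_overlap"))
  }
  c1 <- .chars(s1); c2 <- .chars(s2)
  # longest acceptable overlap wins: scanning from the longest candidate
  # avoids spurious short perfect overlaps inside repetitive sequence
  best_o <- NA_integer_; best_mm <- NA_integer_
  for (o in seq.int(max_o, min_overlap)) {
    mm <- sum(c1[(n1 - o + 1L):n1] != c2[1L:o])
    if (mm / o <= max_mismatch_frac) { best_o <- o; best_mm <- mm; break }
  }
  if (is.na(best_o)) {
    return(list(status = "rejected",
                reason = sprintf("no overlap >= %d nt within mismatch fraction %.2f",
                                 min_overlap, max_mismatch_frac)))
  }
  o <- best_o
  ov1 <- c1[(n1 - o + 1L):n1]; ov2 <- c2[1L:o]
  qv1 <- .chars(q1)[(n1 - o + 1L):n1]; qv2 <- .chars(q2)[1L:o]
  take2 <- ov1 != ov2 & utf8ToInt(paste(qv2, collapse = "")) >
    utf8ToInt(paste(qv1, collapse = ""))
  ov <- ov1; ov[take2] <- ov2[take2]
  qv <- pmax(qv1, qv2)
  merged <- paste0(substr(s1, 1L, n1 - o), paste(ov, collapse = ""),
                   substr(s2, o + 1L, n2))
  mergedq <- paste0(substr(q1, 1L, n1 - o), paste(qv, collapse = ""),
                    substr(q2, o + 1L, n2))
  list(status = "merged", sequence = merged, quality = mergedq,
       overlap = o, mismatches = best_mm)
}

.hamming_prefix <- function(seqs, barcode) {
  bl <- nchar(barcode)
  bc <- .chars(barcode)
  pre <- substr(seqs, 1L, bl)
  mm <- integer(length(seqs))
  for (j in seq_len(bl)) {
    mm <- mm + (substr(pre, j, j) != bc[j])
  }
  mm
}

#' Filter reads by inline barcode
#'
#' Reads carry an 8-base barcode at the start (library structure:
#' adapter - 8-base barcode - primer).  A read is kept iff the Hamming
#' distance of its prefix to the expected barcode is at most
#' `max_mismatch`; kept reads have the barcode trimmed.
#'
#' @param reads data frame with `id`, `sequence`, `quality`.
#' @param barcode expected 8-base barcode.
#' @param max_mismatch maximum Hamming distance (default 0).
#' @return list with `kept` and `discarded` data frames and a `counts`
#'   vector.
#' @export
filter_barcode <- function(reads, barcode, max_mismatch = 0L) {
  barcode <- toupper(barcode)
  if (nchar(barcode) != 8L) {
    stop("`barcode` must be an 8-base string", call. = FALSE)
  }
  mm <- .hamming_prefix(reads$sequence, barcode)
  keep <- mm <= max_mismatch
  kept <- reads[keep, , drop = FALSE]
  bl <- nchar(barcode)
  kept$sequence <- substr(kept$sequence, bl + 1L, nchar(kept$sequence))
  kept$quality <- substr(kept$quality, bl + 1L, nchar(kept$quality))
  rownames(kept) <- NULL
  discarded <- reads[!keep, , drop = FALSE]
  rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded,
       counts = c(kept = sum(keep), discarded = sum(!keep)))
}

#' Place a read on an expected amplicon scaffold
#'
#' Ungapped placement minimising mismatches against the scaffold (the
#' transliterated template with its constant primer flanks).  Accepted iff
#' the mismatch fraction is at most `max_mismatch_frac` (default 0.4,
#' deliberately generous: deamination legitimately changes every C).  A tie
#' between offsets takes the smallest and is flagged.
#'
#' @param read read sequence (string).
#' @param scaffold expected four-letter amplicon (string).
#' @param max_mismatch_frac maximum mismatch fraction.
#' @return list with `status`; when accepted, `offset` (1-based scaffold
#'   position of the read's first base), `mismatches`, `tie`.
#' @export
align_anchored <- function(read, scaffold, max_mismatch_frac = 0.4) {
  read <- toupper(as.character(read)[1L])
  scaffold <- toupper(as.character(scaffold)[1L])
  lr <- nchar(read); ls <- nchar(scaffold)
  if (ls < lr) {
    stop("scaffold shorter than read: check template/run pairing",
         call. = FALSE)
  }
  rc <- .chars(read); sc <- .chars(scaffold)
  n_off <- ls - lr + 1L
  mm <- integer(n_off)
  for (j in seq_len(lr)) {
    mm <- mm + (sc[j:(ls - lr + j)] != rc[j])
  }
  best <- which.min(mm)
  if (mm[best] / lr > max_mismatch_frac) {
    return(list(status = "rejected", mismatches = mm[best]))
  }
  list(status = "accepted", offset = best, mismatches = mm[best],
       tie = sum(mm == mm[best]) > 1L)
}

# Vectorised placement for a batch of reads against one scaffold.
# Equal-length reads at each candidate offset are compared column-wise.
.align_many <- function(seqs, scaffold, max_mismatch_frac = 0.4) {
  out <- data.frame(sequence = seqs, offset = NA_integer_,
                    mismatches = NA_integer_, accepted = FALSE,
                    stringsAsFactors = FALSE)
  ls <- nchar(scaffold)
  sc <- .chars(scaffold)
  for (lr in unique(nchar(seqs))) {
    rows <- which(nchar(seqs) == lr)
    if (ls < lr) {
      stop("scaffold shorter than read: check template/run pairing",
           call. = FALSE)
    }
    n_off <- ls - lr + 1L
    mm <- matrix(0L, nrow = length(rows), ncol = n_off)
    for (off in seq_len(n_off)) {
      ref <- paste(sc[off:(off + lr - 1L)], collapse = "")
      d <- integer(length(rows))
      for (j in seq_len(lr)) {
        d <- d + (substr(seqs[rows], j, j) != substr(ref, j, j))
      }
      mm[, off] <- d
    }
    best <- max.col(-mm, ties.method = "first")
    bmm <- mm[cbind(seq_along(rows), best)]
    ok <- bmm / lr <= max_mismatch_frac
    out$offset[rows] <- best
    out$mismatches[rows] <- bmm
    out$accepted[rows] <- ok
  }
  out
}

#' Build a per-position pileup from aligned reads
#'
#' Accumulates \{A,C,G,T,other\} counts per scaffold coordinate.  The
#' `other` bucket collects N and any unexpected letter.  Given input read
#' order does not matter: reordering reads leaves the table unchanged.
#'
#' @param assignments data frame with `sequence` and `offset` (1-based), as
#'   produced by the anchored aligner; or a character vector of sequences
#'   all at offset 1.
#' @param length scaffold length (default: inferred from the deepest
#'   extent of the assignments).
#' @param template_id identifier stored in the table.
#' @return object of class `pileup_table`: `template_id`, `length`,
#'   `counts` (5 x length matrix), `depth` (per-position totals).
#' @export
build_pileup <- function(assignments, length = NULL, template_id = "") {
  if (is.character(assignments)) {
    assignments <- data.frame(sequence = assignments,
                              offset = rep(1L, base::length(assignments)),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sequence", "offset") %in% names(assignments)))
  ends <- assignments$offset + nchar(assignments$sequence) - 1L
  if (is.null(length)) length <- if (nrow(assignments)) max(ends) else 0L
  if (nrow(assignments) && (any(assignments$offset < 1L) ||
                            any(ends > length))) {
    stop("internal error: assignment outside scaffold coordinates",
         call. = FALSE)
  }
  counts <- matrix(0L, nrow = 5L, ncol = length,
                   dimnames = list(c(PRODUCT_BASES, "other"), NULL))
  grp <- interaction(assignments$offset, nchar(assignments$sequence),
                     drop = TRUE)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    off <- assignments$offset[rows[1L]]
    lr <- nchar(assignments$sequence[rows[1L]])
    chm <- matrix(unlist(strsplit(assignments$sequence[rows], "",
                                  fixed = TRUE), use.names = FALSE),
                  nrow = length(rows), byrow = TRUE)
    code <- match(chm, PRODUCT_BASES)
    code[is.na(code)] <- 5L
    dim(code) <- dim(chm)
    for (j in seq_len(lr)) {
      counts[, off + j - 1L] <- counts[, off + j - 1L] +
        tabulate(code[, j], nbins = 5L)
    }
  }
  structure(list(template_id = template_id, length = length,
                 counts = counts, depth = colSums(counts)),
            class = "pileup_table")
}

#' @export
print.pileup_table <- function(x, ...) {
  cat(sprintf("<pileup_table> %s: %d positions, depth %s\n",
              if (nzchar(x$template_id)) x$template_id else "(unnamed)",
              x$length,
              if (x$length) paste0(min(x$depth), "-", max(x$depth)) else "0"))
  invisible(x)
}

#' Per-position base fractions of a pileup
#'
#' @param pileup a [pileup_table].
#' @param exclude_ambiguous drop the `other` bucket from the denominator
#'   (default `FALSE`: ambiguous bases count toward depth).
#' @return matrix of fractions (rows `A,C,G,T` and, unless excluded,
#'   `other`); zero-depth positions are `NaN`.
#' @export
pileup_fractions <- function(pileup, exclude_ambiguous = FALSE) {
  stopifnot(inherits(pileup, "pileup_table"))
  counts <- pileup$counts
  if (exclude_ambiguous) counts <- counts[PRODUCT_BASES, , drop = FALSE]
  sweep(counts, 2L, colSums(counts), "/")
}

#' Write / read a pileup as a tab-separated table
#'
#' Columns: `position`, `depth`, counts and fractions for A, C, G, T and
#' other.
#'
#' @param pileup a [pileup_table].
#' @param path output file.
#' @return `path` (write) or a [pileup_table] (read).
#' @export
write_pileup <- function(pileup, path) {
  fr <- pileup_fractions(pileup)
  df <- data.frame(position = seq_len(pileup$length),
                   depth = pileup$depth,
                   t(pileup$counts),
                   round(t(fr), 6))
  names(df) <- c("position", "depth",
                 paste0("n_", c(PRODUCT_BASES, "other")),
                 paste0("f_", c(PRODUCT_BASES, "other")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @param template_id identifier stored in the reconstructed table.
#' @export
read_pileup <- function(path, template_id = "") {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  counts <- t(as.matrix(df[, paste0("n_", c(PRODUCT_BASES, "other"))]))
  rownames(counts) <- c(PRODUCT_BASES, "other")
  structure(list(template_id = template_id, length = nrow(df),
                 counts = counts, depth = colSums(counts)),
            class = "pileup_table")
}
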