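# Six-letter base calling from four-letter pileups.
#
# Two workflows:
#  * duplex: the two strands of the original molecule are deaminated and
#    amplified separately (5-triphosphate readout); comparing the sense
#    pileup with the complement-reflected antisense pileup resolves all six
#    letters.  The per-site pair mapping is exactly the composition of the
#    per-strand conversion rules with complementation:
#      (A,A)->A  (T,T)->T  (T,C)->C  (G,A)->G  (C,C)->Z  (G,G)->P
#  * single strand: a deaminated run is compared with a non-deaminated
#    control; Z shows as (C,C) and C as (T,C)->T,C.  G and P are
#    indistinguishable from 5-triphosphate data alone (both read G); a
#    4-triphosphate run, where P reads as an A/G mixture, resolves them.

DUPLEX_MAP <- c("A|A" = "A", "T|T" = "T", "T|C" = "C",
                "G|A" = "G", "C|C" = "Z", "G|G" = "P")

.site_call <- function(position, call, support, flags = character(0)) {
  structure(list(position = position, call = call, support = support,
                 flags = flags), class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf("<site_call> pos %s: %s%s\n",
              ifelse(is.na(x$position), "?", x$position), x$call,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

# Modal base (among A,C,G,T) and its fraction of total depth.
.modal <- function(frac) {
  if (is.null(frac) || length(frac) == 0L || all(is.na(frac)) ||
      !any(frac > 0, na.rm = TRUE)) {
    return(NULL)
  }
  f <- frac[PRODUCT_BASES]
  f[is.na(f)] <- 0
  i <- which.max(f)
  list(base = PRODUCT_BASES[i], frac = unname(f[i]))
}

#' Call one duplex site from sense and antisense base fractions
#'
#' `anti_frac_complemented` must already be reverse-complemented into sense
#' coordinates (as [decode_duplex()] does).  Both modal bases must exceed
#' the dominance threshold; the surviving pair is mapped through the
#' six-entry duplex table, and any unmapped pair is `AMBIGUOUS`.
#'
#' @param sense_frac,anti_frac_complemented named base-fraction vectors
#'   (names `A,C,G,T`, optionally `other`).
#' @param dominance minimum modal fraction for a confident call (default
#'   0.7: worst-case retained fractions around 0.8-0.95 still call cleanly
#'   while near-50/50 mixtures are flagged).
#' @param position 1-based position stored in the call.
#' @return a `site_call` with fields `position`, `call`, `support`,
#'   `flags`.
#' @examples
#' decode_duplex_site(c(A = 0, C = 0, G = 0, T = 0.99),
#'                    c(A = 0, C = 0.98, G = 0.02, T = 0))$call  # "C"
#' @export
decode_duplex_site <- function(sense_frac, anti_frac_complemented,
                               dominance = 0.7, position = NA_integer_) {
  s <- .modal(sense_frac); a <- .modal(anti_frac_complemented)
  support <- list(sense = sense_frac, antisense = anti_frac_complemented)
  if (is.null(s) || is.null(a)) {
    return(.site_call(position, "AMBIGUOUS", support, "low_depth"))
  }
  if (s$frac < dominance || a$frac < dominance) {
    return(.site_call(position, "AMBIGUOUS", support, "below_dominance"))
  }
  call <- DUPLEX_MAP[paste(s$base, a$base, sep = "|")]
  if (is.na(call)) {
    return(.site_call(position, "AMBIGUOUS", support, character(0)))
  }
  .site_call(position, unname(call), support)
}

#' Call one site from single-strand deaminated / control pileups
#'
#' Rules (each side requiring modal dominance): (C,C) -> Z, (T,C) -> C,
#' (T,T) -> T, (A,A) -> A; (G,G) -> P when a 4-triphosphate run is
#' supplied and shows the P signature (A fraction within
#' `p_signature["a_lo"]..p_signature["a_hi"]` with A+G at least
#' `p_signature["ag_min"]`), G otherwise -- without the 4-triphosphate run
#' the G call carries the `g_or_p_unresolved` flag.  Everything else is
#' `AMBIGUOUS`.
#'
#' @param deam_frac fractions from the deaminated, 5-triphosphate run.
#' @param ctrl_frac fractions from the non-deaminated control.
#' @param fourtri_frac optional fractions from a non-deaminated
#'   4-triphosphate run.
#' @param dominance minimum modal fraction.
#' @param p_signature named vector `a_lo`, `a_hi`, `ag_min`: the window of
#'   the 4-triphosphate A/G mixture that identifies P (measured split
#'   ~63/37).
#' @param position 1-based position stored in the call.
#' @return a `site_call`.
#' @export
decode_single_site <- function(deam_frac, ctrl_frac, fourtri_frac = NULL,
                               dominance = 0.7,
                               p_signature = c(a_lo = 0.35, a_hi = 0.85,
                                               ag_min = 0.9),
                               position = NA_integer_) {
  d <- .modal(deam_frac); ctl <- .modal(ctrl_frac)
  support <- list(deaminated = deam_frac, control = ctrl_frac,
                  fourtri = fourtri_frac)
  if (is.null(d) || is.null(ctl)) {
    return(.site_call(position, "AMBIGUOUS", support, "low_depth"))
  }
  if (d$frac < dominance || ctl$frac < dominance) {
    return(.site_call(position, "AMBIGUOUS", support, "below_dominance"))
  }
  key <- paste(d$base, ctl$base, sep = "|")
  call <- switch(key,
                 "C|C" = "Z", "T|C" = "C", "T|T" = "T", "A|A" = "A",
                 "G|G" = "G", NA_character_)
  if (is.na(call)) {
    return(.site_call(position, "AMBIGUOUS", support, character(0)))
  }
  if (call == "G") {
    if (is.null(fourtri_frac)) {
      return(.site_call(position, "G", support, "g_or_p_unresolved"))
    }
    fa <- fourtri_frac["A"]; fg <- fourtri_frac["G"]
    fa <- ifelse(is.na(fa), 0, fa); fg <- ifelse(is.na(fg), 0, fg)
    if (fa >= p_signature[["a_lo"]] && fa <= p_signature[["a_hi"]] &&
        fa + fg >= p_signature[["ag_min"]]) {
      return(.site_call(position, "P", support))
    }
    return(.site_call(position, "G", support))
  }
  .site_call(position, call, support)
}

# Complement-reflect a pileup into the coordinates of the opposite strand:
# reverse positions, swap A<->T and C<->G counts.
.reflect_pileup <- function(pileup) {
  counts <- pileup$counts[c("T", "G", "C", "A", "other"),
                          rev(seq_len(pileup$length)), drop = FALSE]
  rownames(counts) <- c(PRODUCT_BASES, "other")
  structure(list(template_id = pileup$template_id, length = pileup$length,
                 counts = counts, depth = rev(pileup$depth)),
            class = "pileup_table")
}

.calls_frame <- function(calls) {
  data.frame(
    position = vapply(calls, `[[`, 1L, "position"),
    call = vapply(calls, `[[`, "", "call"),
    flags = vapply(calls, function(x) paste(x$flags, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Decode a duplex from its two strand-arm pileups
#'
#' The antisense pileup (in its own read coordinates) is
#' complement-reflected into sense coordinates, then every position is
#' called with [decode_duplex_site()].  Positions where either arm is
#' shallower than `min_depth` are flagged `low_depth` and left
#' `AMBIGUOUS`.
#'
#' @param sense_pileup,anti_pileup [build_pileup()] tables for the
#'   deaminated sense and antisense arms (equal length).
#' @param dominance modal-fraction threshold.
#' @param min_depth minimum per-arm depth for a hard call (default 20).
#' @return data frame with `position`, `call`, `flags`.
#' @export
decode_duplex <- function(sense_pileup, anti_pileup, dominance = 0.7,
                          min_depth = 20L) {
  stopifnot(inherits(sense_pileup, "pileup_table"),
            inherits(anti_pileup, "pileup_table"))
  if (sense_pileup$length != anti_pileup$length) {
    stop("sense and antisense pileups must cover the same amplicon",
         call. = FALSE)
  }
  anti <- .reflect_pileup(anti_pileup)
  fs <- pileup_fractions(sense_pileup)
  fa <- pileup_fractions(anti)
  calls <- lapply(seq_len(sense_pileup$length), function(i) {
    if (sense_pileup$depth[i] < min_depth || anti$depth[i] < min_depth) {
      return(.site_call(i, "AMBIGUOUS",
                        list(sense = fs[, i], antisense = fa[, i]),
                        "low_depth"))
    }
    decode_duplex_site(fs[, i], fa[, i], dominance = dominance,
                       position = i)
  })
  .calls_frame(calls)
}

#' Decode a single strand from deaminated / control pileups
#'
#' @param deam_pileup pileup of the deaminated, 5-triphosphate run.
#' @param ctrl_pileup pileup of the non-deaminated control run.
#' @param fourtri_pileup optional non-deaminated 4-triphosphate pileup for
#'   G/P resolution.
#' @inheritParams decode_duplex
#' @inheritParams decode_single_site
#' @return data frame with `position`, `call`, `flags`.
#' @export
decode_single <- function(deam_pileup, ctrl_pileup, fourtri_pileup = NULL,
                          dominance = 0.7, min_depth = 20L,
                          p_signature = c(a_lo = 0.35, a_hi = 0.85,
                                          ag_min = 0.9)) {
  stopifnot(inherits(deam_pileup, "pileup_table"),
            inherits(ctrl_pileup, "pileup_table"))
  if (deam_pileup$length != ctrl_pileup$length) {
    stop("deaminated and control pileups must cover the same amplicon",
         call. = FALSE)
  }
  fd <- pileup_fractions(deam_pileup)
  fc <- pileup_fractions(ctrl_pileup)
  ff <- if (!is.null(fourtri_pileup)) pileup_fractions(fourtri_pileup)
  calls <- lapply(seq_len(deam_pileup$length), function(i) {
    if (deam_pileup$depth[i] < min_depth || ctrl_pileup$depth[i] < min_depth) {
      return(.site_call(i, "AMBIGUOUS",
                        list(deaminated = fd[, i], control = fc[, i]),
                        "low_depth"))
    }
    decode_single_site(fd[, i], fc[, i],
                       fourtri_frac = if (!is.null(ff)) ff[, i],
                       dominance = dominance, p_signature = p_signature,
                       position = i)
  })
  .calls_frame(calls)
}

#' Collapse a call table to a sequence string
#'
#' @param calls data frame from [decode_duplex()] or [decode_single()].
#' @param ambiguous character used for `AMBIGUOUS` positions (default
#'   `"."`, which is outside the alphabet so unresolved sites stay
#'   visible).
#' @return character string.
#' @export
decoded_string <- function(calls, ambiguous = ".") {
  out <- calls$call
  out[out == "AMBIGUOUS"] <- ambiguous
  paste(out, collapse = "")
}

#' Transliteration composition by original base class
#'
#' For each original-base class (A, T, C, G, Z, P) of the template, the
#' depth-weighted mean distribution of product bases across that class's
#' positions, with the across-position standard deviation.  Primer-region
#' positions should be excluded via `exclude` (see [primer_flanks()]);
#' classes with no remaining positions are omitted.
#'
#' @param pileup a [pileup_table] aligned to `template`.
#' @param template the originating [expanded_seq].
#' @param exclude integer positions to drop (e.g. primer regions).
#' @param exclude_ambiguous drop the `other` bucket from denominators.
#' @return data frame with `class`, `product`, `fraction`, `sd`,
#'   `n_positions`.
#' @export
composition_table <- function(pileup, template, exclude = integer(0),
                              exclude_ambiguous = FALSE) {
  stopifnot(inherits(pileup, "pileup_table"))
  tch <- .chars(.seq_string(template))
  if (length(tch) != pileup$length) {
    stop("pileup and template lengths differ", call. = FALSE)
  }
  fr <- pileup_fractions(pileup, exclude_ambiguous = exclude_ambiguous)
  keep <- setdiff(seq_along(tch), exclude)
  out <- list()
  for (cls in c("A", "T", "C", "G", "Z", "P")) {
    pos <- keep[tch[keep] == cls]
    pos <- pos[pileup$depth[pos] > 0]
    if (length(pos) == 0L) next
    w <- pileup$depth[pos] / sum(pileup$depth[pos])
    sub <- fr[PRODUCT_BASES, pos, drop = FALSE]
    mean_fr <- as.vector(sub %*% w)
    sd_fr <- apply(sub, 1L, function(x) if (length(x) > 1L) stats::sd(x)
                   else NA_real_)
    out[[cls]] <- data.frame(class = cls, product = PRODUCT_BASES,
                             fraction = mean_fr, sd = unname(sd_fr),
                             n_positions = length(pos),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sequence-logo matrix of a pileup
#'
#' Per-position product-base frequencies (normalised over A,C,G,T) and
#' information content in bits, `2 - H` with `H` the Shannon entropy
#' (log2).  Information content always lies in \[0, 2\].
#'
#' @param pileup a [pileup_table].
#' @return list of class `logo_matrix` with `freq` (4 x L matrix) and
#'   `info` (numeric vector, bits); zero-depth positions are `NA`.
#' @examples
#' p <- build_pileup(c("AC", "AG"))
#' logo_matrix(p)$info  # 2 bits, 1 bit
#' @export
logo_matrix <- function(pileup) {
  stopifnot(inherits(pileup, "pileup_table"))
  fr <- pileup_fractions(pileup, exclude_ambiguous = TRUE)
  info <- apply(fr, 2L, function(p) {
    if (any(is.na(p))) return(NA_real_)
    nz <- p[p > 0]
    2 + sum(nz * log2(nz))
  })
  structure(list(freq = fr, info = info), class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("<logo_matrix> %d positions, mean information %.3f bits\n",
              ncol(x$freq), mean(x$info, na.rm = TRUE)))
  invisible(x)
}
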