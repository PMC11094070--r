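# Forward model of the transliteration chemistry.
#
# A molecule moves through up to four stages, in the order they occur at
# the bench:
#   1. Z:P loss during 6-triphosphate PCR: each Z/P site survives all d
#      copying events with probability f^d; a lost pair becomes C:G
#      (C at a former-Z, G at a former-P position).
#   2. Cytidine deamination: every C (including C created by loss in stage
#      1, since deamination acts on the amplicon) becomes U with the given
#      efficiency.  Z and all other letters are untouched.
#   3. Transliterative PCR readout: each letter is replaced by a product
#      base drawn from its conversion-profile row (U reads T, retained Z
#      reads C, retained P reads G).
#   4. Sequencing: i.i.d. substitution errors.
# The per-read independent f^d approximation replaces a full amplification
# tree: population fractions, which are all the pileup statistics see, are
# identical under both, and lineage ("jackpot") correlation is invisible at
# that resolution.

#' Deaminate cytidines in a single strand
#'
#' Each C independently becomes U with probability `efficiency`; all other
#' letters (including Z) are untouched.
#'
#' @param s [expanded_seq] or string.
#' @param efficiency conversion probability in \[0, 1\] (default 1: the
#'   enzymatic conversion is complete at the tested sites).
#' @return same type as `s`, with C positions stochastically replaced by U.
#' @examples
#' deaminate("AGCT")  # "AGUT"
#' @export
deaminate <- function(s, efficiency = 1) {
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1) {
    stop("`efficiency` must lie in [0, 1]", call. = FALSE)
  }
  str <- .seq_string(s)
  ch <- .chars(str)
  .check_alphabet(ch)
  hit <- ch == "C" & stats::runif(length(ch)) < efficiency
  ch[hit] <- "U"
  out <- paste(ch, collapse = "")
  if (is_expanded_seq(s)) expanded_seq(s$name, out, strand = s$strand,
                                       note = s$note) else out
}

#' Expected (most probable) transliteration of a sequence
#'
#' Deterministic mode of the forward model: every letter is replaced by the
#' most probable product base of its profile row.  Standard bases map to
#' themselves, U to T.  Used to build alignment scaffolds and reference
#' strings.
#'
#' @param s [expanded_seq] or string (N not allowed: instantiate first).
#' @param profile a [conversion_profile].
#' @return four-letter character string.
#' @examples
#' transliterate_expected("GAZP", conversion_preset("5tri"))
#' @export
transliterate_expected <- function(s, profile) {
  stopifnot(inherits(profile, "conversion_profile"))
  str <- .seq_string(s)
  if (nchar(str) == 0L) return("")
  ch <- .chars(str)
  .check_alphabet(ch, allow = setdiff(XNA_LETTERS, "N"))
  out <- character(length(ch))
  for (letter in unique(ch)) {
    row <- .profile_row(profile, letter)
    out[ch == letter] <- PRODUCT_BASES[which.max(row)]
  }
  paste(out, collapse = "")
}

# Vectorised simulation of m product molecules from one template.
# Returns the product character matrix plus per-read truth: Z/P retention
# flags and instantiated N letters.
.simulate_block <- function(tchars, m, profile, deaminate = FALSE,
                            efficiency = 1, doublings = 0L,
                            seq_error_rate = 0) {
  L <- length(tchars)
  mat <- matrix(rep(tchars, each = m), nrow = m, ncol = L)

  inst <- NULL
  ncols <- which(tchars == "N")
  if (length(ncols) > 0L) {
    inst <- matrix(sample(PRODUCT_BASES, m * length(ncols), replace = TRUE),
                   nrow = m)
    colnames(inst) <- ncols
    mat[, ncols] <- inst
  }

  # KOD-style misincorporation: a template G can acquire a Z (reads C)
  if (profile$z_misincorporation > 0) {
    gcols <- which(tchars == "G")
    if (length(gcols) > 0L) {
      hit <- matrix(stats::runif(m * length(gcols)) <
                      profile$z_misincorporation, nrow = m)
      sub <- mat[, gcols, drop = FALSE]
      sub[hit] <- "Z"
      mat[, gcols] <- sub
    }
  }

  retained <- NULL
  zpcols <- which(tchars %in% c("Z", "P"))
  if (length(zpcols) > 0L) {
    f <- profile$per_cycle_zp_fidelity
    if (!is.na(f) && doublings > 0L) {
      p_ret <- f^doublings
      retained <- matrix(stats::runif(m * length(zpcols)) < p_ret, nrow = m)
    } else {
      retained <- matrix(TRUE, nrow = m, ncol = length(zpcols))
    }
    colnames(retained) <- zpcols
    for (j in seq_along(zpcols)) {
      lost <- !retained[, j]
      if (any(lost)) {
        mat[lost, zpcols[j]] <- if (tchars[zpcols[j]] == "Z") "C" else "G"
      }
    }
  }

  if (deaminate) {
    hit <- mat == "C" & stats::runif(m * L) < efficiency
    mat[hit] <- "U"
  }

  out <- mat
  for (letter in intersect(c("A", "C", "G", "T", "U", "Z", "P"),
                           unique(as.vector(mat)))) {
    idx <- which(mat == letter)
    row <- .profile_row(profile, letter)
    if (max(row) == 1) {
      out[idx] <- PRODUCT_BASES[which.max(row)]
    } else {
      out[idx] <- sample(PRODUCT_BASES, length(idx), replace = TRUE,
                         prob = row)
    }
  }

  if (seq_error_rate > 0) {
    idx <- which(stats::runif(m * L) < seq_error_rate)
    if (length(idx) > 0L) {
      code <- match(out[idx], PRODUCT_BASES)
      out[idx] <- PRODUCT_BASES[(code - 1L +
                                 sample.int(3L, length(idx), replace = TRUE)) %% 4L + 1L]
    }
  }

  list(mat = out, retained = retained, inst = inst)
}

#' Simulate one product molecule
#'
#' Runs a single template strand through the forward model (Z:P loss over
#' `doublings` copying events, optional deamination, profile-row draws,
#' substitution errors) and returns the four-letter product.  The logical
#' attribute `"retained"` (named by 1-based position) records which Z/P
#' sites survived.
#'
#' @param s [expanded_seq] or string (N positions are instantiated
#'   uniformly at random).
#' @param profile a [conversion_profile].
#' @param doublings number of nominal population doublings d; a Z/P site is
#'   retained with probability `f^d` where `f` is the profile's per-cycle
#'   fidelity.  With `d = 0` retention probability is 1.
#' @param deaminate run the deamination stage first (as in the
#'   sequencing readout of amplicons).
#' @param efficiency deamination efficiency.
#' @param seq_error_rate per-base substitution probability.
#' @return four-letter string with attribute `"retained"`.
#' @export
simulate_molecule <- function(s, profile, doublings = 0L, deaminate = FALSE,
                              efficiency = 1, seq_error_rate = 0) {
  stopifnot(inherits(profile, "conversion_profile"))
  if (doublings < 0L) stop("`doublings` must be >= 0", call. = FALSE)
  tchars <- .chars(.seq_string(s))
  .check_alphabet(tchars)
  blk <- .simulate_block(tchars, 1L, profile, deaminate = deaminate,
                         efficiency = efficiency, doublings = doublings,
                         seq_error_rate = seq_error_rate)
  out <- paste(blk$mat[1L, ], collapse = "")
  if (!is.null(blk$retained)) {
    ret <- blk$retained[1L, ]
    names(ret) <- colnames(blk$retained)
    attr(out, "retained") <- ret
  }
  out
}

#' Simulation run configuration
#'
#' Bundles everything needed to generate a reproducible FASTQ: the template
#' mixture, the chemistry (profile, deamination, doublings), the sequencer
#' (read count, substitution error rate) and the library structure (8-base
#' inline barcode).
#'
#' @param templates an [expanded_seq] or list of them.
#' @param fractions mixture fractions (non-negative, summing to 1); default
#'   equal.
#' @param profile a [conversion_profile].
#' @param deaminate logical: run the deamination stage.
#' @param deamination_efficiency per-C conversion probability.
#' @param doublings nominal doublings for the Z:P loss stage.
#' @param n_reads number of reads to emit.
#' @param seq_error_rate per-base substitution probability (default 1e-3).
#' @param barcode 8-base inline barcode prepended to every read.
#' @param seed integer seed; identical seed and config give byte-identical
#'   FASTQ.
#' @return object of class `sim_run_config`.
#' @export
sim_run_config <- function(templates, fractions = NULL, profile,
                           deaminate = FALSE, deamination_efficiency = 1,
                           doublings = 0L, n_reads,
                           seq_error_rate = 0.001, barcode = "ACGTTGCA",
                           seed = NULL) {
  if (is_expanded_seq(templates)) templates <- list(templates)
  if (length(templates) == 0L) stop("empty template list", call. = FALSE)
  stopifnot(all(vapply(templates, is_expanded_seq, TRUE)))
  if (is.null(fractions)) fractions <- rep(1 / length(templates),
                                           length(templates))
  if (length(fractions) != length(templates) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be non-negative and sum to 1, one per template",
         call. = FALSE)
  }
  stopifnot(inherits(profile, "conversion_profile"))
  if (nchar(barcode) != 8L) {
    stop("`barcode` must be an 8-base string", call. = FALSE)
  }
  .check_alphabet(.chars(toupper(barcode)), allow = c("A", "C", "G", "T"),
                  what = "barcode")
  if (n_reads < 0L) stop("`n_reads` must be >= 0", call. = FALSE)
  structure(list(templates = templates, fractions = fractions,
                 profile = profile, deaminate = isTRUE(deaminate),
                 deamination_efficiency = deamination_efficiency,
                 doublings = as.integer(doublings),
                 n_reads = as.integer(n_reads),
                 seq_error_rate = seq_error_rate,
                 barcode = toupper(barcode),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_run_config")
}

#' Generate simulated FASTQ reads with ground truth
#'
#' Draws each read's template by mixture fraction, instantiates N positions
#' uniformly at random per molecule, runs the forward model, and prepends
#' the inline barcode.  Substitution errors apply to the product sequence
#' (the barcode is emitted clean; barcode errors are exercised separately
#' through [filter_barcode()]).  The truth sidecar records, per read, the
#' source template, the Z/P retention flags (`"1"`/`"0"` per site, in
#' template order) and the instantiated N letters.
#'
#' @param cfg a [sim_run_config].
#' @return list with `reads` (data frame `id`, `sequence`, `quality`) and
#'   `truth` (data frame `id`, `template`, `retained`, `n_bases`).
#' @export
generate_reads <- function(cfg) {
  stopifnot(inherits(cfg, "sim_run_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_reads
  k <- length(cfg$templates)
  tpl_idx <- if (k == 1L) rep(1L, n) else {
    sample.int(k, n, replace = TRUE, prob = cfg$fractions)
  }
  tpl_names <- vapply(cfg$templates, `[[`, "", "name")

  seqs <- character(n)
  retained <- rep(NA_character_, n)
  n_bases <- rep(NA_character_, n)
  for (j in seq_len(k)) {
    rows <- which(tpl_idx == j)
    m <- length(rows)
    if (m == 0L) next
    tchars <- .chars(cfg$templates[[j]]$bases)
    blk <- .simulate_block(tchars, m, cfg$profile,
                           deaminate = cfg$deaminate,
                           efficiency = cfg$deamination_efficiency,
                           doublings = cfg$doublings,
                           seq_error_rate = cfg$seq_error_rate)
    seqs[rows] <- do.call(paste0, lapply(seq_len(ncol(blk$mat)),
                                         function(c) blk$mat[, c]))
    if (!is.null(blk$retained)) {
      flag <- ifelse(blk$retained, "1", "0")
      retained[rows] <- do.call(paste0, lapply(seq_len(ncol(flag)),
                                               function(c) flag[, c]))
    }
    if (!is.null(blk$inst)) {
      n_bases[rows] <- do.call(paste0, lapply(seq_len(ncol(blk$inst)),
                                              function(c) blk$inst[, c]))
    }
  }

  ids <- sprintf("read%07d", seq_len(n))
  reads <- data.frame(
    id = ids,
    sequence = paste0(cfg$barcode, seqs),
    quality = strrep("I", nchar(cfg$barcode) + nchar(seqs)),
    stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, template = tpl_names[tpl_idx],
                      retained = retained, n_bases = n_bases,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}
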