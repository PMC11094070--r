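# Quantitative fidelity machinery: Z:P retention, nominal doublings,
# per-cycle fidelity, mixture-series calibration, flanking-context bias.

#' Per-site Z retention from a deaminated-arm pileup
#'
#' At a position that originally held Z, a retained Z reads C in the
#' deaminated 5-triphosphate readout while a lost Z (converted to C during
#' six-nucleotide PCR) is deaminated and reads T.  Retention at site i is
#' therefore the C fraction among covering reads; the overall value is the
#' depth-weighted mean.  For the antisense arm pass the sense template with
#' `strand_role = "antisense"`: its Z sites are the former P sites of the
#' sense strand, so sense P retention is measured from the antisense arm.
#'
#' @param pileup deaminated-arm [pileup_table] in the sequenced strand's
#'   coordinates.
#' @param template the sense-strand [expanded_seq].
#' @param strand_role which strand the pileup reads came from.
#' @param doublings optional nominal doublings d; when given, the per-cycle
#'   fidelity `overall^(1/d)` is included.
#' @param denominator `"all"` counts every covering read; `"acgt"`
#'   restricts to unambiguous bases.
#' @return object of class `retention_result`: `per_site` (data frame
#'   `position`, `original`, `retention`, `depth`), `overall`, `doublings`,
#'   `per_cycle_fidelity`.  A template without Z sites on the sequenced
#'   strand gives an empty `per_site` and `NA` overall, with a note.
#' @export
retention <- function(pileup, template,
                      strand_role = c("sense", "antisense"),
                      doublings = NULL, denominator = c("all", "acgt")) {
  strand_role <- match.arg(strand_role)
  denominator <- match.arg(denominator)
  stopifnot(inherits(pileup, "pileup_table"))
  strand <- if (strand_role == "sense") .seq_string(template) else
    reverse_complement(.seq_string(template))
  tch <- .chars(strand)
  if (length(tch) != pileup$length) {
    stop("pileup and template lengths differ", call. = FALSE)
  }
  sites <- which(tch == "Z")
  if (length(sites) == 0L) {
    res <- structure(list(per_site = data.frame(position = integer(0),
                                                original = character(0),
                                                retention = numeric(0),
                                                depth = integer(0)),
                          overall = NA_real_, doublings = doublings,
                          per_cycle_fidelity = NA_real_,
                          note = "template has no Z sites on this strand"),
                     class = "retention_result")
    return(res)
  }
  denom <- if (denominator == "all") pileup$depth[sites] else
    colSums(pileup$counts[PRODUCT_BASES, sites, drop = FALSE])
  r <- ifelse(denom > 0, pileup$counts["C", sites] / denom, NA_real_)
  overall <- sum(r * denom, na.rm = TRUE) / sum(denom[!is.na(r)])
  f <- if (!is.null(doublings) && doublings >= 1L && !is.na(overall) &&
           overall > 0) {
    per_cycle_fidelity(overall, doublings)
  } else NA_real_
  structure(list(per_site = data.frame(position = sites,
                                       original = tch[sites],
                                       retention = as.numeric(r),
                                       depth = as.integer(denom)),
                 overall = overall, doublings = doublings,
                 per_cycle_fidelity = f, note = NULL),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  if (!is.null(x$note)) {
    cat("<retention_result>", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("<retention_result> overall %.4f over %d site(s)\n",
              x$overall, nrow(x$per_site)))
  if (!is.na(x$per_cycle_fidelity)) {
    cat(sprintf("  per-cycle fidelity %.4f over %d doublings\n",
                x$per_cycle_fidelity, x$doublings))
  }
  invisible(x)
}

#' Nominal doublings from a primer:template ratio
#'
#' The template population can double roughly `log2(ratio)` times before
#' primer exhaustion; the value is rounded half-up (50,000:1 gives
#' `log2 = 15.61`, reported as 16).
#'
#' @param primer_to_template_ratio ratio, at least 1.
#' @return integer doublings.
#' @examples
#' nominal_doublings(50000)  # 16
#' @export
nominal_doublings <- function(primer_to_template_ratio) {
  if (!is.numeric(primer_to_template_ratio) ||
      primer_to_template_ratio < 1) {
    stop("`primer_to_template_ratio` must be >= 1", call. = FALSE)
  }
  as.integer(floor(log2(primer_to_template_ratio) + 0.5))
}

#' Per-cycle fidelity from overall retention, and its inverse
#'
#' A Z:P pair surviving each of `d` copying events independently with
#' probability `f` is retained overall with probability `f^d`; hence
#' `f = R^(1/d)`.  The two functions are exact inverses.
#'
#' @param R overall retention in (0, 1].
#' @param d nominal doublings, at least 1.
#' @return per-cycle fidelity `f`.
#' @examples
#' round(100 * per_cycle_fidelity(0.90, 16), 2)  # 99.34
#' @export
per_cycle_fidelity <- function(R, d) {
  if (!is.numeric(R) || R <= 0 || R > 1) {
    stop("`R` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(d) || d < 1) stop("`d` must be >= 1", call. = FALSE)
  R^(1 / d)
}

#' @rdname per_cycle_fidelity
#' @param f per-cycle fidelity in \[0, 1\].
#' @export
expected_retention <- function(f, d) {
  if (!is.numeric(f) || f < 0 || f > 1) {
    stop("`f` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(d) || d < 0) stop("`d` must be >= 0", call. = FALSE)
  f^d
}

#' Fit the mixture-series calibration line
#'
#' Ordinary least squares of observed percentage on prepared percentage,
#' `Y = aX + b`.  The measured series on prepared AEGIS fractions of
#' 10-90% gave `Y = 0.984X - 4.601`; [apply_calibration()] inverts the
#' line to correct an observed percentage back to the prepared scale.
#'
#' @param prepared_x prepared percentages (at least two distinct values).
#' @param observed_y observed percentages.
#' @return object of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @examples
#' fit_calibration(c(10, 50, 90), c(5.24, 44.6, 83.96))
#' @export
fit_calibration <- function(prepared_x, observed_y) {
  if (length(prepared_x) != length(observed_y)) {
    stop("`prepared_x` and `observed_y` lengths differ", call. = FALSE)
  }
  if (length(unique(prepared_x)) < 2L) {
    stop("singular fit: need at least two distinct prepared values",
         call. = FALSE)
  }
  fit <- stats::lm(observed_y ~ prepared_x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((observed_y - mean(observed_y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = length(prepared_x)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> Y = %.4fX %+.4f (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_calibration
#' @param fit a `calibration_fit` (or list with `slope` and `intercept`).
#' @return corrected prepared-scale values `(Y - b) / a`.
#' @export
apply_calibration <- function(fit, observed_y) {
  (observed_y - fit$intercept) / fit$slope
}

#' Flanking-context bias of a conversion
#'
#' For reads aligned over a randomised-context cassette, extracts the k
#' left and k right flanking bases around the focal position and tabulates,
#' per (left, right) context, how many reads carry the expected converted
#' base (C to T, Z to C, or P to G depending on the run).  A chi-square
#' test of homogeneity across contexts is reported, not thresholded.
#'
#' @param seqs character vector of reads in template coordinates (all
#'   covering `focal` with k bases to spare on both sides).
#' @param focal 1-based focal position.
#' @param expected expected product base at the focal position.
#' @param k flank width, 1, 2 or 3.
#' @return object of class `context_bias`: `table` (data frame `left`,
#'   `right`, `n`, `n_expected`, `frac_expected`), `statistic`, `p_value`,
#'   `k`, `focal`, `expected`.
#' @export
context_bias <- function(seqs, focal, expected, k = 1L) {
  if (!k %in% 1:3) stop("`k` must be 1, 2 or 3", call. = FALSE)
  if (focal - k < 1L || any(focal + k > nchar(seqs))) {
    stop("reads do not cover the focal position with k flanking bases",
         call. = FALSE)
  }
  left <- substr(seqs, focal - k, focal - 1L)
  right <- substr(seqs, focal + 1L, focal + k)
  hit <- substr(seqs, focal, focal) == toupper(expected)
  agg <- stats::aggregate(cbind(n = rep(1L, length(seqs)),
                                n_expected = as.integer(hit)),
                          by = list(left = left, right = right), FUN = sum)
  agg <- agg[order(agg$left, agg$right), , drop = FALSE]
  agg$frac_expected <- agg$n_expected / agg$n
  rownames(agg) <- NULL
  test <- if (nrow(agg) >= 2L) {
    suppressWarnings(stats::chisq.test(cbind(agg$n_expected,
                                             agg$n - agg$n_expected)))
  } else NULL
  structure(list(table = agg,
                 statistic = if (!is.null(test)) unname(test$statistic)
                 else NA_real_,
                 p_value = if (!is.null(test)) test$p.value else NA_real_,
                 k = as.integer(k), focal = as.integer(focal),
                 expected = toupper(expected)),
            class = "context_bias")
}

#' @export
print.context_bias <- function(x, ...) {
  cat(sprintf("<context_bias> k=%d around position %d (expected %s): %d contexts, chi-square p = %.3g\n",
              x$k, x$focal, x$expected, nrow(x$table), x$p_value))
  invisible(x)
}
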