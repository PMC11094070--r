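# Conversion profiles: the forward model of transliteration.
#
# A profile maps each template letter to a probability distribution over the
# four sequencer-readable product bases, for one PCR chemistry condition.
# The shipped presets carry the measured transliteration percentages:
#   * 4-triphosphate PCR (dNTPs only): Z -> C via the deprotonated Z-:G
#     mismatch (>99%); P has no Watson-Crick partner and is read as a
#     mixture of A (~63%) and G (~37%).
#   * 5-triphosphate PCR (+dZTP): P pairs Z in the first round and is then
#     transliterated almost exclusively to G (~94.5%); Z -> C as before.
#   * 6-triphosphate PCR (+dZTP+dPTP): the Z:P pair is replicated as such
#     with a per-cycle fidelity f; a lost pair becomes C:G.  Product rows
#     are those of the 5-triphosphate readout.

PRODUCT_BASES <- c("A", "C", "G", "T")

#' Conversion profile for one chemistry condition
#'
#' @param condition_id identifier.
#' @param matrix numeric matrix, one row per template letter (subset of
#'   A,C,G,T,U,Z,P), columns `A,C,G,T`; each row a probability distribution.
#' @param triphosphates `"4tri"`, `"5tri"` or `"6tri"`.
#' @param per_cycle_zp_fidelity probability that a Z:P pair survives one
#'   copying event (6tri only; `NA` otherwise).
#' @param z_misincorporation probability that a template G acquires a Z
#'   (reading as C downstream); models the behaviour seen with KOD exo-.
#' @param ph_label,dptp_label condition labels (no mechanistic model of pH
#'   or dPTP concentration is attempted; they select measured profiles).
#' @return object of class `conversion_profile`.
#' @export
conversion_profile <- function(condition_id, matrix,
                               triphosphates = c("5tri", "4tri", "6tri"),
                               per_cycle_zp_fidelity = NA_real_,
                               z_misincorporation = 0,
                               ph_label = "", dptp_label = "") {
  triphosphates <- match.arg(triphosphates)
  stopifnot(is.matrix(matrix), identical(colnames(matrix), PRODUCT_BASES))
  if (!all(rownames(matrix) %in% c("A", "C", "G", "T", "U", "Z", "P"))) {
    stop("profile rows must be template letters A,C,G,T,U,Z,P", call. = FALSE)
  }
  if (any(matrix < 0) || any(matrix > 1)) {
    stop("profile probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    stop("each profile row must sum to 1", call. = FALSE)
  }
  if (!is.na(per_cycle_zp_fidelity) &&
      (per_cycle_zp_fidelity < 0 || per_cycle_zp_fidelity > 1)) {
    stop("`per_cycle_zp_fidelity` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(condition_id = condition_id, matrix = matrix,
                 triphosphates = triphosphates,
                 per_cycle_zp_fidelity = per_cycle_zp_fidelity,
                 z_misincorporation = z_misincorporation,
                 ph_label = ph_label, dptp_label = dptp_label),
            class = "conversion_profile")
}

.profile_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- PRODUCT_BASES
  m
}

#' Shipped chemistry presets
#'
#' Transliteration profiles with the measured defaults: Z->C at 0.99
#' (reported as >99%), P->\{A:0.63, G:0.37\} under 4-triphosphate PCR,
#' P->G at 0.945 under 5-triphosphate PCR (residual split between A and T
#' in the 63:37 A-heavy ratio seen under 4tri; the residual breakdown is a
#' configurable choice, not a measured value), and for the 6-triphosphate
#' condition a per-cycle Z:P fidelity of 0.9934 at pH 8.0 / 0.5 mM dPTP.
#' Standard bases always map to themselves and U to T.
#'
#' With `exact = TRUE` the near-unity conversions (Z->C, and P->G under
#' 5tri) are snapped to 1, giving a noiseless chemistry for round-trip
#' checks; the 4tri P mixture is left untouched because the mixture *is*
#' the mechanism there.
#'
#' @param kind `"4tri"`, `"5tri"` or `"6tri"`.
#' @param ph,dptp condition labels; the only measured 6tri fidelity preset
#'   is pH `"8.0"` at `"0.5 mM"` dPTP.
#' @param fidelity override for the per-cycle Z:P fidelity (required for
#'   6tri label combinations without a shipped value).
#' @param z_to_c,p_to_g_5tri,p_to_a_4tri tunable conversion rates.
#' @param exact snap near-unity conversions to 1.
#' @return a [conversion_profile].
#' @examples
#' conversion_preset("5tri")$matrix["P", ]
#' @export
conversion_preset <- function(kind = c("5tri", "4tri", "6tri"),
                              ph = "8.9", dptp = NULL, fidelity = NULL,
                              z_to_c = 0.99, p_to_g_5tri = 0.945,
                              p_to_a_4tri = 0.63, exact = FALSE) {
  kind <- match.arg(kind)
  if (exact) z_to_c <- 1
  std <- list(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
              G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
              U = c(0, 0, 0, 1))
  zrow <- c(0, z_to_c, 0, 1 - z_to_c)  # residual Z fate: T (pyrimidine)
  if (kind == "4tri") {
    prow <- c(p_to_a_4tri, 0, 1 - p_to_a_4tri, 0)
  } else {
    if (exact) p_to_g_5tri <- 1
    resid <- 1 - p_to_g_5tri
    prow <- c(resid * p_to_a_4tri, 0, p_to_g_5tri, resid * (1 - p_to_a_4tri))
  }
  f <- NA_real_
  if (kind == "6tri") {
    if (!is.null(fidelity)) {
      f <- fidelity
    } else if (identical(ph, "8.0") && identical(dptp, "0.5 mM")) {
      f <- 0.9934
    } else {
      stop(paste("no shipped per-cycle fidelity for this 6tri condition;",
                 "supply `fidelity`"), call. = FALSE)
    }
  }
  conversion_profile(
    condition_id = paste0(kind, "_pH", ph,
                          if (!is.null(dptp)) paste0("_dPTP", gsub(" ", "", dptp)) else ""),
    matrix = .profile_matrix(c(std, list(Z = zrow, P = prow))),
    triphosphates = kind, per_cycle_zp_fidelity = f,
    ph_label = ph, dptp_label = if (is.null(dptp)) "" else dptp)
}

#' @export
print.conversion_profile <- function(x, ...) {
  cat(sprintf("<conversion_profile> %s (%s)\n", x$condition_id,
              x$triphosphates))
  print(round(x$matrix, 4))
  if (!is.na(x$per_cycle_zp_fidelity)) {
    cat(sprintf("  per-cycle Z:P fidelity: %.4f\n", x$per_cycle_zp_fidelity))
  }
  invisible(x)
}

.profile_row <- function(profile, letter) {
  if (!letter %in% rownames(profile$matrix)) {
    stop(sprintf("profile '%s' has no row for template letter '%s'",
                 profile$condition_id, letter), call. = FALSE)
  }
  profile$matrix[letter, ]
}
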