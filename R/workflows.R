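# End-to-end glue: simulate -> filter -> align -> pileup -> decode, plus a
# manifest-driven workflow runner used by the command-line wrapper.

#' Pileup an amplicon run against its expected scaffold
#'
#' Builds the alignment scaffold as the expected transliteration of the
#' (optionally deaminated) template, places every read with the anchored
#' ungapped aligner, and accumulates the pileup.  Input reads may already
#' be barcode-trimmed (`barcode = NULL`) or carry the inline barcode.
#'
#' @param reads data frame (`id`, `sequence`, `quality`), character vector
#'   of sequences, or path to a FASTQ file.
#' @param template the originating [expanded_seq] (strand as sequenced).
#' @param profile the run's [conversion_profile].
#' @param deaminated whether the run was deaminated (determines the
#'   scaffold's C positions).
#' @param barcode inline barcode to filter/trim, or `NULL`.
#' @param max_mismatch_frac aligner acceptance threshold.
#' @return a [pileup_table]; attributes `n_input`, `n_barcode_kept`,
#'   `n_aligned` record filter attrition.
#' @export
amplicon_pileup <- function(reads, template, profile, deaminated = FALSE,
                            barcode = NULL, max_mismatch_frac = 0.4) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(reads)) {
    reads <- data.frame(id = seq_along(reads), sequence = reads,
                        quality = strrep("I", nchar(reads)),
                        stringsAsFactors = FALSE)
  }
  n_input <- nrow(reads)
  if (!is.null(barcode)) {
    reads <- filter_barcode(reads, barcode)$kept
  }
  n_bc <- nrow(reads)
  tmpl <- if (deaminated) {
    # deaminated-arm scaffold: original C reads T, retained Z still reads C
    transliterate_expected(chartr("C", "U", .seq_string(template)), profile)
  } else {
    transliterate_expected(template, profile)
  }
  aln <- .align_many(reads$sequence, tmpl,
                     max_mismatch_frac = max_mismatch_frac)
  acc <- aln[aln$accepted, c("sequence", "offset"), drop = FALSE]
  p <- build_pileup(acc, length = nchar(tmpl),
                    template_id = if (is_expanded_seq(template))
                      template$name else "")
  attr(p, "n_input") <- n_input
  attr(p, "n_barcode_kept") <- n_bc
  attr(p, "n_aligned") <- nrow(acc)
  p
}

#' Simulate an amplicon run and return its pileup
#'
#' Convenience wrapper chaining [generate_reads()], [filter_barcode()] and
#' [amplicon_pileup()] for one template.
#'
#' @inheritParams sim_run_config
#' @param template an [expanded_seq].
#' @param ... passed to [sim_run_config()] (e.g. `doublings`,
#'   `deamination_efficiency`).
#' @return a [pileup_table].
#' @export
simulate_pileup <- function(template, profile, n_reads, deaminate = FALSE,
                            seq_error_rate = 0, seed = NULL, ...) {
  cfg <- sim_run_config(templates = template, profile = profile,
                        deaminate = deaminate, n_reads = n_reads,
                        seq_error_rate = seq_error_rate, seed = seed, ...)
  gr <- generate_reads(cfg)
  amplicon_pileup(gr$reads, template, profile, deaminated = cfg$deaminate,
                  barcode = cfg$barcode)
}

.as_profile <- function(p) {
  if (inherits(p, "conversion_profile")) return(p)
  do.call(conversion_preset, p)
}

.template_from <- function(inputs, params) {
  tpls <- if (!is.null(inputs$templates)) read_templates(inputs$templates)
  else aegis_templates()
  nm <- params$template
  if (is.null(nm)) stop("manifest must name a `template`", call. = FALSE)
  if (!nm %in% names(tpls)) {
    stop(sprintf("template '%s' not found", nm), call. = FALSE)
  }
  tpls[[nm]]
}

#' Run a manifest-described workflow
#'
#' A manifest is a list with `workflow` (one of `simulate`, `decode-ss`,
#' `decode-ds`, `retention`, `calibrate`, `digest`), an `inputs` list of
#' file paths, a `params` list, an optional `seed`, and `out_dir`.  Inputs
#' are validated before anything is written; outputs are staged in a
#' temporary directory and moved into `out_dir` together with
#' `manifest.json` only on success, so a failing stage leaves no partial
#' outputs.  Filter attrition (barcode, alignment) is reported via
#' `message()`.
#'
#' @param manifest the manifest list.
#' @return named character vector of written artifact paths, invisibly.
#' @export
run_workflow <- function(manifest) {
  stopifnot(is.list(manifest), !is.null(manifest$workflow),
            !is.null(manifest$out_dir))
  wf <- manifest$workflow
  inputs <- manifest$inputs %||% list()
  params <- manifest$params %||% list()
  for (p in unlist(inputs)) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  stage <- tempfile("esega_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  emit <- function(name) file.path(stage, name)

  written <- switch(
    wf,
    "simulate" = {
      tpls <- if (!is.null(inputs$templates)) read_templates(inputs$templates)
      else aegis_templates()
      nms <- params$templates %||% names(tpls)[1L]
      fractions <- params$fractions %||% rep(1 / length(nms), length(nms))
      cfg <- sim_run_config(
        templates = tpls[nms], fractions = fractions,
        profile = .as_profile(params$profile %||% list(kind = "5tri")),
        deaminate = params$deaminate %||% FALSE,
        deamination_efficiency = params$deamination_efficiency %||% 1,
        doublings = params$doublings %||% 0L,
        n_reads = params$n_reads %||% 1000L,
        seq_error_rate = params$seq_error_rate %||% 0.001,
        barcode = params$barcode %||% "ACGTTGCA",
        seed = manifest$seed)
      gr <- generate_reads(cfg)
      write_fastq(gr$reads, emit("reads.fastq"))
      utils::write.table(gr$truth, emit("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      message(sprintf("simulate: %d reads from %s", nrow(gr$reads),
                      paste(nms, collapse = "+")))
      c("reads.fastq", "truth.tsv")
    },
    "decode-ds" = {
      tpl <- .template_from(inputs, params)
      profile <- .as_profile(params$profile %||% list(kind = "5tri"))
      bc <- params$barcode %||% NULL
      ps <- amplicon_pileup(inputs$sense_fastq, tpl, profile,
                            deaminated = TRUE, barcode = bc)
      pa <- amplicon_pileup(inputs$anti_fastq, reverse_complement(tpl),
                            profile, deaminated = TRUE, barcode = bc)
      message(sprintf("decode-ds: sense %d/%d aligned, antisense %d/%d",
                      attr(ps, "n_aligned"), attr(ps, "n_input"),
                      attr(pa, "n_aligned"), attr(pa, "n_input")))
      calls <- decode_duplex(ps, pa,
                             dominance = params$dominance %||% 0.7,
                             min_depth = params$min_depth %||% 20L)
      utils::write.table(calls, emit("calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      dec <- decoded_string(calls)
      writeLines(c(paste0(">", tpl$name, "_decoded"), dec),
                 emit("decoded.fasta"))
      c("calls.tsv", "decoded.fasta")
    },
    "decode-ss" = {
      tpl <- .template_from(inputs, params)
      p5 <- .as_profile(params$profile %||% list(kind = "5tri"))
      p4 <- .as_profile(params$fourtri_profile %||% list(kind = "4tri"))
      bc <- params$barcode %||% NULL
      pd <- amplicon_pileup(inputs$deam_fastq, tpl, p5, deaminated = TRUE,
                            barcode = bc)
      pc <- amplicon_pileup(inputs$ctrl_fastq, tpl, p5, deaminated = FALSE,
                            barcode = bc)
      pf <- if (!is.null(inputs$fourtri_fastq)) {
        amplicon_pileup(inputs$fourtri_fastq, tpl, p4, deaminated = FALSE,
                        barcode = bc)
      }
      message(sprintf("decode-ss: deam %d/%d aligned, ctrl %d/%d",
                      attr(pd, "n_aligned"), attr(pd, "n_input"),
                      attr(pc, "n_aligned"), attr(pc, "n_input")))
      calls <- decode_single(pd, pc, fourtri_pileup = pf,
                             dominance = params$dominance %||% 0.7,
                             min_depth = params$min_depth %||% 20L)
      utils::write.table(calls, emit("calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(c(paste0(">", tpl$name, "_decoded"),
                   decoded_string(calls)),
                 emit("decoded.fasta"))
      c("calls.tsv", "decoded.fasta")
    },
    "retention" = {
      tpl <- .template_from(inputs, params)
      profile <- .as_profile(params$profile %||% list(kind = "5tri"))
      role <- params$strand_role %||% "sense"
      seq_tpl <- if (role == "sense") tpl else reverse_complement(tpl)
      p <- amplicon_pileup(inputs$fastq, seq_tpl, profile,
                           deaminated = TRUE,
                           barcode = params$barcode %||% NULL)
      res <- retention(p, tpl, strand_role = role,
                       doublings = params$doublings)
      utils::write.table(res$per_site, emit("retention.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(jsonlite::toJSON(
        list(overall = res$overall, doublings = res$doublings,
             per_cycle_fidelity = res$per_cycle_fidelity),
        auto_unbox = TRUE, digits = NA, null = "null"),
        emit("retention_summary.json"))
      c("retention.tsv", "retention_summary.json")
    },
    "calibrate" = {
      df <- utils::read.table(inputs$series, sep = "\t", header = TRUE)
      fit <- fit_calibration(df$prepared, df$observed)
      out <- data.frame(slope = fit$slope, intercept = fit$intercept,
                        r_squared = fit$r_squared, n_points = fit$n_points)
      utils::write.table(out, emit("calibration.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      "calibration.tsv"
    },
    "digest" = {
      tpl <- .template_from(inputs, params)
      enzymes <- restriction_presets()
      enz <- enzymes[[params$enzyme %||% "AluI"]]
      if (is.null(enz)) stop("unknown enzyme: ", params$enzyme,
                             call. = FALSE)
      lens <- digest_lengths(tpl, enz)
      utils::write.table(
        data.frame(enzyme = enz$name, fragment = seq_along(lens),
                   length = lens),
        emit("digest.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      "digest.tsv"
    },
    stop("unknown workflow: ", wf, call. = FALSE))

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             emit("manifest.json"))
  written <- c(written, "manifest.json")
  if (!dir.exists(manifest$out_dir)) {
    dir.create(manifest$out_dir, recursive = TRUE)
  }
  ok <- file.copy(file.path(stage, written), manifest$out_dir,
                  overwrite = TRUE)
  if (!all(ok)) stop("failed to move outputs into out_dir", call. = FALSE)
  invisible(stats::setNames(file.path(manifest$out_dir, written), written))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
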