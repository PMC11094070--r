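# Shared fixtures: everything is generated in code from the shipped
# templates and profiles.

random_template <- function(len, letters = c("A", "C", "G", "T", "Z", "P")) {
  expanded_seq("rand", paste(sample(letters, len, replace = TRUE),
                             collapse = ""))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# One simulated sequencing arm, error-free unless asked otherwise.
arm_pileup <- function(template, profile, n = 100, deaminate = FALSE,
                       seq_error_rate = 0, ...) {
  simulate_pileup(template, profile, n_reads = n, deaminate = deaminate,
                  seq_error_rate = seq_error_rate, ...)
}

# Duplex workflow: both strands deaminated and read under the 5tri profile.
duplex_decode <- function(template, profile, n = 100, ...) {
  ps <- arm_pileup(template, profile, n, deaminate = TRUE)
  pa <- arm_pileup(reverse_complement(template), profile, n,
                   deaminate = TRUE)
  decode_duplex(ps, pa, ...)
}

# Single-strand workflow: deaminated + control arms, optional 4tri arm.
single_decode <- function(template, profile5, profile4 = NULL, n = 100,
                          ...) {
  pd <- arm_pileup(template, profile5, n, deaminate = TRUE)
  pc <- arm_pileup(template, profile5, n, deaminate = FALSE)
  pf <- if (!is.null(profile4)) {
    arm_pileup(template, profile4, n, deaminate = FALSE)
  }
  decode_single(pd, pc, fourtri_pileup = pf, ...)
}

# Independent forward-model oracle for one original duplex letter: the
# per-strand conversion rules (deamination then 5tri readout) composed with
# complementation, written without touching the package's profile/decode
# machinery.
oracle_duplex_pair <- function(letter) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", Z = "P", P = "Z")
  strand_read <- function(x) {
    if (x == "C") x <- "U"                     # deamination
    switch(x, A = "A", U = "T", T = "T", G = "G", Z = "C", P = "G")
  }
  s <- strand_read(letter)
  a <- strand_read(comp[[letter]])
  c(sense = s, anti = comp[[a]])               # anti mapped to sense coords
}

frac_of <- function(base) {
  f <- c(A = 0, C = 0, G = 0, T = 0)
  f[base] <- 1
  f
}
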