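# esega

Decoding six-letter AEGIS DNA from four-letter sequencing reads.

## The problem

The artificially expanded genetic information system (AEGIS) adds a third
Watson–Crick pair, Z:P, to the standard A:T and G:C pairs, giving a
six-letter GACTZP alphabet with higher information density and richer
functional-group chemistry for in vitro evolution. Standard sequencers,
however, only read A, C, G and T. Enzyme-assisted sequencing of the
expanded genetic alphabet (ESEGA) works around this by *transliterating*
six-letter DNA into four-letter DNA in two controlled steps and then
decoding the reads back:

* **Deamination.** An APOBEC-family cytidine deaminase converts every C in
  a single strand to U, which reads as T after PCR. Z is untouched.
* **Transliterative PCR.** At elevated pH, Z deprotonates and pairs with
  G, so Z reads as C (>99%). P has no standard partner; with dZTP added to
  the dNTP mix (5-triphosphate PCR) P pairs Z in the first round and reads
  as G (~94.5%). Without dZTP (4-triphosphate PCR) P is forced to
  mismatch and reads as a diagnostic A/G mixture (~63%/37%).

After these steps, positions are recovered at single-base resolution by
comparing runs: a deaminated run against a non-deaminated control
(single-strand workflow), or the separately processed sense and antisense
strands of a duplex (duplex workflow). The duplex rule set is the
composition of the per-strand chemistry with complementation — writing
(sense, complemented antisense) modal bases:

| observed pair | original base |
|---|---|
| (A, A) | A |
| (T, T) | T |
| (T, C) | C |
| (G, A) | G |
| (C, C) | Z |
| (G, G) | P |

For six-nucleotide PCR (all six triphosphates), the package also provides
the fidelity statistics used to optimise conditions: per-position Z:P
**retention** R, **nominal doublings** d = round(log2(primer:template)),
and **per-cycle fidelity** f = R^(1/d) — e.g. 90% retention over the 16
nominal doublings of a 50,000:1 amplification corresponds to f = 99.34%.
A mixture calibration line Y = aX + b (observed vs prepared AEGIS
percentage) corrects population estimates, and flanking-context tables
check that conversion is sequence-independent.

The package is aimed at people developing or using expanded-alphabet
sequencing: it ships the study's amplicon templates, a seeded forward
simulator of the chemistry (which generates all test data), lightweight
amplicon read processing (pair merging, inline-barcode filtering, anchored
ungapped alignment, pileups), the single-strand and duplex decoders, and
the retention/calibration/context statistics.

## Worked example

Simulate an error-free duplex run of the six-letter template ZP-1 at depth
200 per strand, and decode it:

```r
library(esega)
set.seed(7)

tpl <- aegis_templates()[["ZP-1"]]
p5  <- conversion_preset("5tri", exact = TRUE)

sense <- simulate_pileup(tpl, p5, n_reads = 200, deaminate = TRUE)
anti  <- simulate_pileup(reverse_complement(tpl), p5, n_reads = 200,
                         deaminate = TRUE)
calls <- decode_duplex(sense, anti)
decoded_string(calls)
#> "TAAGATGAGAGTTGAGGAGAGTTACGTGZACGCPTPGTCAZCACAGTATAGTAGTGTAAGTAGATAGTGGA"
identical(decoded_string(calls), tpl$bases)
#> TRUE
```

The decoder recovers the six-letter template exactly, Z and P included.
Next, measure Z:P retention in a simulated six-triphosphate PCR at the
measured optimum (pH 8.0, 0.5 mM dPTP, per-cycle fidelity 0.9934) after
the 16 nominal doublings of a 50,000:1 primer:template amplification:

```r
p6 <- conversion_preset("6tri", ph = "8.0", dptp = "0.5 mM", exact = TRUE)
p  <- simulate_pileup(aegis_templates()$ZZ, p6, n_reads = 50000,
                      deaminate = TRUE, doublings = nominal_doublings(50000))
retention(p, aegis_templates()$ZZ, doublings = 16)
#> <retention_result> overall 0.8991 over 3 site(s)
#>   per-cycle fidelity 0.9934 over 16 doublings
```

About 90% of Z sites still read C (retained) rather than T (lost to C:G
and then deaminated), and inverting R = f^d recovers the per-cycle
fidelity that generated the data. Finally, the mixture calibration:

```r
x <- seq(10, 90, 10)
fit <- fit_calibration(x, 0.984 * x - 4.601)
fit
#> <calibration_fit> Y = 0.9840X -4.6010 (r^2 = 1.0000, n = 9)
apply_calibration(fit, 39.679)
#> 45
```

An observed AEGIS population of 39.679% corrects back to the prepared
45%.

A thin command-line wrapper over the same functions lives in
`inst/cli/esega.R` (workflows `simulate`, `decode-ss`, `decode-ds`,
`retention`, `calibrate`, `digest`); every output directory contains the
`manifest.json` that reproduces it.

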