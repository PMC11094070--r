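---
title: "Methods: transliteration chemistry, decoding rules, and fidelity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transliteration chemistry, decoding rules, and fidelity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esega)
```

## The chemistry being modelled

Six-letter GACTZP DNA carries the AEGIS Z:P pair alongside the standard
A:T and G:C pairs. Sequencers read four letters, so the workflow converts
six-letter molecules into four-letter reads through two orthogonal,
near-deterministic transliterations and then inverts the composite map:

1. **Cytidine deamination** (APOBEC family): C becomes U in single
   strands; after PCR the position reads T. Z, a C analog, is *not* a
   deaminase substrate, which is what makes C and Z separable.
2. **Transliterative PCR** at elevated pH: deprotonated Z⁻ pairs with G
   in Watson–Crick geometry, so Z reads C. P is handled by adding dZTP to
   the dNTP pool ("5-triphosphate PCR"): P templates Z in the first
   round, and that Z then reads C on the opposite strand — net effect, P
   reads G at ~94.5%. Without dZTP ("4-triphosphate PCR") P is forced
   into non-Watson–Crick mismatches and reads as a characteristic A/G
   mixture (~63/37), which is noisy as a conversion but useful as a
   *signature* distinguishing P from a true G.

In six-triphosphate PCR (dNTPs + dZTP + dPTP) the Z:P pair is propagated
as itself; the relevant failure mode is *loss*, in which a Z:P pair is
replaced by C:G (dGTP out-competing dPTP opposite Z⁻). The package
treats survival of one copying event as a Bernoulli trial with
probability `f`, the per-cycle fidelity, so a site survives `d` doublings
with probability `f^d`.

## The forward model

`conversion_profile` objects hold, per template letter, a probability
distribution over product bases. The shipped presets
(`conversion_preset()`) use the measured values: Z→C at 0.99 (reported
as >99%), P→{A:0.63, G:0.37} under 4tri, P→G at 0.945 under 5tri, and a
per-cycle Z:P fidelity of 0.9934 for the 6tri condition at pH 8.0 with
0.5 mM dPTP. pH and dPTP concentration are *labels selecting measured
profiles*; no mechanistic model of Z deprotonation is attempted.

A simulated molecule passes through the stages in bench order:

1. **Loss** (6tri only): each Z/P site independently retained with
   probability `f^d`; a lost Z becomes C and a lost P becomes G.
2. **Deamination** (if the run is deaminated): every C present — both
   original C and C created by loss — becomes U with the configured
   efficiency. This ordering is what makes retention measurable: in the
   deaminated readout a retained Z reads C while a lost Z reads T.
3. **Readout**: each letter is replaced by a draw from its profile row
   (U reads T deterministically).
4. **Sequencing error**: i.i.d. substitutions at `seq_error_rate`.

`generate_reads()` wraps this per-read, draws templates by mixture
fraction, instantiates randomised (N) positions uniformly per molecule,
prepends the 8-base inline barcode, and emits FASTQ plus a ground-truth
sidecar (source template, per-site retention flags, instantiated N
letters). Identical seed and configuration give byte-identical output.

**What the simulator does not emulate.** The per-read independent `f^d`
draw replaces a full branching amplification tree: population fractions —
all that pileup statistics observe — are identical in expectation under
both, but lineage correlation ("jackpot" amplification), PCR efficiency
differences between templates, chimeras, primer artifacts, indels and
quality-score structure are absent. Sequencing error is substitution-only
at a flat default of 10⁻³; deamination efficiency defaults to 1.0
(conversion is essentially complete at tested sites). Passing round-trip
tests on these simulations therefore demonstrates the correctness of the
*decoding logic and statistics*, not robustness to every artifact of real
libraries; the anchored aligner exposes a mismatch-fraction threshold
precisely so real, messier reads can still be placed.

## Read processing

Reads are filtered by exact (default) inline-barcode match at the read
start, trimmed, and placed on a scaffold — the expected transliteration
of the (deaminated) template — by ungapped minimal-mismatch search.
Ungapped placement is a deliberate simplification: amplicons are
fixed-length with constant primer flanks and the simulator emits no
indels, so a gapped aligner would add parameters without power. The
acceptance threshold defaults to a mismatch fraction of 0.4, deliberately
generous because deamination legitimately rewrites every C; ties go to
the smallest offset and are flagged. Pair merging prefers the *longest*
overlap within the mismatch budget (scanning from the longest candidate
avoids spurious short perfect overlaps in repetitive sequence) and
resolves disagreements toward the higher-quality base.

Pileups tabulate {A,C,G,T,other} per template position. The `other`
bucket (N and unexpected letters) counts toward depth by default;
`exclude_ambiguous = TRUE` removes it from denominators. Both behaviours
are exercised in tests since either convention is defensible.

## Decoding rules and thresholds

Calls are frequency-threshold based, not quality-aware probabilistic
calls, mirroring how the percentage tables are read in practice.

* **Dominance 0.7**: the modal base of each contributing pileup must
  exceed 70%. Worst-case legitimate fractions (retained Z:P around
  0.80–0.95) call cleanly while near-50/50 mixtures are flagged
  `below_dominance` rather than guessed.
* **Minimum depth 20**: positions shallower than 20 reads in any
  contributing arm are flagged `low_depth` and left `AMBIGUOUS`.
* **Duplex mapping**: (A,A)→A, (T,T)→T, (T,C)→C, (G,A)→G, (C,C)→Z,
  (G,G)→P on (sense, complemented antisense) modal bases. The test suite
  verifies this table against brute-force enumeration of all six original
  pairs through the forward model.
* **G vs P in the single-strand workflow**: from 5-triphosphate data
  alone, G and P both read G in both the deaminated and control runs, so
  they are *indistinguishable*; every (G,G) site is therefore called G
  with the explicit flag `g_or_p_unresolved` rather than silently
  resolved. Supplying a 4-triphosphate run resolves the ambiguity via the
  P signature: A fraction within [0.35, 0.85] and A+G ≥ 0.9. The window
  is centred on the measured 63/37 split and wide enough that binomial
  sampling at depth 100 sits ≥6 SD inside it, while a true G (A fraction
  ≈ 0) can never enter it. Whether the bench control arm used 4 or 5
  triphosphates is not fixed by the protocol description, so both control
  modes are supported.

Composition tables and retention statistics exclude the constant
primer-flank positions (24 nt forward, 26 nt reverse in the shipped
templates), since those positions are primer-derived rather than
template-derived. Ambiguous decoded positions are rendered as `"."` —
deliberately outside the alphabet — because decoded output must never
contain N or U.

## Fidelity statistics

* `nominal_doublings(ratio)` = round(log2 ratio), half-up: a 50,000:1
  primer:template ratio gives log2 = 15.61, reported as 16. The
  convention matters: 0.90^(1/16) = 0.99344, matching the quoted 99.34%
  per-cycle fidelity, whereas the unrounded exponent would give 99.33%.
* `retention()` reads the C fraction at former-Z sites of the sequenced
  strand in a deaminated-arm pileup (depth-weighted overall mean). Sense
  P sites are measured from the antisense arm, where they appear as Z;
  on the same strand a lost P reads G exactly like a retained one, so no
  signal exists there. The denominator includes every covering read by
  default (`denominator = "acgt"` restricts to unambiguous bases; the
  convention is not fixed by the protocol description, so both are
  available).
* `fit_calibration()` is ordinary least squares of observed on prepared
  percentage; `apply_calibration()` inverts the line. The measured series
  (prepared 10–90%) gave Y = 0.984X − 4.601; the ~4.5% shortfall is
  treated as an observation consistent with the fitted intercept (likely
  reflecting the slightly lower first-round efficiency of the Z⁻:G
  mismatch), not as an independent constant to be imposed.
* `context_bias()` tabulates, per (left, right) flanking k-mer pair
  (k ∈ {1,2,3}), the fraction of reads carrying the expected converted
  base at a randomised-cassette focal position, with a chi-square test of
  homogeneity that is reported, never thresholded, and deliberately not
  multiplicity-corrected — it is a descriptive screen.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open; everything user-facing is
1-based. Lowercase input is upper-cased; any letter outside
{A,C,G,T,Z,P,U,N} is rejected rather than coerced. U complements to A (it
behaves as T), N to N; complementation is an involution on every letter
except U. Restriction-site scanning requires pure four-letter input and
tells the caller to transliterate first; cut positions at a fragment
boundary of zero length are dropped so fragment lengths always sum to the
sequence length. Cut offsets (AluI AG^CT, PspOMI G^GGCCC) follow the
standard REBASE definitions, as only the recognition motifs are fixed by
the assay, and are configurable per enzyme. Zero-depth pileup positions
propagate NaN fractions and are flagged rather than called. Profile rows
must sum to 1 within 1e-9. The residual 5.5% non-G fate of P under 5tri
is split between A and T in the 63:37 A-heavy proportion observed under
4tri — the true breakdown is not established, so the split is a
configurable default, not a claimed fact.

## Problem sizes used by the shipped tests

The suite favours sizes that make binomial 3-SD bounds decisive while
keeping a full run around twenty seconds: round-trip decoding uses 200
random 60-nt six-letter templates at depth 100 per arm; the
retention-vs-closed-form comparison uses 10⁵ reads over the three Z
sites of the 71-nt ZZ template; the calibration series simulates
triplicate measurements (matching the bench design of three independent
measurements per ratio) at depth 10⁴ per point across prepared fractions
of 10–90%; context-bias nulls use 20 replicates of 1,500 reads and the
planted-effect check 6,000 reads.

## Known limitations

Only the Z:P pair of the twelve-letter AEGIS scheme is supported — the
workflow being modelled covers Z/P only. There is no modelling of qPCR
quantification, polymerase processivity beyond the single fidelity
scalar, or functionalised-P chemistry beyond swapping in an alternate
conversion profile or fidelity value. The caller is frequency-based and
ignores base qualities. Real SRA data would additionally need adapter
trimming and (for non-amplicon designs) a gapped aligner; the anchored
aligner exposes a hook-level mismatch threshold but is not a Bowtie2
replacement.
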