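# Six-letter inference: per-site rules, whole-template round trips,
# composition tables, logo matrices.

test_that("duplex site rules follow the strand-comparison logic", {
  # C:G original: sense reads T (deaminated C), antisense complement reads C
  s <- c(A = 0.004, C = 0.004, G = 0.002, T = 0.99)
  a <- c(A = 0.01, C = 0.98, G = 0.005, T = 0.005)
  expect_identical(decode_duplex_site(s, a)$call, "C")
  expect_identical(decode_duplex_site(frac_of("C") * 0.95 + 0.0125,
                                      frac_of("C") * 0.96 + 0.01)$call, "Z")
  expect_identical(decode_duplex_site(frac_of("A"), frac_of("A"))$call, "A")
  expect_identical(decode_duplex_site(frac_of("G"), frac_of("G"))$call, "P")
  expect_identical(decode_duplex_site(frac_of("G"), frac_of("A"))$call, "G")
  # unmapped pair and weak dominance are AMBIGUOUS
  expect_identical(decode_duplex_site(frac_of("A"), frac_of("C"))$call,
                   "AMBIGUOUS")
  weak <- c(A = 0.55, C = 0.45, G = 0, T = 0)
  call <- decode_duplex_site(weak, frac_of("A"))
  expect_identical(call$call, "AMBIGUOUS")
  expect_true("below_dominance" %in% call$flags)
  empty <- decode_duplex_site(numeric(0), frac_of("A"))
  expect_true("low_depth" %in% empty$flags)
})

test_that("duplex mapping equals brute-force enumeration of the forward model", {
  for (letter in c("A", "C", "G", "T", "Z", "P")) {
    pair <- oracle_duplex_pair(letter)
    call <- decode_duplex_site(frac_of(pair[["sense"]]),
                               frac_of(pair[["anti"]]))
    expect_identical(call$call, letter)
  }
})

test_that("single-strand site rules use the deaminated/control contrast", {
  zf <- c(A = 0.01, C = 0.98, G = 0.005, T = 0.005)
  expect_identical(decode_single_site(zf, zf)$call, "Z")
  tf <- c(A = 0, C = 0, G = 0.01, T = 0.99)
  cf <- c(A = 0, C = 0.99, G = 0, T = 0.01)
  expect_identical(decode_single_site(tf, cf)$call, "C")
  expect_identical(decode_single_site(tf, tf)$call, "T")
  gf <- c(A = 0.005, C = 0.005, G = 0.99, T = 0)
  p4 <- c(A = 0.63, C = 0, G = 0.37, T = 0)
  expect_identical(decode_single_site(gf, gf, fourtri_frac = p4)$call, "P")
  expect_identical(decode_single_site(gf, gf, fourtri_frac = frac_of("G"))$call,
                   "G")
  noctl <- decode_single_site(gf, gf)
  expect_identical(noctl$call, "G")
  expect_true("g_or_p_unresolved" %in% noctl$flags)
  expect_identical(decode_single_site(frac_of("A"), frac_of("T"))$call,
                   "AMBIGUOUS")
})

test_that("error-free duplex sequencing round-trips the shipped templates", {
  set.seed(31)
  p5 <- conversion_preset("5tri", exact = TRUE)
  for (nm in c("ZP-1", "ZP-2", "ZZ", "Nat")) {
    tpl <- aegis_templates()[[nm]]
    calls <- duplex_decode(tpl, p5, n = 100)
    expect_identical(decoded_string(calls), tpl$bases)
  }
})

test_that("single-strand decoding round-trips given a 4tri control", {
  set.seed(32)
  p5 <- conversion_preset("5tri", exact = TRUE)
  p4 <- conversion_preset("4tri")
  zp2 <- aegis_templates()[["ZP-2"]]
  calls <- single_decode(zp2, p5, p4, n = 100)
  expect_identical(decoded_string(calls), zp2$bases)
  # without the 4tri run every P site is flagged, all non-P calls correct
  calls2 <- single_decode(zp2, p5, NULL, n = 100)
  tch <- strsplit(zp2$bases, "")[[1]]
  ppos <- which(tch == "P")
  flagged <- which(grepl("g_or_p_unresolved", calls2$flags))
  expect_true(all(ppos %in% flagged))
  expect_identical(sort(flagged), sort(which(tch %in% c("G", "P"))))
  nonp <- setdiff(seq_along(tch), ppos)
  expect_identical(calls2$call[nonp], tch[nonp])
})

test_that("shallow positions are suppressed as low_depth", {
  set.seed(33)
  p5 <- conversion_preset("5tri", exact = TRUE)
  tpl <- aegis_templates()$ZZ
  calls <- duplex_decode(tpl, p5, n = 10, min_depth = 20)
  expect_true(all(calls$call == "AMBIGUOUS"))
  expect_true(all(grepl("low_depth", calls$flags)))
})

test_that("composition tables recover the generating profile by base class", {
  set.seed(34)
  tpls <- aegis_templates()
  p5 <- conversion_preset("5tri")
  flank <- primer_flanks()
  exclude <- c(seq_len(flank$fwd), (71 - flank$rev + 1):71)

  nat <- simulate_pileup(tpls$Nat, p5, n_reads = 2000)
  ct <- composition_table(nat, tpls$Nat, exclude = exclude)
  for (cls in c("A", "T", "C", "G")) {
    self <- ct$fraction[ct$class == cls & ct$product == cls]
    expect_equal(self, 1.0)
  }

  zz <- simulate_pileup(tpls$ZZ, p5, n_reads = 3000)
  ctz <- composition_table(zz, tpls$ZZ, exclude = exclude)
  zc <- ctz$fraction[ctz$class == "Z" & ctz$product == "C"]
  expect_lt(abs(zc - 0.99), 3 * sqrt(0.99 * 0.01 / 3000))

  p4 <- conversion_preset("4tri")
  zp1 <- simulate_pileup(tpls[["ZP-1"]], p4, n_reads = 5000)
  ctp <- composition_table(zp1, tpls[["ZP-1"]], exclude = exclude)
  pa <- ctp$fraction[ctp$class == "P" & ctp$product == "A"]
  pg <- ctp$fraction[ctp$class == "P" & ctp$product == "G"]
  tol <- 3 * sqrt(0.63 * 0.37 / (2 * 5000))
  expect_lt(abs(pa - 0.63), tol)
  expect_lt(abs(pg - 0.37), tol)

  # each class's product distribution sums to 1
  sums <- tapply(ctp$fraction, ctp$class, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("logo information content is 2 - Shannon entropy in bits", {
  p <- build_pileup(c("AA", "AC", "AG", "AT"))
  lg <- logo_matrix(p)
  expect_equal(lg$info[1], 2)            # single base
  expect_equal(lg$info[2], 0)            # uniform ACGT
  mix <- build_pileup(c(rep("A", 63), rep("G", 37)))
  expect_equal(logo_matrix(mix)$info, 1.0494, tolerance = 1e-4)
  set.seed(35)
  rnd <- simulate_pileup(aegis_templates()[["ZP-2"]],
                         conversion_preset("5tri"), n_reads = 200,
                         deaminate = TRUE)
  info <- logo_matrix(rnd)$info
  expect_true(all(info >= 0 - 1e-12 & info <= 2 + 1e-12))
})
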