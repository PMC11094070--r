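# Retention, doublings, per-cycle fidelity, calibration, context bias.

test_that("nominal doublings round log2 of the primer:template ratio", {
  expect_identical(nominal_doublings(50000), 16L)
  expect_identical(nominal_doublings(1), 0L)
  expect_identical(nominal_doublings(65536), 16L)
  expect_error(nominal_doublings(0.5), ">= 1")
})

test_that("per-cycle fidelity and expected retention are exact inverses", {
  expect_equal(per_cycle_fidelity(0.90, 16), 0.9934, tolerance = 1e-4)
  expect_identical(round(100 * per_cycle_fidelity(0.90, 16), 2), 99.34)
  expect_equal(expected_retention(1.0, 30), 1.0)
  set.seed(41)
  for (i in 1:25) {
    f <- runif(1, 0.9, 1)
    d <- sample(1:30, 1)
    expect_equal(per_cycle_fidelity(expected_retention(f, d), d), f,
                 tolerance = 1e-12)
  }
  expect_equal(per_cycle_fidelity(expected_retention(0.987, 16), 16), 0.987)
  expect_error(per_cycle_fidelity(0, 16), "\\(0, 1\\]")
  expect_error(per_cycle_fidelity(0.9, 0), ">= 1")
})

test_that("retention reads the C fraction at former-Z sites", {
  set.seed(42)
  zz <- aegis_templates()$ZZ
  p6 <- conversion_preset("6tri", ph = "8.0", dptp = "0.5 mM",
                          exact = TRUE)
  # f = 1 (or d = 0): every site retained exactly
  p <- simulate_pileup(zz, conversion_preset("6tri", ph = "8.0",
                                             dptp = "0.5 mM", fidelity = 1,
                                             exact = TRUE),
                       n_reads = 500, deaminate = TRUE, doublings = 16)
  r <- retention(p, zz)
  expect_identical(r$per_site$retention, rep(1, 3))
  expect_identical(r$overall, 1)
  p0 <- simulate_pileup(zz, p6, n_reads = 500, deaminate = TRUE,
                        doublings = 0)
  expect_identical(retention(p0, zz)$overall, 1)
  # a template without Z on the sequenced strand yields an empty result
  empty <- retention(simulate_pileup(aegis_templates()$Nat,
                                     conversion_preset("5tri"),
                                     n_reads = 50, deaminate = TRUE),
                     aegis_templates()$Nat)
  expect_identical(nrow(empty$per_site), 0L)
  expect_true(is.na(empty$overall))
  expect_match(empty$note, "no Z sites")
})

test_that("antisense-arm retention measures the sense strand's P sites", {
  set.seed(43)
  zp1 <- aegis_templates()[["ZP-1"]]
  p6 <- conversion_preset("6tri", ph = "8.0", dptp = "0.5 mM",
                          exact = TRUE)
  anti <- reverse_complement(zp1)
  p <- simulate_pileup(anti, p6, n_reads = 4000, deaminate = TRUE,
                       doublings = 16)
  r <- retention(p, zp1, strand_role = "antisense", doublings = 16)
  # former sense-P positions 34 and 36 are Z on the antisense strand
  expect_identical(r$per_site$position, c(71L - 36L + 1L, 71L - 34L + 1L))
  p_ret <- 0.9934^16
  expect_lt(abs(r$overall - p_ret),
            3 * sqrt(p_ret * (1 - p_ret) / (2 * 4000)))
  expect_equal(r$per_cycle_fidelity, r$overall^(1 / 16))
})

test_that("retention estimator is unbiased over stochastic replicates", {
  set.seed(44)
  zz <- aegis_templates()$ZZ
  p6 <- conversion_preset("6tri", ph = "8.0", dptp = "0.5 mM",
                          exact = TRUE)
  p_ret <- 0.9934^16
  n_rep <- 50; depth <- 400
  overall <- vapply(seq_len(n_rep), function(i) {
    retention(simulate_pileup(zz, p6, n_reads = depth, deaminate = TRUE,
                              doublings = 16), zz)$overall
  }, 0)
  se <- sqrt(p_ret * (1 - p_ret) / (3 * depth)) / sqrt(n_rep)
  expect_lt(abs(mean(overall) - p_ret), 3 * se)
})

test_that("calibration fitting and inversion reproduce the printed line", {
  x <- seq(10, 90, by = 10)
  y <- 0.984 * x - 4.601
  fit <- fit_calibration(x, y)
  expect_equal(fit$slope, 0.984, tolerance = 1e-9)
  expect_equal(fit$intercept, -4.601, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(apply_calibration(fit, 39.679), 45.0, tolerance = 1e-9)
  ident <- fit_calibration(c(0, 50, 100), c(0, 50, 100))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_error(fit_calibration(c(10, 10), c(5, 6)), "singular")
  # recovery under binomial noise: slope within 3 SE of the generator
  set.seed(45)
  depth <- 10000
  yn <- 100 * rbinom(length(x), depth, (0.984 * x - 4.601) / 100) / depth
  fitn <- fit_calibration(x, yn)
  se <- sqrt(sum((yn - (fitn$slope * x + fitn$intercept))^2) /
               (length(x) - 2) / sum((x - mean(x))^2))
  expect_lt(abs(fitn$slope - 0.984), 3 * max(se, 1e-3))
})

test_that("context tables are homogeneous when conversion is context-free", {
  set.seed(46)
  n <- 3000
  p_conv <- 0.94
  flank <- function() sample(c("A", "C", "G", "T"), n, replace = TRUE)
  focal <- ifelse(runif(n) < p_conv, "C", "T")
  seqs <- paste0(flank(), focal, flank())
  cb <- context_bias(seqs, focal = 2, expected = "C", k = 1)
  expect_lte(nrow(cb$table), 16L)
  expect_lt(abs(sum(cb$table$n_expected) / n - p_conv),
            3 * sqrt(p_conv * (1 - p_conv) / n))
  expect_identical(sum(cb$table$n), as.integer(n))
  expect_error(context_bias(seqs, 2, "C", k = 4), "1, 2 or 3")
})

test_that("a planted context effect surfaces as the extreme context", {
  set.seed(47)
  n <- 6000
  left <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  right <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  p <- ifelse(left == "G", 0.45, 0.9)  # halved conversion after left-G
  focal <- ifelse(runif(n) < p, "C", "T")
  cb <- context_bias(paste0(left, focal, right), 2, "C", k = 1)
  worst <- cb$table[which.min(cb$table$frac_expected), ]
  expect_identical(worst$left, "G")
  expect_lt(cb$p_value, 1e-6)
  g_rows <- cb$table$left == "G"
  expect_lt(max(cb$table$frac_expected[g_rows]),
            min(cb$table$frac_expected[!g_rows]))
})
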