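# Pair merging, barcode filtering, anchored placement, pileups.

test_that("pair merging recovers the amplicon from overlapping mates", {
  set.seed(5)
  amp <- random_dna(250)
  r1 <- list(sequence = substr(amp, 1, 150), quality = strrep("I", 150))
  r2 <- list(sequence = reverse_complement(substr(amp, 101, 250)),
             quality = strrep("I", 150))
  m <- merge_pairs(r1, r2)
  expect_identical(m$status, "merged")
  expect_identical(m$sequence, amp)
  expect_identical(m$overlap, 50L)

  # identical full-overlap mates merge to themselves
  s <- random_dna(50)
  full <- merge_pairs(list(sequence = s, quality = strrep("I", 50)),
                      list(sequence = reverse_complement(s),
                           quality = strrep("I", 50)))
  expect_identical(full$sequence, s)

  # no usable overlap -> rejection, not error
  bad <- merge_pairs(list(sequence = random_dna(40), quality = strrep("I", 40)),
                     list(sequence = random_dna(40), quality = strrep("I", 40)),
                     min_overlap = 30)
  expect_identical(bad$status, "rejected")
})

test_that("overlap disagreements resolve toward the higher-quality base", {
  amp <- strrep("A", 60)
  r1 <- list(sequence = amp, quality = paste0(strrep("I", 30), strrep("#", 30)))
  mut <- paste0(strrep("A", 40), "C", strrep("A", 19))
  r2 <- list(sequence = reverse_complement(mut), quality = strrep("I", 60))
  m <- merge_pairs(r1, r2, max_mismatch_frac = 0.1)
  expect_identical(m$status, "merged")
  expect_identical(substr(m$sequence, 41, 41), "C")  # r2 base, higher Q
})

test_that("barcode filter keeps exact prefixes and trims them", {
  reads <- data.frame(id = c("a", "b"),
                      sequence = c("AACCGGTTACGT", "TACCGGTTACGT"),
                      quality = c(strrep("I", 12), strrep("I", 12)),
                      stringsAsFactors = FALSE)
  res <- filter_barcode(reads, "AACCGGTT")
  expect_identical(res$counts, c(kept = 1L, discarded = 1L))
  expect_identical(res$kept$sequence, "ACGT")
  expect_identical(res$kept$quality, "IIII")
  res1 <- filter_barcode(reads, "AACCGGTT", max_mismatch = 1)
  expect_identical(unname(res1$counts["kept"]), 2L)
  expect_error(filter_barcode(reads, "ACGT"), "8-base")
})

test_that("wrong-barcode spike-ins are removed at the spiked rate", {
  set.seed(8)
  n <- 2000
  spike <- runif(n) < 0.05
  bc <- ifelse(spike, "TTTTTTTT", "AACCGGTT")
  reads <- data.frame(id = seq_len(n),
                      sequence = paste0(bc, vapply(seq_len(n), function(i)
                        random_dna(20), "")),
                      quality = strrep("I", 28), stringsAsFactors = FALSE)
  res <- filter_barcode(reads, "AACCGGTT")
  kept_frac <- res$counts[["kept"]] / n
  expect_lt(abs(kept_frac - 0.95), 3 * sqrt(0.95 * 0.05 / n))
})

test_that("anchored placement minimises mismatches and rejects strangers", {
  set.seed(9)
  scaffold <- random_dna(120)
  a <- align_anchored(scaffold, scaffold)
  expect_identical(a$offset, 1L)
  expect_identical(a$mismatches, 0L)
  read <- substr(scaffold, 31, 90)
  expect_identical(align_anchored(read, scaffold)$offset, 31L)
  # 10% random substitutions keep the same placement
  ch <- strsplit(read, "")[[1]]
  hit <- sample(60, 6)
  ch[hit] <- vapply(ch[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  expect_identical(align_anchored(paste(ch, collapse = ""), scaffold)$offset,
                   31L)
  # a read from an unrelated template is rejected
  expect_identical(align_anchored(random_dna(60), scaffold,
                                  max_mismatch_frac = 0.4)$status,
                   "rejected")
  expect_error(align_anchored(random_dna(200), scaffold),
               "scaffold shorter")
})

test_that("pileups count every assigned base exactly once", {
  reads <- rep("ACGT", 100)
  p <- build_pileup(reads, template_id = "toy")
  expect_identical(unname(p$depth), rep(100, 4))
  expect_identical(unname(p$counts["A", 1]), 100L)
  fr <- pileup_fractions(p)
  expect_true(all(abs(colSums(fr) - 1) < 1e-12))
  expect_identical(sum(p$counts), 400L)

  # order invariance
  set.seed(10)
  seqs <- vapply(1:50, function(i) random_dna(12), "")
  p1 <- build_pileup(seqs)
  p2 <- build_pileup(sample(seqs))
  expect_identical(p1$counts, p2$counts)

  # mixed offsets and an ambiguous letter
  asg <- data.frame(sequence = c("ACGT", "NT"), offset = c(1L, 2L))
  p3 <- build_pileup(asg, length = 5L)
  expect_identical(unname(p3$depth), c(1, 2, 2, 1, 0))
  expect_identical(unname(p3$counts["other", 2]), 1L)
  expect_error(build_pileup(data.frame(sequence = "ACGT", offset = 3L),
                            length = 5L), "outside scaffold")
})

test_that("simulated pileups reproduce the generating profile", {
  set.seed(12)
  zz <- aegis_templates()$ZZ
  p5 <- conversion_preset("5tri")
  p <- simulate_pileup(zz, p5, n_reads = 3000, deaminate = TRUE)
  expect_true(all(p$depth == 3000))
  fr <- pileup_fractions(p)
  zpos <- which(strsplit(zz$bases, "")[[1]] == "Z")
  for (i in zpos) {
    expect_lt(abs(fr["C", i] - 0.99), 3 * sqrt(0.99 * 0.01 / 3000))
  }
  # error-free modal base equals the expected transliteration everywhere
  expected <- transliterate_expected(chartr("C", "U", zz$bases), p5)
  modal <- rownames(fr)[apply(fr, 2, which.max)]
  expect_identical(paste(modal, collapse = ""), expected)
})

test_that("pileup TSV round-trips counts and depth", {
  set.seed(13)
  p <- build_pileup(vapply(1:20, function(i) random_dna(15), ""),
                    template_id = "t")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(p, f)
  q <- read_pileup(f, template_id = "t")
  expect_identical(q$counts, p$counts)
  expect_identical(q$depth, p$depth)
})
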