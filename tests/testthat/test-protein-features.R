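test_that("hydropathy profile matches hand values on constant sequences", {
  polyL <- strrep("L", 31)
  prof <- hydropathy_profile(polyL, window = 19)
  expect_equal(prof$score[10:22], rep(3.8, 13))
  polyR <- strrep("R", 31)
  expect_equal(hydropathy_profile(polyR, 19)$score[10:22], rep(-4.5, 13))
  expect_error(hydropathy_profile(polyL, window = 18), "odd")
  expect_error(hydropathy_profile(polyL, window = 3), "odd")
  expect_error(hydropathy_profile("LLL", window = 19), "longer")
})

test_that("a hydrophobic core flanked by arginines shows the hand-computed shape", {
  seq <- paste0(strrep("R", 5), strrep("L", 25), strrep("R", 5))
  prof <- hydropathy_profile(seq, window = 19)
  centre <- prof$score[prof$position == 18]  # window 9..27, all leucine
  expect_equal(centre, 3.8)
  expect_gt(min(prof$score[15:21]), 1.6)     # central plateau
  expect_lt(prof$score[1], 0)                # flanks dominated by arginine
  expect_lt(prof$score[35], 0)
})

test_that("TM segment calls recover planted poly-leucine inserts", {
  # all-hydrophilic protein: nothing called
  none <- predict_tm_segments(hydropathy_profile(strrep("RKDE", 30), 19))
  expect_identical(nrow(none), 0L)

  for (seed in 1:4) {
    one <- plant_tm_protein(1, transit = FALSE, seed = seed)
    prof <- hydropathy_profile(one$record$sequence, 19)
    seg <- predict_tm_segments(prof)
    expect_identical(nrow(seg), 1L)
    tm_lo <- one$truth$tm_starts[[1]]
    expect_lt(seg$start[[1]], tm_lo + 25)
    expect_gt(seg$end[[1]], tm_lo)

    two <- plant_tm_protein(2, transit = FALSE, seed = seed + 10)
    seg2 <- predict_tm_segments(hydropathy_profile(two$record$sequence, 19))
    expect_identical(nrow(seg2), 2L)
  }
})

test_that("TM segments are sorted, non-overlapping, and mergeable", {
  two <- plant_tm_protein(3, transit = FALSE, seed = 5)
  seg <- predict_tm_segments(hydropathy_profile(two$record$sequence, 19))
  expect_identical(seg$start, sort(seg$start))
  if (nrow(seg) > 1) {
    expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
  }
  # two runs separated by < merge_gap fuse into one segment
  prof <- tibble::tibble(position = 1:40,
                         score = c(rep(2, 18), 0, rep(2, 18), rep(0, 3)))
  merged <- predict_tm_segments(prof, threshold = 1.6, min_tm_length = 15,
                                merge_gap = 3)
  expect_identical(nrow(merged), 1L)
})

test_that("transit-peptide heuristic scores composition as specified", {
  allS <- paste0(strrep("S", 40), strrep("L", 20))
  resS <- transit_peptide_heuristic(allS)
  expect_equal(resS$score, 1.0)
  expect_true(resS$call)

  allD <- paste0(strrep("D", 40), strrep("L", 20))
  resD <- transit_peptide_heuristic(allD)
  expect_equal(resD$score, -1.0)
  expect_false(resD$call)

  # "MA" + 20 serines + 18 leucines: (S+T) 20/40, no D/E, alanine bonus
  prefix <- paste0("MA", strrep("S", 20), strrep("L", 18), strrep("G", 20))
  res <- transit_peptide_heuristic(prefix)
  expect_equal(res$score, 20 / 40 + 0.1)
  expect_true(res$call)

  short <- transit_peptide_heuristic(strrep("S", 30))
  expect_false(short$call)
  expect_true(short$too_short)
})

test_that("domain detection: self-match, planted offset, shuffled null", {
  prof <- shared_profile()
  aln <- read_fasta(system.file("extdata", "hemeo_domain_synthetic.fasta",
                                package = "plastome"))
  # a sequence from the packaged alignment recovers its own span
  hit <- detect_hemeo_domain(aln$sequence[[1]], prof)
  expect_identical(hit$start, 0L)
  expect_identical(hit$end, prof$length)

  # planted at offset 100 inside a hydrophilic carrier
  set.seed(21)
  carrier <- paste(sample(c("R", "K", "D", "E", "N", "Q", "G"), 200,
                          replace = TRUE), collapse = "")
  planted <- paste0(substr(carrier, 1, 100), aln$sequence[[2]],
                    substr(carrier, 101, 200))
  hit2 <- detect_hemeo_domain(planted, prof)
  expect_false(is.null(hit2))
  expect_lte(abs(hit2$start - 100), 2)

  # shuffled copies score below the calibrated cutoff
  set.seed(33)
  for (i in 1:5) {
    shuffled <- paste(sample(strsplit(aln$sequence[[i]], "")[[1]]),
                      collapse = "")
    expect_null(detect_hemeo_domain(shuffled, prof))
  }
})

test_that("isotype rules fire in priority order", {
  prof <- shared_profile()
  # transit + no TM -> HMOX1 regardless of compartment annotation
  h1 <- plant_tm_protein(0, transit = TRUE, encoded_in = "nucleus", seed = 1)
  f1 <- protein_features(h1$record$sequence, "nucleus", prof)
  expect_identical(classify_isotype(f1)$isotype, "HMOX1")

  # nucleus + C-terminal TM (+ internal) -> HMOX2
  h2 <- plant_tm_protein(2, transit = FALSE, encoded_in = "nucleus", seed = 2)
  f2 <- protein_features(h2$record$sequence, "nucleus", prof)
  expect_identical(classify_isotype(f2)$isotype, "HMOX2")

  # plastid + C-terminal TM, no transit -> pbsA
  h3 <- plant_tm_protein(1, transit = FALSE, encoded_in = "plastid", seed = 3)
  f3 <- protein_features(h3$record$sequence, "plastid", prof)
  expect_identical(classify_isotype(f3)$isotype, "pbsA")

  # transit + TM: pbsA-type architecture with a conflict note
  h4 <- plant_tm_protein(1, transit = TRUE, encoded_in = "nucleus", seed = 4)
  f4 <- protein_features(h4$record$sequence, "nucleus", prof)
  call4 <- classify_isotype(f4)
  expect_identical(call4$isotype, "pbsA")
  expect_true(any(grepl("conflict", call4$evidence)))

  # no domain -> unclassified
  h5 <- plant_tm_protein(1, transit = FALSE, encoded_in = "plastid",
                         with_domain = FALSE, seed = 5)
  f5 <- protein_features(h5$record$sequence, "plastid", prof)
  expect_identical(classify_isotype(f5)$isotype, "unclassified")

  # purity: same features give the same call
  expect_identical(classify_isotype(f2)$isotype, classify_isotype(f2)$isotype)
})

test_that("classification is perfect on planted architectures", {
  prof <- shared_profile()
  cases <- list(
    list(n_tm = 0, transit = TRUE, enc = "nucleus"),
    list(n_tm = 0, transit = TRUE, enc = "plastid"),
    list(n_tm = 1, transit = FALSE, enc = "plastid"),
    list(n_tm = 1, transit = FALSE, enc = "nucleus"),
    list(n_tm = 2, transit = FALSE, enc = "nucleus"),
    list(n_tm = 3, transit = FALSE, enc = "nucleus")
  )
  for (seed in 1:3) {
    for (cs in cases) {
      pl <- plant_tm_protein(cs$n_tm, transit = cs$transit,
                             encoded_in = cs$enc, seed = seed * 100 + cs$n_tm)
      got <- classify_proteins(pl$record, profile = prof)
      expect_identical(got$isotype, pl$truth$expected_isotype,
                       info = paste(cs$n_tm, cs$transit, cs$enc, seed))
    }
  }
})

test_that("external precomputed feature calls override the heuristics", {
  prof <- shared_profile()
  pl <- plant_tm_protein(0, transit = TRUE, encoded_in = "nucleus", seed = 9)
  ext <- tibble::tibble(
    seq_id = pl$record$seq_id, transit_peptide = FALSE,
    c_terminal_tm = TRUE, internal_tm = TRUE, n_tm = 2L,
    domain_start = 70L, domain_end = 130L
  )
  got <- classify_proteins(pl$record, external = ext, profile = prof)
  expect_identical(got$isotype, "HMOX2")    # external features win
  expect_identical(got$n_tm, 2L)
})

test_that("FASTA round-trips and encoded_in header tags are honoured", {
  prots <- tibble::tibble(
    seq_id = c("a encoded_in=plastid", "b encoded_in=nucleus", "c"),
    sequence = c(strrep("MKRDE", 20), strrep("LDERK", 20), strrep("GDERK", 8))
  )
  f <- withr::local_tempfile(fileext = ".faa")
  write_fasta(prots, f)
  back <- read_fasta(f)
  expect_identical(back$sequence, prots$sequence)
  expect_identical(extract_encoded_in <- plastome:::extract_encoded_in(back$seq_id),
                   c("plastid", "nucleus", "unknown"))
})
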