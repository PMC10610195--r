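# Brute-force oracle: scan every (compound, mode) pair of the target gene.
brute_modulators <- function(pm, target = "PLAUR", threshold = 0.9) {
  hits <- list()
  for (cpd in pm$compounds) {
    best <- NULL
    for (mode in c("KD", "OE")) {
      s <- pm_score(pm, cpd, target, mode)
      if (!is.na(s) && s > threshold) {
        if (is.null(best) || s > best$score) {
          best <- list(mode = mode, score = s)
        }
      }
    }
    if (!is.null(best)) hits[[cpd]] <- best
  }
  hits
}

test_that("a supra-threshold KD score yields a suppressor call with that score", {
  pm <- pm_from_rows(list("pterostilbene", "PLAUR", "KD", 0.9519),
                     list("inert", "PLAUR", "KD", 0.1))
  calls <- identify_modulators(pm)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$compound, "pterostilbene")
  expect_equal(calls$direction, "suppressor")
  expect_equal(calls$score, 0.9519)
})

test_that("the calling threshold is a strict inequality", {
  pm <- pm_from_rows(list("edge", "PLAUR", "KD", 0.90),
                     list("above", "PLAUR", "KD", 0.9000001))
  calls <- identify_modulators(pm)
  expect_equal(calls$compound, "above")
})

test_that("direction mapping is invertible and both-mode ties go to KD", {
  pm <- pm_from_rows(list("c1", "PLAUR", "KD", 0.95),
                     list("c1", "PLAUR", "OE", 0.92),
                     list("c2", "PLAUR", "KD", 0.93),
                     list("c2", "PLAUR", "OE", 0.93))
  calls <- identify_modulators(pm)
  expect_equal(calls$mode, c("KD", "KD"))
  flipped <- identify_modulators(pm, screen_config(kd_means = "stimulator"))
  expect_equal(unique(flipped$direction), "stimulator")
})

test_that("calls equal the brute-force scan on seeded synthetic data", {
  b <- small_bundle()
  calls <- identify_modulators(b$matrix)
  oracle <- brute_modulators(b$matrix)
  expect_setequal(calls$compound, names(oracle))
  for (i in seq_len(nrow(calls))) {
    expect_equal(calls$score[i], oracle[[calls$compound[i]]]$score)
    expect_equal(calls$mode[i], oracle[[calls$compound[i]]]$mode)
  }
  # sorted by descending score then compound
  expect_true(all(diff(calls$score) <= 0))
})

test_that("sham selection matches a brute-force band scan and boundary rules", {
  pm <- pm_from_rows(list("interior", "PLAUR", "KD", 0.0),
                     list("interior", "PLAUR", "OE", 0.1),
                     list("mixed", "PLAUR", "KD", 0.1),
                     list("mixed", "PLAUR", "OE", 0.95),
                     list("edge", "PLAUR", "KD", 0.2))
  expect_setequal(select_sham_compounds(pm), c("edge", "interior"))

  b <- small_bundle()
  sh <- select_sham_compounds(b$matrix)
  oracle <- Filter(function(cpd) {
    s <- pm_score(b$matrix, cpd, "PLAUR")
    m <- s[!is.na(s)]
    length(m) > 0 && all(m >= -0.2 & m <= 0.2)
  }, b$matrix$compounds)
  expect_equal(sh, sort(oracle))
})

test_that("modulator and sham sets partition disjointly for any matrix", {
  b <- small_bundle()
  calls <- identify_modulators(b$matrix)
  shams <- select_sham_compounds(b$matrix)
  expect_length(intersect(calls$compound, shams), 0)
})

test_that("raising the threshold only removes calls; widening the band only adds shams", {
  b <- small_bundle()
  lo <- identify_modulators(b$matrix, screen_config(threshold = 0.85))
  hi <- identify_modulators(b$matrix, screen_config(threshold = 0.95))
  expect_true(all(hi$compound %in% lo$compound))
  narrow <- select_sham_compounds(b$matrix,
                                  screen_config(sham_band = c(-0.1, 0.1)))
  wide <- select_sham_compounds(b$matrix,
                                screen_config(sham_band = c(-0.3, 0.3)))
  expect_true(all(narrow %in% wide))
})

test_that("a missing target gene raises a lookup error naming it", {
  pm <- pm_from_rows(list("c1", "G1", "KD", 0.5))
  expect_error(identify_modulators(pm), "PLAUR",
               class = "pertnet_lookup_error")
  expect_error(select_sham_compounds(pm), "PLAUR",
               class = "pertnet_lookup_error")
})

test_that("co-expression profiles equal a brute-force per-gene scan", {
  pm <- pm_from_rows(list("m1", "PLAUR", "KD", 0.95),
                     list("m1", "G1", "OE", 0.91),
                     list("m1", "G2", "KD", 0.89))
  prof <- coexpressed_targets(pm, "m1")
  expect_equal(prof$m1, c("G1", "PLAUR"))

  b <- small_bundle()
  calls <- identify_modulators(b$matrix)
  prof <- coexpressed_targets(b$matrix, calls)
  for (cpd in calls$compound[1:5]) {
    oracle <- Filter(function(g) {
      any(pm_score(b$matrix, cpd, g) > 0.9, na.rm = TRUE)
    }, b$matrix$genes)
    expect_equal(prof[[cpd]], sort(oracle))
  }
  expect_error(coexpressed_targets(b$matrix, "no_such_compound"),
               class = "pertnet_lookup_error")
})

test_that("demo matrix profiles reproduce the curated modulator gene lists", {
  ref <- load_reference_tables()
  prof <- coexpressed_targets(ref$demo_matrix, ref$real_modulators$compound)
  for (i in seq_len(nrow(ref$real_modulators))) {
    cpd <- ref$real_modulators$compound[i]
    expect_equal(setdiff(prof[[cpd]], "PLAUR"),
                 sort(ref$real_modulators$genes[[i]]),
                 label = cpd)
  }
})
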