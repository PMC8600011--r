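test_that("mutation-string grammar parses and validates", {
  con <- parse_mutation_string("A R45G")
  expect_equal(nrow(con), 1L)
  expect_equal(con$chain_id, "A")
  expect_equal(con$wt, "R")
  expect_equal(con$residue_number, 45L)
  expect_equal(con$mut, "G")

  multi <- parse_mutation_string("A R45G;A K50A")
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$mut, c("G", "A"))
  # whitespace around ';' tolerated; round trip through formatting
  expect_equal(format_mutation_string(parse_mutation_string("A R45G ; A K50A")),
               "A R45G;A K50A")

  expect_error(parse_mutation_string("A R45R"), "wild-type equals mutant")
  expect_error(parse_mutation_string(""), "parse error")
  expect_error(parse_mutation_string("AR45G"), "parse error")
  expect_error(parse_mutation_string("A R45G;A R45W"), "duplicate site")
  expect_error(parse_mutation_string("A B45G"), "non-standard")
})

test_that("Kd conversion follows RT ln(kd_wt/kd_mut)", {
  expect_equal(kd_to_ddg(1e-9, 1e-9), 0)
  # closed form: R*T*ln(0.1) at 298.15 K = -1.364 kcal/mol (3 d.p.)
  expect_equal(round(kd_to_ddg(1e-9, 1e-8), 3), -1.364)
  # antisymmetry
  expect_equal(kd_to_ddg(2e-8, 7e-9), -kd_to_ddg(7e-9, 2e-8))
  expect_error(kd_to_ddg(-1e-9, 1e-9), "domain error")
})

test_that("reverse augmentation obeys the -2 kcal/mol filter exactly", {
  ds <- data.frame(
    complex_id = "cplx1",
    construct = c("A R45G", "A K50A", "A E7Q", "A W9F"),
    ddg = c(-1.0, -2.5, -2.0, 1.2),
    group_id = "cplx1",
    stringsAsFactors = FALSE)
  aug <- augment_with_reverse(ds)
  # size law: forwards + |{ddg >= -2}|
  expect_equal(nrow(aug), 4 + 3)
  rev <- aug[aug$provenance == "reverse", ]
  # -2.5 record gains no partner; boundary -2.0 is retained
  expect_false("A A50K" %in% rev$construct)
  expect_true("A Q7E" %in% rev$construct)
  # every reverse ddg is the exact negation; letters swapped
  expect_equal(rev$ddg, -ds$ddg[rev$partner])
  expect_equal(rev$construct[rev$partner == 1], "A G45R")
  # involution: reversing a reverse reproduces the forward ddg
  rev2 <- augment_with_reverse(
    data.frame(complex_id = "c", construct = rev$construct[1],
               ddg = rev$ddg[1], group_id = "c", stringsAsFactors = FALSE))
  expect_equal(rev2$ddg[2], ds$ddg[1])
  # groups shared between partners
  expect_true(all(rev$group_id == ds$group_id[rev$partner]))
})

test_that("direction labels partition with an inclusive neutral band", {
  ddg <- c(0.5, -0.5, -0.6, 0.51, 2.0, 0, -3)
  lab <- label_direction(ddg)
  expect_equal(lab, c("neutral", "neutral", "decreasing", "increasing",
                      "increasing", "neutral", "decreasing"))
  # labels partition: counts sum to n
  expect_equal(sum(table(lab)), length(ddg))
})

test_that("hot-spot labels apply only to alanine mutations", {
  cons <- c("A R45A", "A R45A", "A R45K", "A R45A;A K50A")
  ddg <- c(-2.3, -0.4, -5, -9)
  expect_equal(label_hotspot(cons, ddg, cutoff = -2),
               c("hot-spot", "non-hot-spot", "not-applicable",
                 "not-applicable"))
  expect_equal(label_hotspot(cons[2], ddg[2], cutoff = -1), "non-hot-spot")
  # boundary inclusive
  expect_equal(label_hotspot("A R45A", -2, cutoff = -2), "hot-spot")
})

test_that("additivity classification follows both stated criteria", {
  expect_equal(classify_additivity(-2.1, c(-1.2, -0.8), "abs_0.2"),
               "additive")
  expect_equal(classify_additivity(-3.0, c(-1.2, -0.8), "abs_0.2"),
               "synergistic")
  expect_equal(classify_additivity(-3.0, c(-1.2, -0.8), "rel_10pct"),
               "synergistic")
  # D/|sum| = 0.2/3.0 ~ 6.7% < 10%
  expect_equal(classify_additivity(-3.2, c(-1.5, -1.5), "rel_10pct"),
               "additive")
  expect_error(classify_additivity(-3, c(-1, NA)), "not-classifiable")
})

test_that("dataset CSV round-trips and converts Kd rows", {
  ds <- data.frame(
    complex_id = c("c1", "c1", "c2"),
    construct = c("A R45G", "A K50A;A E7Q", "B W9F"),
    ddg = c(-1.0, 2.2, NA),
    kd_wt = c(NA, NA, 1e-9),
    kd_mut = c(NA, NA, 1e-8),
    stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".csv")
  write_affinity_csv(ds, tf)
  got <- read_affinity_csv(tf)
  expect_equal(got$ddg[1:2], ds$ddg[1:2])
  expect_equal(round(got$ddg[3], 3), -1.364)
  expect_equal(got$group_id, got$complex_id)
  expect_equal(got$provenance, rep("experimental", 3))
})
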