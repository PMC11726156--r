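# segment_composition: loading, filtering, predominance rule, summaries

toy_records <- function() {
  segment_records(data.frame(
    micrograph_id = c("m1", "m1", "m1", "m1", "m2", "m2"),
    filament_id = c("1", "1", "2", "2", "1", "1"),
    segment_index = c(1L, 2L, 1L, 2L, 1L, 2L),
    type_label = c("I2", "I2", "II2", "I2", "II2", "II2")
  ))
}

test_that("TSV and STAR loaders give identical records on equivalent fixtures", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "micrograph_id\tfilament_id\tsegment_index\ttype_label",
    "mic1.mrc\t1\t1\tI2",
    "mic1.mrc\t1\t2\tI2",
    "mic1.mrc\t2\t1\tII2",
    "mic2.mrc\t1\t1\tII2",
    "mic2.mrc\t1\t2\tother",
    "mic2.mrc\t1\t3\tI2"), tsv)
  star <- tempfile(fileext = ".star")
  writeLines(c(
    "data_particles", "", "loop_",
    "_rlnMicrographName #1",
    "_rlnHelicalTubeID #2",
    "_rlnClassNumber #3",
    "mic1.mrc 1 3",
    "mic1.mrc 1 3",
    "mic1.mrc 2 7",
    "mic2.mrc 1 7",
    "mic2.mrc 1 99",
    "mic2.mrc 1 3"), star)
  cmap <- c("3" = "I2", "7" = "II2")  # class 99 unmapped -> "other"
  a <- load_segment_table(tsv)
  b <- load_segment_table(star, class_map = cmap)
  expect_identical(nrow(a), 6L)
  ord <- function(d) {
    d <- as.data.frame(d)
    d[order(d$micrograph_id, d$filament_id, d$segment_index), ]
  }
  expect_equal(ord(a), ord(b), ignore_attr = TRUE)
  # class map can also come from a JSON file
  mapfile <- tempfile(fileext = ".json")
  jsonlite::write_json(as.list(cmap), mapfile, auto_unbox = TRUE)
  expect_equal(ord(load_segment_table(star, class_map = mapfile)), ord(b),
               ignore_attr = TRUE)
})

test_that("schema and integrity violations are rejected", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("micrograph_id\tfilament_id\ttype_label", "m\t1\tI2"), bad)
  expect_error(load_segment_table(bad), class = "fibril_schema_error")
  dup <- data.frame(micrograph_id = "m", filament_id = "1",
                    segment_index = c(1L, 1L), type_label = "I2")
  expect_error(segment_records(dup), class = "fibril_integrity_error")
})

test_that("micrograph filter keeps micrographs with the required type", {
  rec <- toy_records()
  kept <- filter_micrographs(rec, "I2", 1L)
  expect_setequal(unique(kept$micrograph_id), "m1")
  expect_identical(attr(kept, "n_micrographs_total"), 2L)
  expect_identical(attr(kept, "n_micrographs_selected"), 1L)
  # no micrograph has the type: empty subset
  none <- filter_micrographs(
    segment_records(data.frame(micrograph_id = "m", filament_id = "1",
                               segment_index = 1L, type_label = "II2")),
    "I2")
  expect_identical(nrow(none), 0L)
  # idempotence
  expect_equal(as.data.frame(filter_micrographs(kept, "I2")),
               as.data.frame(kept), ignore_attr = TRUE)
})

test_that("micrograph filter equals brute-force counting on random tables", {
  for (seed in c(101, 102)) {
    set.seed(seed)
    n <- 300
    rec <- segment_records(data.frame(
      micrograph_id = sample(sprintf("m%02d", 1:20), n, replace = TRUE),
      filament_id = as.character(sample(1:3, n, replace = TRUE)),
      segment_index = integer(n), type_label =
        sample(c("I2", "II2", "other"), n, replace = TRUE, prob = c(.1, .8, .1))
    ) |> transform(segment_index = stats::ave(seq_len(n),
        paste(micrograph_id, filament_id), FUN = seq_along)))
    for (mc in c(1L, 2L)) {
      got <- filter_micrographs(rec, "I2", mc)
      want <- brute_filter(rec, "I2", mc)
      expect_setequal(unique(got$micrograph_id), unique(want$micrograph_id))
      expect_identical(nrow(got), nrow(want))
    }
  }
})

test_that("predominance categories match exhaustive enumeration for all small counts", {
  cases <- expand.grid(a = 0:6, b = 0:6)
  cases <- cases[cases$a + cases$b >= 1 & cases$a + cases$b <= 6, ]
  for (r in seq_len(nrow(cases))) {
    a <- cases$a[r]; b <- cases$b[r]
    rec <- segment_records(data.frame(
      micrograph_id = "m", filament_id = "1",
      segment_index = seq_len(a + b),
      type_label = c(rep("I2", a), rep("II2", b))))
    comp <- compose_filaments(rec)
    expect_identical(comp$category, brute_category(a, b),
                     info = sprintf("a=%d b=%d", a, b))
    expect_equal(comp$fraction_I2, a / (a + b))
  }
})

test_that("the 90% threshold is inclusive and counts use typed segments only", {
  # 9 of 10 typed: exactly 90% -> predominant
  rec <- segment_records(data.frame(
    micrograph_id = "m", filament_id = "1", segment_index = 1:12,
    type_label = c(rep("I2", 9), "II2", "other", "other")))
  comp <- compose_filaments(rec, threshold = 0.90)
  expect_identical(comp$category, "predominant-I2")
  expect_equal(comp$fraction_I2, 0.9)
  expect_identical(comp$n_typed, 10L)
  expect_identical(comp$n_other, 2L)
  expect_identical(comp$n_segments, 12L)
  # pure filament
  pure <- compose_filaments(segment_records(data.frame(
    micrograph_id = "m", filament_id = "1", segment_index = 1:10,
    type_label = "I2")))
  expect_identical(pure$category, "exclusive-I2")
  # a filament with only "other" segments is excluded with a message
  mixed_tab <- segment_records(data.frame(
    micrograph_id = "m", filament_id = c("1", "2"), segment_index = 1L,
    type_label = c("I2", "other")))
  expect_message(comp2 <- compose_filaments(mixed_tab), "dropped 1")
  expect_identical(nrow(comp2), 1L)
  expect_error(compose_filaments(toy_records(), threshold = 0.4),
               class = "fibril_argument_error")
})

test_that("strongly_mixed applies the double threshold inclusively", {
  comp <- data.frame(n_I2 = c(10, 9, 50, 0), n_II2 = c(10, 50, 9, 60))
  sm <- strongly_mixed(comp, min_each = 10L)
  expect_identical(sm$count, 1L)
  expect_identical(rownames(sm$filaments), "1")
  # brute-force double-threshold scan on random tables
  set.seed(111)
  rand <- data.frame(n_I2 = rpois(200, 8), n_II2 = rpois(200, 8))
  expect_identical(strongly_mixed(rand, 10L)$count,
                   sum(rand$n_I2 >= 10 & rand$n_II2 >= 10))
})

test_that("summary conserves counts and is permutation invariant", {
  rec <- toy_records()
  comp <- compose_filaments(rec)
  rep1 <- summarize_composition(comp, rec)
  # conservation: per-type counts over filaments equal table totals
  expect_identical(sum(comp$n_I2), sum(rec$type_label == "I2"))
  expect_identical(sum(comp$n_II2), sum(rec$type_label == "II2"))
  expect_identical(sum(rep1$histogram$count), rep1$summary$n_filaments)
  # permutation invariance
  set.seed(121)
  shuf <- rec[sample(nrow(rec)), ]
  rep2 <- summarize_composition(compose_filaments(shuf), shuf)
  expect_equal(rep1$summary, rep2$summary)
  expect_equal(rep1$histogram, rep2$histogram)
  o <- function(d) d[order(d$micrograph_id, d$filament_id), ]
  expect_equal(o(rep1$filaments), o(rep2$filaments), ignore_attr = TRUE)
})

test_that("all-pure tables give histogram mass only at the ends", {
  rec <- segment_records(data.frame(
    micrograph_id = rep(c("m1", "m2"), each = 10),
    filament_id = rep(c("1", "2"), each = 10),
    segment_index = rep(1:10, 2),
    type_label = rep(c("I2", "II2"), each = 10)))
  rep <- summarize_composition(compose_filaments(rec), rec)
  expect_equal(rep$summary$fraction_exclusive_or_predominant, 1.0)
  expect_identical(rep$summary$strongly_mixed_count, 0L)
  expect_identical(rep$histogram$count[c(1, 10)], c(1L, 1L))
  expect_identical(sum(rep$histogram$count[2:9]), 0L)
})

test_that("threshold monotonicity: stricter thresholds never gain filaments", {
  tab <- generate_segment_table(segment_table_config(
    n_micrographs = 40, epsilon = 0.1, seed = 131))
  fracs <- vapply(c(0.75, 0.85, 0.9, 0.95, 1.0), function(th) {
    comp <- compose_filaments(tab$records, threshold = th)
    mean(comp$category != "mixed")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("bundled bookkeeping counts give the published shares", {
  cc <- classification_counts()
  total <- cc$count[cc$quantity == "segments_after_2d"]
  i2 <- cc$count[cc$quantity == "class3d_I2_segments"]
  ii2 <- cc$count[cc$quantity == "class3d_II2_clean_segments"] +
    cc$count[cc$quantity == "class3d_II2_realigned_segments"]
  expect_equal(percent_share(ii2, total), 66)
  expect_equal(percent_share(i2, total), 5)
  expect_equal(round(ii2 / i2), 13)
})
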