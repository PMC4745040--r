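test_that("record-level invariants are enforced on construction", {
  expect_error(colonist_record("x", 4, 3.0, branching_times = 5.0),
               "not younger than colonisation")
  expect_error(colonist_record("x", 6, 1), "status")
  expect_error(colonist_record("x", 3, -1), "positive age")
  expect_error(colonist_record("x", 3, 1, n_missing = -1), "n_missing")
  expect_error(colonist_record("x", 2, 1, branching_times = 0.5),
               "without branching")
  expect_error(colonist_record("x", 4, 2, branching_times = c(1, 1)),
               "strictly decreasing")
  # branching times are stored oldest first regardless of input order
  r <- colonist_record("x", 4, 3, branching_times = c(0.5, 2, 1))
  expect_equal(r$branching_times, c(2, 1, 0.5))
  expect_true(colonist_record("x", 2, 1)$max_age)
})

test_that("dataset-level invariants are enforced", {
  expect_error(island_dataset(4, 1000, class_fractions = c(a = 0.5)),
               "sum to 1")
  expect_error(
    island_dataset(4, 1000,
                   list(colonist_record("late", 3, 5)), c(all = 1)),
    "exceeds island age")
  expect_error(
    island_dataset(4, 1000,
                   list(colonist_record("x", 3, 1, lineage_class = "zz")),
                   c(all = 1)),
    "no positive mainland fraction")
  # class colonist count may not exceed the class share of the pool
  recs <- lapply(1:3, function(i)
    colonist_record(paste0("r", i), 3, 1, lineage_class = "rare"))
  expect_error(island_dataset(4, 1000, recs,
                              c(rare = 0.002, common = 0.998)),
               "mainland share")
  # empty island is a valid dataset
  d <- island_dataset(4, 1000)
  expect_s3_class(d, "island_dataset")
  expect_length(d$colonists, 0)
})

test_that("record species accounting follows the status definitions", {
  expect_equal(record_k(colonist_record("x", 1)), 0L)
  expect_equal(record_k(colonist_record("x", 2, 1)), 1L)
  expect_equal(record_n_species(colonist_record("x", 4, 2, c(1, 0.5),
                                                n_missing = 2)), 5L)
  # status 5 counts the co-occurring non-endemic population
  expect_equal(record_n_species(colonist_record("x", 5, 2, 1)), 3L)
})

test_that("the shipped synthetic fixture mirrors the 8-colonisation design", {
  d <- read_island_dataset(fixture_path("synthetic_archipelago.json"))
  expect_length(d$colonists, 8)
  expect_equal(d$island_age, 4)
  expect_equal(d$M, 1000)
  expect_equal(sum(vapply(d$colonists, record_n_species, integer(1))), 25L)
  expect_equal(sum(d$class_fractions), 1)
})

test_that("JSON and TSV round-trips reproduce datasets exactly", {
  withr::local_seed(7)
  for (rep in 1:8) {
    d <- random_dataset()
    for (fmt in c("json", "tsv")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_island_dataset(d, path, fmt)
      expect_dataset_equal(d, read_island_dataset(path, fmt))
    }
  }
  # empty dataset round-trips too
  d0 <- island_dataset(4.5, 100)
  for (fmt in c("json", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_island_dataset(d0, path, fmt)
    expect_dataset_equal(d0, read_island_dataset(path, fmt))
  }
  # the upper-bound flag survives the round-trip
  d2 <- island_dataset(4, 100, list(colonist_record("ub", 2, 3.5)),
                       c(all = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_island_dataset(d2, path)
  expect_true(read_island_dataset(path)$colonists[[1]]$max_age)
})

test_that("malformed files give parse errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"island_age": 4}', path)
  expect_error(read_island_dataset(path), "missing field")
  writeLines('{"island_age": 4, "M": 10, "class_fractions": {"all": 1},
              "colonists": [{"label": "x"}]}', path)
  expect_error(read_island_dataset(path), "no status")
  writeLines("not json at all {", path)
  expect_error(read_island_dataset(path), "parse error")
  expect_error(read_island_dataset("/nonexistent/f.json"), "not found")
})
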