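# shared fixtures: built in code, deterministic under withr seeds

fixture_path <- function(name)
  system.file("extdata", name, package = "islandassembly", mustWork = TRUE)

# mild generic parameters used across oracle checks
params_mild <- function() parameter_set(0.3, 0.4, 0.3, 0.25, Inf)
params_dd <- function() parameter_set(0.4, 1.2, 0.5, 0.6, K_prime = 3)

two_class_params <- function() list(
  "DF-type" = parameter_set(0.002, 1.5, 1.0, 0.8, Inf),
  "non-DF-type" = parameter_set(0.002, 0.3, 1.0, 0.1, Inf))

two_class_fractions <- function() c("DF-type" = 0.163, "non-DF-type" = 0.837)

small_dataset <- function() island_dataset(
  island_age = 4, M = 1000,
  colonists = list(
    colonist_record("clade", 4, 2.5, c(1.2, 0.4)),
    colonist_record("nonend", 3, 1.0),
    colonist_record("bounded", 2, 4)),
  class_fractions = c(all = 1))

# a random valid dataset for round-trip property tests
random_dataset <- function() {
  age <- runif(1, 2, 10)
  n <- sample(0:6, 1)
  classes <- c("a", "b")
  recs <- lapply(seq_len(n), function(i) {
    st <- sample(1:5, 1)
    tc <- runif(1, 0.1, age)
    nb <- if (st >= 4) sample(0:4, 1) else 0
    bt <- if (nb) sort(runif(nb, 0.01, tc * 0.95), decreasing = TRUE)
          else numeric()
    colonist_record(paste0("r", i), st,
                    if (st == 1) NA_real_ else tc, bt,
                    n_missing = sample(0:2, 1),
                    lineage_class = sample(classes, 1))
  })
  island_dataset(age, 500, recs, c(a = 0.3, b = 0.7))
}

expect_dataset_equal <- function(d1, d2) {
  expect_equal(d1$island_age, d2$island_age)
  expect_equal(d1$M, d2$M)
  expect_equal(d1$class_fractions, d2$class_fractions)
  expect_equal(length(d1$colonists), length(d2$colonists))
  for (i in seq_along(d1$colonists))
    expect_equal(d1$colonists[[i]], d2$colonists[[i]])
}
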