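test_that("the model registry defines the documented parameter counts", {
  expect_equal(islandassembly:::n_free_params(island_model("M1")), 5L)
  expect_equal(islandassembly:::n_free_params(island_model("M1p")), 4L)
  expect_equal(islandassembly:::n_free_params(island_model("M5")), 6L)
  expect_equal(islandassembly:::n_free_params(island_model("M8")), 7L)
  expect_error(model_spec("none", "all",
                          fixed = list(gamma = 0.1, lambda_c = 0.1,
                                       lambda_a = 0.1, mu = 0.1)),
               "no free parameters")
  # fixed parameters are honoured when expanding to per-class sets
  m <- model_spec("fx", c("a", "b"),
                  sharing = list(mu = "per-class"),
                  fixed = list("mu[b]" = 0.5))
  est <- setNames(rep(0.1, islandassembly:::n_free_params(m)),
                  vapply(islandassembly:::param_layout(m), `[[`, "", "name"))
  pbc <- islandassembly:::params_from_vector(m, est)
  expect_equal(pbc$b$mu, 0.5)
  expect_equal(pbc$a$mu, 0.1)
})

test_that("information weights follow the exp(-delta/2) formula", {
  f <- function(name, bic, ll = -10)
    structure(list(model = list(name = name), loglik = ll, bic = bic,
                   aic = bic, data_fingerprint = c(1, 2, 3, 4)),
              class = "fit_result")
  # equal criteria -> equal weights
  w <- information_weights(list(f("a", 100), f("b", 100)))
  expect_equal(unname(w), c(0.5, 0.5))
  # delta = 2 ln(100): weights (0.99, 0.01) (direct evaluation)
  w2 <- information_weights(list(f("a", 100), f("b", 100 + 2 * log(100))))
  expect_equal(unname(w2), c(1, 0.01) / 1.01, tolerance = 1e-10)
  # shift invariance
  w3 <- information_weights(list(f("a", 350), f("b", 350 + 2 * log(100))))
  expect_equal(w2, w3)
  expect_equal(sum(w2), 1)
  # different datasets are rejected
  g <- f("c", 90)
  g$data_fingerprint <- c(9, 9, 9, 9)
  expect_error(information_weights(list(f("a", 100), g)), "same dataset")
})

test_that("a one-parameter fit agrees with a grid-search oracle", {
  d <- island_dataset(4, 200, list(
    colonist_record("a", 3, 1.2), colonist_record("b", 3, 0.4),
    colonist_record("c", 2, 4)), c(all = 1))
  m <- model_spec("gamma-only", "all",
                  fixed = list(lambda_c = 0, lambda_a = 0, mu = 0))
  fit <- fit_model(d, m, n_starts = 5, seed = 3)
  grid <- 10^seq(-4, 0, length.out = 2000)
  ll <- vapply(grid, function(g)
    loglik_dataset(d, list(all = parameter_set(g, 0, 0, 0))), numeric(1))
  expect_equal(unname(fit$estimates["gamma"]), grid[which.max(ll)],
               tolerance = 1e-2)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("fitting is deterministic under a fixed seed", {
  d <- small_dataset()
  m <- island_model("M1p", classes = "all")
  f1 <- fit_model(d, m, n_starts = 1, seed = 11, maxit = 200)
  f2 <- fit_model(d, m, n_starts = 1, seed = 11, maxit = 200)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(f1$bic, -2 * f1$loglik + f1$n_params * log(d$M))
  expect_equal(f1$aic, -2 * f1$loglik + 2 * f1$n_params)
})

test_that("a nested model never beats the nesting model by likelihood", {
  withr::local_seed(31)
  d <- simulate_island(two_class_params(), 500, two_class_fractions(),
                       4)$dataset
  f_eq <- fit_model(d, island_model("M1p"), n_starts = 4, seed = 5,
                    maxit = 250)
  f_diff <- fit_model(d, island_model("M5"), n_starts = 4, seed = 5,
                      maxit = 250)
  expect_gte(f_diff$loglik, f_eq$loglik - 1e-4)
})

test_that("sensitivity sweeps refit across an axis and report row errors", {
  d <- island_dataset(4, 1000, list(
    colonist_record("a", 3, 3.0, lineage_class = "DF-type"),
    colonist_record("b", 3, 0.9, lineage_class = "non-DF-type"),
    colonist_record("upperbound-b", 2, 2.5,
                    lineage_class = "non-DF-type")),
    two_class_fractions())
  m <- model_spec("gamma-only", c("DF-type", "non-DF-type"),
                  fixed = list(lambda_c = 0, lambda_a = 0, mu = 0))
  # degenerate sweep equals a direct fit
  sw <- sensitivity_sweep(d, m, axis = "island_age", values = 4,
                          n_starts = 2, seed = 9)
  fit <- fit_model(d, m, n_starts = 2, seed = 9)
  expect_equal(sw$loglik[1], fit$loglik, tolerance = 1e-6)
  expect_equal(sw$gamma[1], unname(fit$estimates["gamma"]),
               tolerance = 1e-4)
  # age sweep: one row per value, errors contained to their rows
  sw2 <- sensitivity_sweep(d, m, axis = "island_age",
                           values = c(2, 4, 6), n_starts = 1, seed = 9)
  expect_equal(nrow(sw2), 3)
  expect_match(sw2$error[1], "older|younger")  # age 2 < oldest colonisation
  expect_true(all(sw2$error[2:3] == ""))
  # class-fraction sweep keeps fractions summing to one
  sw3 <- sensitivity_sweep(d, m, axis = "class_fraction",
                           values = c(0.05, 0.163, 0.28),
                           class = "DF-type", n_starts = 1, seed = 9)
  expect_equal(nrow(sw3), 3)
  expect_true(all(is.finite(sw3$loglik)))
  # fixing one record's colonisation time
  sw4 <- sensitivity_sweep(d, m, axis = "fixed_colonisation_time",
                           values = c(0.5, 2.0),
                           record_label = "upperbound-b", n_starts = 1,
                           seed = 9)
  expect_equal(nrow(sw4), 2)
  expect_true(all(is.finite(sw4$loglik)))
})

test_that("the immigration estimate shrinks when the pool grows", {
  # same data, larger mainland pool: the ML immigration rate must drop
  # (gamma-only model, so only non-diverged records are usable)
  d1 <- island_dataset(4, 1000, list(
    colonist_record("a", 3, 1.2), colonist_record("b", 3, 0.4),
    colonist_record("c", 2, 4), colonist_record("d", 3, 2.2)), c(all = 1))
  d2 <- d1
  d2$M <- 500
  m <- model_spec("gamma-only", "all",
                  fixed = list(lambda_c = 0, lambda_a = 0, mu = 0))
  g1000 <- fit_model(d1, m, n_starts = 3, seed = 2)$estimates["gamma"]
  g500 <- fit_model(d2, m, n_starts = 3, seed = 2)$estimates["gamma"]
  expect_lt(g1000, g500)
})
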