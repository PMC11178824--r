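# Objective construction, searches, Michaelis-Menten fitting and ensemble
# filtering.

test_that("weighted objective matches hand computation and scaling", {
  p <- phos_preset("M4")
  suite <- gen_calibration_suite(p, "PP1", noise_model(0, 1), seed = 21)
  pm <- phos_parmap(p, enzymes = "PP1")
  obj <- phos_objective(suite$dephos_34$bands)
  # truth parameters reproduce the noiseless data
  expect_lt(objective_wsse(parmap_truth(pm), obj, pm), 1e-6)
  # hand computation on a tiny synthetic two-experiment toy
  ds <- suite$dephos_34$bands
  sim <- phoscycle:::.simulate_dataset(p, ds)
  obs <- as.matrix(ds$summary[phoscycle:::.fraction_cols])
  sdm <- as.matrix(ds$summary[paste0("sd_", phoscycle:::.fraction_cols)])
  hand <- sum(((obs - sim) / sdm)^2) / length(obs)
  expect_equal(objective_wsse(parmap_truth(pm), obj, pm), hand,
               tolerance = 1e-9)
  # doubling every sd divides the objective by four
  ds2 <- ds
  for (cc in paste0("sd_", phoscycle:::.fraction_cols)) {
    ds2$summary[[cc]] <- 2 * ds2$summary[[cc]]
  }
  th <- parmap_truth(pm) + 0.1
  expect_equal(objective_wsse(th, phos_objective(ds2), pm),
               objective_wsse(th, phos_objective(ds), pm) / 4,
               tolerance = 1e-9)
  # invariance under dataset reordering
  obj_ab <- phos_objective(list(suite$dephos_34$bands, suite$ir_a))
  obj_ba <- phos_objective(list(suite$ir_a, suite$dephos_34$bands))
  expect_equal(objective_wsse(th, obj_ab, pm),
               objective_wsse(th, obj_ba, pm))
})

test_that("genetic search optimizes a convex benchmark deterministically", {
  qf <- function(x) sum((x - c(1, -0.5))^2) + 1
  ga <- genetic_search(qf, c(-3, -3), c(3, 3), population = 25,
                       generations = 50, seed = 9)
  expect_lt(ga$value - 1, 0.01)
  ga2 <- genetic_search(qf, c(-3, -3), c(3, 3), population = 25,
                        generations = 50, seed = 9)
  expect_identical(ga$history, ga2$history)
  expect_true(all(diff(ga$history) <= 0))
  expect_true(all(ga$par >= -3 & ga$par <= 3))
})

test_that("Hooke-Jeeves refines to the optimum and never worsens", {
  qf <- function(x) sum((x - c(0.3, -1.2, 2))^2)
  hj <- hooke_jeeves(qf, c(-2, 2, -2), rep(-4, 3), rep(4, 3),
                     max_iter = 200, tol = 1e-7)
  expect_lt(sqrt(hj$value), 1e-4)
  # start at the optimum: stays there
  hj0 <- hooke_jeeves(qf, c(0.3, -1.2, 2), rep(-4, 3), rep(4, 3))
  expect_equal(hj0$par, c(0.3, -1.2, 2))
  # returned value never exceeds the starting value
  start <- c(3, 3, 3)
  expect_lte(hooke_jeeves(qf, start, rep(-4, 3), rep(4, 3),
                          max_evals = 50)$value, qf(start))
})

test_that("Michaelis-Menten initial-rate fitting recovers and flags", {
  s <- c(0.5, 1, 2, 5, 10, 25, 60) * 1e-6
  v <- oracle_mm_curve(0.1, 1, s, 5e-6)   # Vmax 0.1, Km 5e-6
  fit <- fit_mm_initial_rates(data.frame(substrate_molar = s, rate = v))
  expect_equal(fit$Vmax, 0.1, tolerance = 1e-3)
  expect_equal(fit$Km, 5e-6, tolerance = 1e-3)
  expect_length(fit$flags, 0)
  # data collected only near half-saturation leave Km poorly constrained
  s2 <- c(4.5, 4.8, 5, 5.2, 5.5) * 1e-6
  set.seed(2)
  v2 <- oracle_mm_curve(0.1, 1, s2, 5e-6) * (1 + rnorm(5, 0, 0.05))
  fit2 <- fit_mm_initial_rates(data.frame(substrate_molar = s2, rate = v2))
  expect_true(length(fit2$flags) > 0)
  expect_error(
    fit_mm_initial_rates(data.frame(substrate_molar = s, rate = -v)),
    "positive")
})

test_that("ensembles are reproducible and filtering isolates a planted
           outlier", {
  p <- phos_preset("M4")
  suite <- gen_calibration_suite(p, "PP1", noise_model(0, 1), seed = 31)
  pm <- phos_parmap(p, enzymes = "PP1",
                    groups = c("PP1.b", "PP1.aprime"))
  obj <- phos_objective(suite$dephos_ab$bands)
  ens <- ensemble_calibrate(obj, pm, n_runs = 2, seed = 4,
                            ga_generations = 3, ga_population = 8,
                            hj_max_evals = 20)
  ens2 <- ensemble_calibrate(obj, pm, n_runs = 2, seed = 4,
                             ga_generations = 3, ga_population = 8,
                             hj_max_evals = 20)
  expect_identical(ens$theta, ens2$theta)
  expect_identical(ens$objective, ens2$objective)

  # planted outlier among copies of the truth
  truth <- parmap_truth(pm)
  theta <- rbind(matrix(rep(truth, 5), 5, byrow = TRUE),
                 truth + c(1.5, -1, 0.5, 0.5, 0, 0))
  colnames(theta) <- pm$names
  fake <- structure(list(parmap = pm, theta = theta,
                         objective = rep(0, 6), seeds = 1:6,
                         flagged = rep(FALSE, 6)),
                    class = "phos_ensemble")
  filt <- filter_ensemble(fake, suite$dephos_ab$bands)
  expect_identical(which(filt$flagged), 6L)
  # identical members: nothing flagged (zero-SD edge case)
  all_same <- fake
  all_same$theta <- matrix(rep(truth, 4), 4, byrow = TRUE,
                           dimnames = list(NULL, pm$names))
  all_same$objective <- rep(0, 4); all_same$seeds <- 1:4
  all_same$flagged <- rep(FALSE, 4)
  filt2 <- filter_ensemble(all_same, suite$dephos_ab$bands)
  expect_false(any(filt2$flagged))
})
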