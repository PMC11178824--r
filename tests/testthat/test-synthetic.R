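# Synthetic-data generators: determinism, truth-tracking, and the
# qualitative features of the reference biochemistry.

test_that("generation is deterministic and truth travels with the data", {
  p <- phos_preset("M4")
  a <- gen_dephos_timecourse(p, "PP1", noise_model(0.03, 3), seed = 5)
  b <- gen_dephos_timecourse(p, "PP1", noise_model(0.03, 3), seed = 5)
  expect_identical(a$bands$data, b$bands$data)
  expect_identical(a$occupancy$data, b$occupancy$data)
  d <- gen_dephos_timecourse(p, "PP1", noise_model(0.03, 3), seed = 6)
  expect_false(identical(a$bands$data, d$bands$data))
  # zero noise reproduces the simulator truth exactly
  z <- gen_dephos_timecourse(p, "PP1", noise_model(0, 1), seed = 5)
  expect_equal(unname(as.matrix(z$bands$data[phoscycle:::.fraction_cols])),
               unname(as.matrix(z$bands$meta$truth)), tolerance = 1e-12)
  expect_error(gen_dephos_timecourse(p, "PKA"), "PP1 or PP2A")
})

test_that("dephosphorylation truth shows the hierarchical pattern", {
  p <- phos_preset("M4")
  for (pp in c("PP1", "PP2A")) {
    z <- gen_dephos_timecourse(p, pp, noise_model(0, 1), seed = 1,
                               times_s = c(0, 300, 600, 1200, 2400, 3600))
    tr <- z$bands$meta$truth
    t20 <- 5; t60 <- 6                       # rows for 20 and 60 min
    # rapid 3P/4P loss
    expect_lt(tr$f3[t60] + tr$f4[t60], 0.02)
    # slow mono-phosphorylated tail, still declining
    expect_gt(tr$f1[t20], tr$f1[t60])
    expect_gt(tr$f1[t60], 0)
  }
  # the late 2P pool is ab, not ad: check on the state-level truth
  net <- phos_network("M4")
  y0 <- make_state(net, c(abd = 1e-5, abgd = 1e-5))
  tc <- integrate_adaptive(p, enzyme_levels(PP1 = 1e-7), y0, 2400)
  late <- tc$states[nrow(tc$states), ]
  expect_gt(late["ab"] / max(late["ab"] + late["ad"], 1e-30), 0.9)
})

test_that("initial-rate data approach the analytic MM curve as quench -> 0", {
  p <- phos_preset("M4")
  grid <- c(2, 5, 10, 20, 50) * 1e-6
  ir <- gen_initial_rate_dataset(p, "PP1", "a", grid, quench_s = 1,
                                 noise = noise_model(0, 1), seed = 1)
  r <- p$rates[p$rates$id == "PP1:a>0P", ]
  expect_equal(ir$meta$truth_rate,
               oracle_mm_curve(r$kcat, 1e-7, grid, r$Km),
               tolerance = 0.01)
  expect_false(ir$meta$quench_warning)
  # zero-substrate row gives zero rate
  ir0 <- gen_initial_rate_dataset(p, "PP1", "a", c(0, grid), 60,
                                  noise = noise_model(0, 1), seed = 1)
  expect_equal(ir0$meta$truth_rate[1], 0)
  # an over-long quench is flagged
  irw <- gen_initial_rate_dataset(p, "PP1", "d", grid, quench_s = 600,
                                  noise = noise_model(0, 1), seed = 1)
  expect_true(irw$meta$quench_warning)
})

test_that("fitted Km ratio of the alpha and delta assays is about four", {
  p <- phos_preset("M4")
  suite <- gen_calibration_suite(p, "PP1", noise_model(0, 1), seed = 2)
  fa <- fit_mm_initial_rates(suite$ir_a)
  fd <- fit_mm_initial_rates(suite$ir_d)
  expect_equal(fa$Km / fd$Km, 4, tolerance = 0.15)
  # and alpha turns over more slowly
  expect_lt(fa$Vmax / suite$ir_a$meta$enzymes[["PP1"]],
            fd$Vmax / suite$ir_d$meta$enzymes[["PP1"]])
})

test_that("dose-response generator covers the switch and its backgrounds", {
  p <- phos_preset("M4")
  grid <- c(0, 10^seq(-9, -6, length.out = 6))
  ds <- gen_dose_response_dataset(p, grid, "PP1", 0.5e-6,
                                  noise = noise_model(0, 1), seed = 1)
  tr <- as.matrix(ds$meta$truth)
  expect_gt(tr[1, 1], 0.999)             # PKA = 0: all unphosphorylated
  expect_gt(tr[7, 4], 0.5)               # high PKA: 3P dominant
  expect_true(all(ds$meta$converged))
  # PKCe background with PP2A drives the 4P state at high PKA
  ds4 <- gen_dose_response_dataset(p, grid, "PP2A", 0.1e-6,
                                   background = c(PKCe = 1e-7),
                                   noise = noise_model(0, 1), seed = 1)
  tr4 <- as.matrix(ds4$meta$truth)
  expect_gt(tr4[7, 5], 0.5)
})

test_that("distribution datasets round-trip their generating truth", {
  p <- phos_preset("M4")
  enz <- enzyme_levels(PKA = 1.36e-7, RSK2 = 1e-8, PKCe = 2e-8,
                       PP1 = 5e-8, PP2A = 9.5e-7)
  ds <- gen_distribution_dataset(p, enz, noise_model(0, 1), seed = 3)
  expect_equal(unname(unlist(ds$data[phoscycle:::.fraction_cols])),
               ds$meta$truth, tolerance = 1e-12)
  # all-zero kinases: pure 0P
  ds0 <- gen_distribution_dataset(p, enzyme_levels(PP1 = 1e-7),
                                  noise_model(0, 1), seed = 3)
  expect_equal(ds0$meta$truth, c(1, 0, 0, 0, 0), tolerance = 1e-3)
  # enzyme vectors differing 3-fold in PKA are distinguishable
  dsA <- gen_distribution_dataset(p, enzyme_levels(PKA = 3e-8, PP1 = 1e-7),
                                  noise_model(0, 1), seed = 3)
  dsB <- gen_distribution_dataset(p, enzyme_levels(PKA = 9e-8, PP1 = 1e-7),
                                  noise_model(0, 1), seed = 3)
  expect_gt(max(abs(dsA$meta$truth - dsB$meta$truth)), 0.05)
})
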