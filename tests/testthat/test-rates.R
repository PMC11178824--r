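# Rate laws and the assembled ODE right-hand side.

test_that("competitive MM rate matches its closed forms and oracle", {
  # half-saturation, single substrate
  expect_equal(mm_competitive_rate(1e-7, 1e-5, 2, 1e-5), 2 * 1e-7 / 2)
  expect_equal(mm_competitive_rate(1e-7, 0, 2, 1e-5), 0)
  expect_error(mm_competitive_rate(-1, 1, 1, 1), "negative")
  set.seed(11)
  for (k in 1:50) {
    n <- sample(2:4, 1)
    s <- stats::runif(n, 0, 5e-5)
    K <- 10^stats::runif(n, -6, -4)
    kcat <- stats::runif(n, 0.1, 20)
    e <- 10^stats::runif(1, -8, -6)
    i <- sample(n, 1)
    competing <- lapply(setdiff(seq_len(n), i),
                        function(j) c(s[j], K[j]))
    got <- mm_competitive_rate(e, s[i], kcat[i], K[i], competing)
    expect_equal(got, oracle_mm_rate(e, s, K, kcat, i),
                 tolerance = 1e-12)
    # printed denominator form equals the kappa form
    kappa <- sum(s / K)
    alt <- kcat[i] * e * (s[i] / K[i]) / (1 + kappa)
    expect_equal(got, alt, tolerance = 1e-12)
  }
})

test_that("phenomenological activation is hyperbolic in the 2P/3P pool", {
  expect_equal(phenomenological_alpha_rate(1e-8, 0, 0.05, 0.5), 1e-8)
  expect_equal(phenomenological_alpha_rate(1e-8, 10, 0.05, 0.05),
               1e-8 * 6)
  expect_equal(phenomenological_alpha_rate(1e-8, 10, 1e-6, 1),
               1e-8 * 11, tolerance = 1e-5)
  expect_error(phenomenological_alpha_rate(1e-8, 10, 0.05, 1.2), "0, 1")
})

test_that("allosteric rate law has the correct limits", {
  # no activator, no competitors: plain MM
  expect_equal(allosteric_rate(1e-7, 1e-5, 0, 2, 1e-5, 5, 1e-6, 0.5),
               2 * 1e-7 * 1e-5 / (1e-5 + 1e-5))
  # k_A = k_j, lambda = 1, K_A -> Inf reduces to the activator-free value
  v0 <- allosteric_rate(1e-7, 1e-5, 0, 2, 1e-5, 2, 1e30, 1)
  v1 <- allosteric_rate(1e-7, 1e-5, 5e-6, 2, 1e-5, 2, 1e30, 1)
  expect_equal(v1, v0, tolerance = 1e-9)
  # a -> infinity saturates toward k_A * e_T
  v_inf <- allosteric_rate(1e-7, 1e-2, 1e3, 2, 1e-5, 5, 1e-6, 0.5)
  expect_equal(v_inf, 5 * 1e-7, tolerance = 1e-3)
  expect_error(allosteric_rate(1e-7, 1e-5, -1, 2, 1e-5, 5, 1e-6, 0.5),
               "negative")
})

test_that("tQSSA rate matches direct evaluation and its bounds", {
  # single substrate, e_T = K, s = K + e_T: direct evaluation of the rate
  # law gives k*e_T/2
  K <- 1e-6
  expect_equal(tqssa_rate(K, 2 * K, 3, K), 3 * K / 2)
  # converges to the competitive MM law when e_T sits far below every
  # Michaelis constant in the competition
  set.seed(3)
  for (k in 1:20) {
    K <- 10^stats::runif(1, -6, -4)
    s <- stats::runif(1, 0, 5e-5)
    kcat <- stats::runif(1, 0.1, 10)
    K2 <- 10^stats::runif(1, -6, -4)
    comp <- list(c(stats::runif(1, 0, 2e-5), K2))
    eT <- 1e-6 * min(K, K2)
    expect_equal(tqssa_rate(eT, s, kcat, K, comp),
                 mm_competitive_rate(eT, s, kcat, K, comp),
                 tolerance = 1e-6)
    # bound: rate <= kcat * e_T
    expect_lte(tqssa_rate(1e-7, s, kcat, K, comp), kcat * 1e-7)
  }
})

test_that("rates are nonnegative and monotone in substrate and enzyme", {
  set.seed(5)
  for (k in 1:20) {
    K <- 10^stats::runif(1, -6, -4)
    kcat <- stats::runif(1, 0.1, 10)
    comp <- list(c(stats::runif(1, 0, 2e-5), 1e-5))
    s <- sort(stats::runif(2, 0, 5e-5))
    e <- sort(10^stats::runif(2, -9, -6))
    expect_gte(mm_competitive_rate(e[1], s[1], kcat, K, comp), 0)
    expect_lte(mm_competitive_rate(e[1], s[1], kcat, K, comp),
               mm_competitive_rate(e[1], s[2], kcat, K, comp))
    expect_lte(mm_competitive_rate(e[1], s[1], kcat, K, comp),
               mm_competitive_rate(e[2], s[1], kcat, K, comp))
  }
})

test_that("ode_rhs conserves mass and matches a hand-written toy cycle", {
  for (v in c("M1", "M2", "M3", "M4")) {
    p <- phos_preset(v)
    net <- phos_network(v)
    enz <- enzyme_levels(PKA = 1e-7, RSK2 = 2e-8, PKCe = 5e-8,
                         PP1 = 1e-7, PP2A = 5e-8)
    set.seed(17)
    for (k in 1:5) {
      y <- stats::runif(net$n_forms, 0, 5e-6)
      dy <- ode_rhs(0, y, p, enz)
      expect_lt(abs(sum(dy)), 1e-15 * max(abs(dy), 1e-300) * net$n_forms)
    }
    # zero enzymes: no flux (isomerization may still act in M4)
    y <- stats::runif(net$n_forms, 0, 5e-6)
    dy0 <- ode_rhs(0, y, p, enzyme_levels())
    if (v != "M4") expect_equal(dy0, rep(0, 8))
  }
  expect_error(ode_rhs(0, numeric(3), phos_preset("M1"), enzyme_levels()),
               "match")

  # toy: M1 with all reactions silenced except 0P <-> a
  p <- phos_preset("M1")
  keep <- p$rates$id %in% c("PKA:0P>a", "PP1:a>0P")
  p$rates$kcat[!keep] <- 0
  enz <- enzyme_levels(PKA = 2e-8, PP1 = 3e-8)
  net <- phos_network("M1")
  y <- make_state(net, c(`0P` = 8e-6, a = 4e-6, ab = 1e-6))
  # hand-written competitive rates: PKA binds 0P, a, ab, d, ad, abd (its
  # substrates); PP1 binds abg, abgd, d, ad, abd, abgd, ab, a
  r <- p$rates
  kap_pka <- sum(y[r$sub[r$enzyme == "PKA"]] / r$Km[r$enzyme == "PKA"])
  kap_pp1 <- sum(y[r$sub[r$enzyme == "PP1"]] / r$Km[r$enzyme == "PP1"])
  kcat_k <- r$kcat[r$id == "PKA:0P>a"]; K_k <- r$Km[r$id == "PKA:0P>a"]
  kcat_p <- r$kcat[r$id == "PP1:a>0P"]; K_p <- r$Km[r$id == "PP1:a>0P"]
  vk <- kcat_k * 2e-8 * (y["0P"] / K_k) / (1 + kap_pka)
  vp <- kcat_p * 3e-8 * (y["a"] / K_p) / (1 + kap_pp1)
  dy <- ode_rhs(0, y, p, enz)
  expect_equal(dy[1], unname(vp - vk), tolerance = 1e-12)
  expect_equal(dy[2], unname(vk - vp), tolerance = 1e-12)
  expect_equal(dy[3:8], rep(0, 6))
})

test_that("fast isomerization with alpha-like conformer kinetics reduces
           M4 to M1", {
  p4 <- phos_preset("M4")
  # make the ordered conformer kinetically identical to alpha and let it
  # relax instantly
  r <- p4$rates
  a_row <- r$id == "PP1:a>0P"
  for (pp in c("PP1", "PP2A")) {
    src <- r$id == paste0(pp, ":a>0P")
    dst <- r$id == paste0(pp, ":aprime>0P")
    r$kcat[dst] <- r$kcat[src]; r$Km[dst] <- r$Km[src]
  }
  p4$rates <- r
  p4$variant_params$k_iso_F <- 1e4
  p4$variant_params$k_iso_R <- 0
  p1 <- phos_preset("M1")
  net4 <- phos_network("M4"); net1 <- phos_network("M1")
  enz <- enzyme_levels(PKA = 5e-8, PP1 = 1e-7)
  y4 <- make_state(net4, c(abd = 1e-5, abgd = 1e-5))
  y1 <- make_state(net1, c(abd = 1e-5, abgd = 1e-5))
  tc4 <- integrate_adaptive(p4, enz, y4, 3600)
  tc1 <- integrate_adaptive(p1, enz, y1, 3600)
  b4 <- t(apply(tc4$states, 1, band_projection, network = net4))
  b1 <- t(apply(tc1$states, 1, band_projection, network = net1))
  expect_lt(max(abs(b4 - b1)), 0.01)
})
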