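# Phosphorylation-state network: form enumeration, reaction construction,
# observation operators.

test_that("form enumeration matches the state scheme and its hierarchy", {
  f8 <- enumerate_forms("M1")
  expect_length(f8, 8)
  expect_identical(f8, c("0P", "a", "ab", "abg", "d", "ad", "abd", "abgd"))
  f9 <- enumerate_forms("M4_STRUCTURAL")
  expect_length(f9, 9)
  expect_identical(setdiff(f9, f8), "aprime")
  # sequential hierarchy: beta implies alpha, gamma implies beta
  for (f in f9) {
    sites <- phoscycle:::.form_sites(f)
    if ("b" %in% sites) expect_true("a" %in% sites)
    if ("g" %in% sites) expect_true("b" %in% sites)
  }
  expect_error(enumerate_forms("M9"), "M9")
  # deterministic across calls
  expect_identical(enumerate_forms("M2"), enumerate_forms("m2_phenom"))
})

test_that("reaction lists have the derived sizes and single-site steps", {
  for (v in c("M1", "M2", "M3")) {
    rx <- build_reactions(v)
    expect_identical(nrow(rx), 28L)
    expect_identical(as.vector(table(rx$enzyme)[c("PKA", "RSK2", "PKCe",
                                                  "PP1", "PP2A")]),
                     c(6L, 2L, 4L, 8L, 8L))
  }
  rx4 <- build_reactions("M4")
  expect_identical(nrow(rx4), 34L)
  expect_identical(sum(rx4$direction == "isomerization"), 2L)
  expect_identical(sum(rx4$enzyme == "PP1"), 9L)
  # every (de)phosphorylation changes exactly one site, the named one
  enz <- rx4[rx4$direction != "isomerization", ]
  for (i in seq_len(nrow(enz))) {
    s1 <- phoscycle:::.form_sites(enz$sub[i])
    s2 <- phoscycle:::.form_sites(enz$prod[i])
    expect_identical(sort(c(setdiff(s1, s2), setdiff(s2, s1))), enz$site[i])
  }
  # determinism
  expect_identical(build_reactions("M4"), rx4)
})

test_that("PKA acts as a chain and phosphatases can reach the empty state", {
  for (v in c("M1", "M4")) {
    net <- phos_network(v)
    rx <- net$reactions
    pka <- rx[rx$enzyme == "PKA", ]
    # on each delta stratum PKA forms the chain a -> b -> g
    for (delta in c(FALSE, TRUE)) {
      chain <- pka[grepl("d", pka$sub) == delta & pka$sub != "aprime", ]
      expect_identical(chain$site, c("a", "b", "g"))
    }
    # reachability of 0P under each phosphatase alone
    for (pp in c("PP1", "PP2A")) {
      edges <- rx[rx$enzyme == pp | rx$direction == "isomerization",
                  c("sub", "prod")]
      reached <- "0P"
      repeat {
        nxt <- unique(edges$sub[edges$prod %in% reached])
        if (all(nxt %in% reached)) break
        reached <- union(reached, nxt)
      }
      expect_setequal(reached, net$forms)
    }
  }
})

test_that("band projection pools forms by phosphate count", {
  net <- phos_network("M4")
  pure <- make_state(net, c(abgd = 1e-6))
  expect_equal(unname(band_projection(pure, net)), c(0, 0, 0, 0, 1))
  mix <- make_state(net, c(abd = 1e-5, abgd = 1e-5))
  expect_equal(unname(band_projection(mix, net)), c(0, 0, 0, 0.5, 0.5))
  # the ordered conformer is a 1P species
  ap <- make_state(net, c(aprime = 2e-6, a = 2e-6))
  expect_equal(unname(band_projection(ap, net)), c(0, 1, 0, 0, 0))
  # normalization for arbitrary nonnegative inputs
  set.seed(42)
  for (k in 1:20) {
    y <- stats::runif(9, 0, 1e-5)
    expect_equal(sum(band_projection(y, net)), 1, tolerance = 1e-12)
  }
  expect_error(band_projection(numeric(9), net), "positive")
  # invariant under permutations of equal-count forms (2P block: ab <-> ad)
  y <- make_state(net, c(ab = 3e-6, ad = 1e-6, a = 5e-6))
  y2 <- make_state(net, c(ab = 1e-6, ad = 3e-6, a = 5e-6))
  expect_equal(band_projection(y, net), band_projection(y2, net))
})

test_that("site occupancy counts the ordered conformer toward alpha", {
  net <- phos_network("M4")
  full <- make_state(net, c(abgd = 1e-6))
  expect_equal(unname(site_occupancy(full, net)), c(1, 1, 1, 1))
  half <- make_state(net, c(a = 1e-6, aprime = 1e-6))
  expect_equal(unname(site_occupancy(half, net)), c(1, 0, 0, 0))
  mix <- make_state(net, c(abd = 1e-5, abgd = 1e-5))
  expect_equal(site_occupancy(mix, net),
               c(a = 1, b = 1, g = 0.5, d = 1))
})

test_that("delta lumping partitions the forms", {
  net <- phos_network("M1")
  expect_equal(unname(lump_delta(make_state(net, c(d = 1e-6)), net)),
               c(1, 0, 0, 0))
  both <- make_state(net, c(abg = 1e-6, abgd = 1e-6))
  expect_equal(unname(lump_delta(both, net)), c(0, 0, 0, 1))
  uniform <- stats::setNames(rep(1e-6, 8), net$forms)
  expect_equal(unname(lump_delta(uniform, net)), rep(0.25, 4))
  # partition property: lump of any state sums to 1
  set.seed(7)
  y <- stats::runif(8)
  expect_equal(sum(lump_delta(y, net)), 1, tolerance = 1e-12)
})
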