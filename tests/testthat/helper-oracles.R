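# Independent oracles used across test files.

# rapid-equilibrium oracle for competitive Michaelis-Menten: the free
# enzyme follows from the conservation e_T = e_free * (1 + sum_j s_j/K_j),
# and the rate of reaction i is kcat_i * e_free * s_i / K_i.
oracle_mm_rate <- function(e_total, s, K, kcat, i) {
  e_free <- e_total / (1 + sum(s / K))
  kcat[i] * e_free * s[i] / K[i]
}

# scalar Michaelis-Menten curve (single substrate, no competition)
oracle_mm_curve <- function(kcat, e, s, Km) kcat * e * s / (Km + s)

# balance root of a single-site phosphorylation cycle solved by bisection;
# x is the phosphorylated concentration, s_tot - x the unphosphorylated.
oracle_cycle_root <- function(kcat_k, K_k, e_k, kcat_p, K_p, e_p, s_tot,
                              tol = 1e-10) {
  f <- function(x) {
    u <- s_tot - x
    vk <- kcat_k * e_k * (u / K_k) / (1 + u / K_k)
    vp <- kcat_p * e_p * (x / K_p) / (1 + x / K_p)
    vk - vp
  }
  lo <- 0; hi <- s_tot
  while (hi - lo > tol * s_tot) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# named state vector with chosen forms populated
make_state <- function(net, values) {
  y <- stats::setNames(numeric(net$n_forms), net$forms)
  y[names(values)] <- values
  y
}
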