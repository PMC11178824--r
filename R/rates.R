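# Rate laws.  All concentrations mol/L, times seconds, rates mol/L/s.

#' Competitive Michaelis-Menten rate
#'
#' Rate of conversion of substrate `s_i` by an enzyme whose substrates
#' compete for the active site:
#' `v = kcat * e * s_i / (Km * (1 + kappa_E - s_i/Km) + s_i)`, where
#' `kappa_E = sum_j s_j/K_j` over all substrates of the enzyme (including
#' `s_i` itself).  Algebraically this equals
#' `kcat * e * (s_i/Km) / (1 + kappa_E)`, the rapid-equilibrium result for
#' an enzyme partitioned among its competing substrates.
#'
#' @param e free-enzyme-pool concentration (total enzyme under the
#'   substrate-excess assumption), mol/L.
#' @param s_i substrate concentration, mol/L.
#' @param kcat turnover number, 1/s.
#' @param Km Michaelis constant of this reaction, mol/L.
#' @param competing list of `c(s_j, K_j)` pairs for the *other* substrates
#'   of the same enzyme (the `s_i/Km` term is added internally).
#' @return rate in mol/L/s.
#' @export
mm_competitive_rate <- function(e, s_i, kcat, Km, competing = list()) {
  if (e < 0 || s_i < 0 || kcat < 0 || Km <= 0) {
    stop("negative concentration or non-positive Km", call. = FALSE)
  }
  kappa <- s_i / Km
  for (p in competing) {
    if (p[1] < 0 || p[2] <= 0) stop("invalid competing substrate entry")
    kappa <- kappa + p[1] / p[2]
  }
  kcat * e * s_i / (Km * (1 + kappa - s_i / Km) + s_i)
}

#' Phenomenological activation of alpha dephosphorylation
#'
#' Multiplies a base dephosphorylation rate with `1 + f_act * h`, where
#' `h = r23 / (K_act + r23)` is a hyperbolic function of the fraction of
#' substrate in bis- and tris-phosphorylated forms.  Applied only to the
#' alpha-removal step of each phosphatase in model M2.
#'
#' @param base_rate unmodified rate, mol/L/s.
#' @param f_act maximum activation factor (dimensionless, `>= 0`).
#' @param K_act half-saturation constant on the fraction scale (`> 0`).
#' @param r23 fraction of total substrate in 2P+3P forms, in `[0, 1]`.
#' @export
phenomenological_alpha_rate <- function(base_rate, f_act, K_act, r23) {
  if (r23 < 0 || r23 > 1) stop("r23 must lie in [0, 1]", call. = FALSE)
  if (f_act < 0 || K_act <= 0) stop("invalid activation parameters")
  base_rate * (1 + f_act * r23 / (K_act + r23))
}

#' Allosteric-activation rate law
#'
#' Steady-state rate for catalysis of a substrate `s_j` by an enzyme that is
#' allosterically activated by `a` while other substrates compete
#' non-allosterically, derived under the rapid-equilibrium approximation:
#' `v = (k_j e_T s_j + k_A e_T s_j a / (lambda K_A)) /
#'      (K_j + e_T a / K_A + s_j a / (lambda K_A) + K_j * sum_i(s_i/K_i) + s_j)`
#' with the sum over competing substrates excluding `s_j`.  Used for the
#' alpha-removal step of each phosphatase in model M3 with activator
#' `a = [ab] + [ad]`.
#'
#' @param e_T total enzyme concentration, mol/L.
#' @param s_j substrate concentration, mol/L.
#' @param a activator concentration, mol/L.
#' @param k_j,K_j basal turnover (1/s) and Michaelis constant (mol/L).
#' @param k_A,K_A activated turnover (1/s) and activator dissociation
#'   constant (mol/L).
#' @param lambda dimensionless scaling of the activated-complex affinity.
#' @param competing list of `c(s_i, K_i)` pairs, excluding `s_j`.
#' @export
allosteric_rate <- function(e_T, s_j, a, k_j, K_j, k_A, K_A, lambda,
                            competing = list()) {
  if (any(c(e_T, s_j, a, k_j, k_A) < 0) || K_j <= 0 || K_A <= 0 ||
      lambda <= 0) {
    stop("negative input or non-positive constant", call. = FALSE)
  }
  comp <- 0
  for (p in competing) comp <- comp + p[1] / p[2]
  num <- k_j * e_T * s_j + k_A * e_T * s_j * a / (lambda * K_A)
  den <- K_j + e_T * a / K_A + s_j * a / (lambda * K_A) +
    K_j * comp + s_j
  num / den
}

#' Total quasi-steady-state (tQSSA) rate
#'
#' Rate law for an irreversible distributive multisite system that remains
#' valid when enzyme and substrate concentrations are comparable:
#' `v = kcat e_T s_j / ((Km + e_T) * (1 + sum_i s_i/(K_i + e_T)))`,
#' sum over all substrates of the enzyme (including `s_j`).
#'
#' @inheritParams mm_competitive_rate
#' @param e_T total enzyme concentration, mol/L.
#' @param s_j substrate concentration, mol/L.
#' @param competing list of `c(s_i, K_i)` pairs for the other substrates.
#' @export
tqssa_rate <- function(e_T, s_j, kcat, Km, competing = list()) {
  if (e_T < 0 || s_j < 0 || kcat < 0 || Km <= 0) {
    stop("negative concentration or non-positive Km", call. = FALSE)
  }
  kap <- s_j / (Km + e_T)
  for (p in competing) kap <- kap + p[1] / (p[2] + e_T)
  kcat * e_T * s_j / ((Km + e_T) * (1 + kap))
}

# ---- ODE right-hand side ----------------------------------------------------

# Precompiled evaluation structure for one (network, params, enzymes,
# rate_mode) combination.  Everything index-based so the rhs closure is cheap.
phos_engine <- function(params, enzymes, rate_mode = c("mm", "tqssa")) {
  rate_mode <- match.arg(rate_mode)
  net <- phos_network(params$variant)
  rx <- params$rates
  stopifnot(nrow(rx) == nrow(net$reactions))
  n <- net$n_forms
  nr <- nrow(rx)
  sub_idx <- match(rx$sub, net$forms)
  prod_idx <- match(rx$prod, net$forms)
  is_enz <- rx$direction != "isomerization"
  enz_idx <- match(rx$enzyme, PHOS_ENZYMES)          # NA for iso rows
  e_of_rxn <- ifelse(is_enz, unclass(enzymes)[enz_idx], 0)
  # stoichiometry: forms x reactions
  S <- matrix(0, n, nr)
  S[cbind(sub_idx, seq_len(nr))] <- S[cbind(sub_idx, seq_len(nr))] - 1
  S[cbind(prod_idx, seq_len(nr))] <- S[cbind(prod_idx, seq_len(nr))] + 1
  # competition membership: enzymes x reactions (enzymatic rows only)
  Emat <- matrix(0, length(PHOS_ENZYMES), nr)
  Emat[cbind(enz_idx[is_enz], which(is_enz))] <- 1
  kcat <- rx$kcat
  Km <- rx$Km
  kcat[!is_enz] <- 0
  Km[!is_enz] <- 1        # placeholder, never used for iso rows
  enz_row <- ifelse(is.na(enz_idx), 1L, enz_idx)
  vp <- params$variant_params
  variant <- params$variant
  idx_iso_F <- which(rx$direction == "isomerization" & rx$sub == "aprime")
  idx_iso_R <- which(rx$direction == "isomerization" & rx$sub == "a")
  idx_alpha_deph <- which(rx$direction == "dephosphorylation" &
                            rx$site == "a" & rx$sub == "a")
  i_ab <- match("ab", net$forms)
  i_ad <- match("ad", net$forms)
  idx_23 <- which(net$counts %in% c(2L, 3L) & net$forms != "aprime")

  # precomputed kernels: ke = kcat * [E]; invK = 1 / (Km or Km + e_T)
  ke <- kcat * e_of_rxn
  invK <- if (rate_mode == "mm") 1 / Km else 1 / (Km + e_of_rxn)

  rates_fun <- function(y) {
    if (any(y < 0)) y[y < 0] <- 0
    s <- y[sub_idx]
    w <- s * invK
    kap <- as.numeric(Emat %*% w)
    v <- ke * w / (1 + kap[enz_row])
    if (variant == "M2") {
      tot <- sum(y)
      if (tot > 0) {
        r23 <- sum(y[idx_23]) / tot
        v[idx_alpha_deph] <- v[idx_alpha_deph] *
          (1 + vp$f_act * r23 / (vp$K_act + r23))
      }
    } else if (variant == "M3" && rate_mode == "mm") {
      act <- y[i_ab] + y[i_ad]
      for (j in idx_alpha_deph) {
        eT <- e_of_rxn[j]
        comp <- kap[enz_row[j]] - s[j] / Km[j]
        num <- kcat[j] * eT * s[j] + vp$k_A * eT * s[j] * act /
          (vp$lambda * vp$K_A)
        den <- Km[j] + eT * act / vp$K_A + s[j] * act /
          (vp$lambda * vp$K_A) + Km[j] * comp + s[j]
        v[j] <- num / den
      }
    } else if (variant == "M4") {
      if (length(idx_iso_F)) v[idx_iso_F] <- vp$k_iso_F * s[idx_iso_F]
      if (length(idx_iso_R)) v[idx_iso_R] <- vp$k_iso_R * s[idx_iso_R]
    }
    v
  }

  list(
    network = net,
    n = n,
    rates = rates_fun,
    rhs = function(t, y) as.vector(S %*% rates_fun(y)),
    desolve = function(t, y, parms) list(as.vector(S %*% rates_fun(y)))
  )
}

#' ODE right-hand side of the phosphorylation network
#'
#' Derivative of the state vector under a parameter set, enzyme levels and
#' rate mode.  Mass is conserved exactly: the derivatives sum to zero.
#'
#' @param t time (s); the system is autonomous, `t` is ignored.
#' @param state concentrations in canonical form order, mol/L.
#' @param params `phos_params`.
#' @param enzymes `phos_enzymes` from [enzyme_levels()].
#' @param rate_mode `"mm"` (substrate-excess competitive Michaelis-Menten)
#'   or `"tqssa"` (total quasi-steady-state).
#' @return derivative vector, mol/L/s.
#' @export
ode_rhs <- function(t, state, params, enzymes, rate_mode = "mm") {
  eng <- phos_engine(params, enzymes, rate_mode)
  if (length(state) != eng$n) {
    stop("state vector length ", length(state), " does not match variant ",
         params$variant, " (", eng$n, " forms)", call. = FALSE)
  }
  eng$rhs(t, state)
}
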