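# Site labels: a = alpha (pS288), b = beta (pS279), g = gamma (pS313),
# d = delta (pS308); rat numbering. "aprime" is the transiently ordered
# conformer of the mono-alpha-phosphorylated protein (structural-transition
# model only).
PHOS_SITES <- c("a", "b", "g", "d")

PHOS_ENZYMES <- c("PKA", "RSK2", "PKCe", "PP1", "PP2A")

PHOS_VARIANTS <- c("M1", "M2", "M3", "M4")

# memo cache for constructed network objects (they are immutable)
.phos_cache <- new.env(parent = emptyenv())

# Canonical form ordering: PKA chain on the delta-free stratum, then the
# delta-bearing stratum, then the ordered conformer.  This matches the
# state-vector CSV column order (c_0P, c_a, c_ab, c_abg, c_d, c_ad, c_abd,
# c_abgd[, c_aprime]) so that parameter vectors and file columns are stable.
FORMS_BASE <- c("0P", "a", "ab", "abg", "d", "ad", "abd", "abgd")
FORMS_M4 <- c(FORMS_BASE, "aprime")

.normalize_variant <- function(variant) {
  v <- toupper(as.character(variant)[1])
  v <- sub("_.*$", "", v)
  if (!v %in% PHOS_VARIANTS) {
    stop("unknown model variant: ", variant, call. = FALSE)
  }
  v
}

.form_sites <- function(form) {
  if (form == "0P") return(character(0))
  if (form == "aprime") return("a")
  strsplit(form, "")[[1]]
}

.form_count <- function(form) length(.form_sites(form))

#' Enumerate the phosphorylation forms of a model variant
#'
#' The substrate can adopt eight chemically distinct phosphorylation states:
#' the empty state, the sequential PKA ladder `a`, `ab`, `abg`
#' (alpha = pS288, beta = pS279, gamma = pS313) and the same four states
#' carrying the independently regulated delta site (pS308): `d`, `ad`,
#' `abd`, `abgd`.  Every state obeys the sequential hierarchy
#' (beta implies alpha, gamma implies beta).  The structural-transition
#' variant adds a ninth kinetic state, `aprime`, a transiently ordered
#' conformer of `a`.
#'
#' @param variant model variant: `"M1"` (plain competitive Michaelis-Menten),
#'   `"M2"` (phenomenological activation), `"M3"` (allosteric activation) or
#'   `"M4"` (structural transition); the long aliases `"M1_MM"`,
#'   `"M2_PHENOM"`, `"M3_ALLOSTERIC"`, `"M4_STRUCTURAL"` are accepted.
#' @return character vector of form identifiers in canonical order.
#' @export
enumerate_forms <- function(variant) {
  v <- .normalize_variant(variant)
  if (v == "M4") FORMS_M4 else FORMS_BASE
}

#' Build the reaction list of a model variant
#'
#' PKA phosphorylates alpha, then beta, then gamma on both delta strata;
#' RSK2 phosphorylates alpha only; PKC-epsilon adds delta to every
#' delta-free form.  Both phosphatases remove gamma from `abg`/`abgd`,
#' delta from every delta-bearing form, beta from `ab` and alpha from `a`.
#' In the structural-transition variant, removal of beta from `ab` or of
#' delta from `ad` yields the ordered conformer `aprime`, which phosphatases
#' dephosphorylate with their own (much faster) kinetics and which kinases
#' treat like `a`; first-order isomerization connects `aprime` and `a`.
#'
#' @inheritParams enumerate_forms
#' @return data frame with columns `id`, `enzyme`, `site`, `direction`,
#'   `sub`, `prod`, one row per reaction, in deterministic order.
#' @export
build_reactions <- function(variant) {
  v <- .normalize_variant(variant)
  m4 <- v == "M4"
  rx <- list()
  add <- function(enzyme, site, direction, sub, prod) {
    rx[[length(rx) + 1L]] <<- data.frame(
      id = paste0(enzyme, ":", sub, ">", prod),
      enzyme = enzyme, site = site, direction = direction,
      sub = sub, prod = prod, stringsAsFactors = FALSE
    )
  }
  # PKA: sequential alpha -> beta -> gamma on each delta stratum
  add("PKA", "a", "phosphorylation", "0P", "a")
  add("PKA", "b", "phosphorylation", "a", "ab")
  add("PKA", "g", "phosphorylation", "ab", "abg")
  add("PKA", "a", "phosphorylation", "d", "ad")
  add("PKA", "b", "phosphorylation", "ad", "abd")
  add("PKA", "g", "phosphorylation", "abd", "abgd")
  if (m4) add("PKA", "b", "phosphorylation", "aprime", "ab")
  # RSK2: alpha only
  add("RSK2", "a", "phosphorylation", "0P", "a")
  add("RSK2", "a", "phosphorylation", "d", "ad")
  # PKCe: delta on every delta-free form
  add("PKCe", "d", "phosphorylation", "0P", "d")
  add("PKCe", "d", "phosphorylation", "a", "ad")
  add("PKCe", "d", "phosphorylation", "ab", "abd")
  add("PKCe", "d", "phosphorylation", "abg", "abgd")
  if (m4) add("PKCe", "d", "phosphorylation", "aprime", "ad")
  # Phosphatases: gamma from abg/abgd, delta from every delta-bearing form,
  # beta from ab, alpha from a (and aprime in M4)
  for (pp in c("PP1", "PP2A")) {
    add(pp, "g", "dephosphorylation", "abg", "ab")
    add(pp, "g", "dephosphorylation", "abgd", "abd")
    add(pp, "d", "dephosphorylation", "d", "0P")
    add(pp, "d", "dephosphorylation", "ad", if (m4) "aprime" else "a")
    add(pp, "d", "dephosphorylation", "abd", "ab")
    add(pp, "d", "dephosphorylation", "abgd", "abg")
    add(pp, "b", "dephosphorylation", "ab", if (m4) "aprime" else "a")
    add(pp, "a", "dephosphorylation", "a", "0P")
    if (m4) add(pp, "a", "dephosphorylation", "aprime", "0P")
  }
  if (m4) {
    add("iso", "none", "isomerization", "aprime", "a")
    add("iso", "none", "isomerization", "a", "aprime")
  }
  out <- do.call(rbind, rx)
  rownames(out) <- NULL
  out
}

#' Construct a phosphorylation-network object
#'
#' @inheritParams enumerate_forms
#' @return object of class `phos_network` holding the canonical form list and
#'   the reaction table.
#' @export
phos_network <- function(variant = "M4") {
  v <- .normalize_variant(variant)
  cached <- .phos_cache[[v]]
  if (!is.null(cached)) return(cached)
  forms <- enumerate_forms(v)
  reactions <- build_reactions(v)
  counts <- vapply(forms, .form_count, integer(1))
  net <- structure(
    list(variant = v, forms = forms, n_forms = length(forms),
         counts = counts, reactions = reactions),
    class = "phos_network"
  )
  .phos_cache[[v]] <- net
  net
}

#' @export
print.phos_network <- function(x, ...) {
  cat("cMyBP-C phosphorylation network, variant ", x$variant, "\n", sep = "")
  cat("  forms (", x$n_forms, "): ", paste(x$forms, collapse = " "), "\n",
      sep = "")
  tab <- table(x$reactions$enzyme)
  cat("  reactions (", nrow(x$reactions), "): ",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

.check_state <- function(state, network) {
  if (length(state) != network$n_forms) {
    stop("state vector has length ", length(state), ", expected ",
         network$n_forms, call. = FALSE)
  }
  total <- sum(pmax(state, 0))
  if (!is.finite(total) || total <= 0) {
    stop("total substrate concentration must be positive", call. = FALSE)
  }
  # tolerate solver-scale negative drift, reject genuinely negative input
  if (any(state < -1e-9 * total)) {
    stop("negative concentrations in state vector", call. = FALSE)
  }
  total
}

#' Project a state vector onto 0P-4P band fractions
#'
#' Mimics the PhosTag gel measurement operator: each band collects every
#' form carrying the same number of phosphate groups; the ordered conformer
#' counts as 1P (it is chemically mono-phosphorylated).
#'
#' @param state nonnegative concentrations in canonical form order (mol/L).
#' @param network a [phos_network()].
#' @return named numeric vector `c(f0, f1, f2, f3, f4)` summing to 1.
#' @export
band_projection <- function(state, network) {
  total <- .check_state(state, network)
  state <- pmax(state, 0)
  out <- numeric(5)
  for (k in 0:4) out[k + 1L] <- sum(state[network$counts == k])
  names(out) <- paste0("f", 0:4)
  out / total
}

#' Per-site occupancy fractions
#'
#' Fraction of total substrate phosphorylated at each of the four sites
#' (the antibody view of the system).  The ordered conformer counts toward
#' alpha occupancy.
#'
#' @inheritParams band_projection
#' @return named numeric vector over sites `a`, `b`, `g`, `d`.
#' @export
site_occupancy <- function(state, network) {
  total <- .check_state(state, network)
  state <- pmax(state, 0)
  occ <- vapply(PHOS_SITES, function(s) {
    has <- vapply(network$forms, function(f) s %in% .form_sites(f),
                  logical(1))
    sum(state[has])
  }, numeric(1))
  occ / total
}

#' Delta-lumped fractions
#'
#' Collapses the network onto four groups that differ only by delta
#' phosphorylation: `0P+d`, `a+ad` (including the ordered conformer),
#' `ab+abd`, `abg+abgd`.
#'
#' @inheritParams band_projection
#' @return named numeric vector of four fractions summing to 1.
#' @export
lump_delta <- function(state, network) {
  total <- .check_state(state, network)
  state <- pmax(state, 0)
  groups <- list(`0P+d` = c("0P", "d"),
                 `a+ad` = c("a", "ad", "aprime"),
                 `ab+abd` = c("ab", "abd"),
                 `abg+abgd` = c("abg", "abgd"))
  out <- vapply(groups, function(g) {
    sum(state[network$forms %in% g])
  }, numeric(1))
  out / total
}
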