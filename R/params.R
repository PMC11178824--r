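# Parameter containers: per-reaction kcat/Km plus variant-specific constants.
# Units are mol/L and seconds throughout.

#' Construct a kinetic parameter set
#'
#' @param network a [phos_network()].
#' @param kcat,Km numeric vectors aligned with the enzymatic rows of
#'   `network$reactions` (isomerization rows take `NA`).
#' @param variant_params named list of variant-specific constants:
#'   `f_act`, `K_act` (M2); `k_A`, `K_A`, `lambda` (M3);
#'   `k_iso_F`, `k_iso_R` (M4).
#' @return object of class `phos_params`.
#' @export
phos_params <- function(network, kcat, Km, variant_params = list()) {
  rx <- network$reactions
  enz <- rx$direction != "isomerization"
  if (length(kcat) != nrow(rx) || length(Km) != nrow(rx)) {
    stop("kcat/Km must have one entry per reaction", call. = FALSE)
  }
  if (any(kcat[enz] < 0, na.rm = TRUE)) stop("kcat must be >= 0")
  if (any(Km[enz] <= 0, na.rm = TRUE)) stop("Km must be > 0")
  rates <- data.frame(rx, kcat = kcat, Km = Km, stringsAsFactors = FALSE)
  structure(
    list(variant = network$variant, rates = rates,
         variant_params = variant_params),
    class = "phos_params"
  )
}

#' @export
print.phos_params <- function(x, ...) {
  cat("phos_params (variant ", x$variant, "), ",
      sum(x$rates$direction != "isomerization"), " enzymatic reactions\n",
      sep = "")
  if (length(x$variant_params)) {
    cat("  variant constants: ",
        paste(names(x$variant_params),
              signif(unlist(x$variant_params), 4),
              sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Enzyme concentration vector
#'
#' @param PKA,RSK2,PKCe,PP1,PP2A concentrations in mol/L (all `>= 0`).
#' @return named numeric vector of class `phos_enzymes`.
#' @export
enzyme_levels <- function(PKA = 0, RSK2 = 0, PKCe = 0, PP1 = 0, PP2A = 0) {
  x <- c(PKA = PKA, RSK2 = RSK2, PKCe = PKCe, PP1 = PP1, PP2A = PP2A)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("enzyme concentrations must be finite and >= 0", call. = FALSE)
  }
  structure(x, class = "phos_enzymes")
}

# Default per-(enzyme, site) kinetics of the ground-truth preset, chosen to
# encode the qualitative constraints of the biochemistry:
#  - sequential PKA specificity (alpha > beta > gamma);
#  - alpha dephosphorylation has ~4x the Km of delta and a lower kcat for
#    both phosphatases (pS288 is a poor phosphatase substrate);
#  - for PP1 the specificity ratio of the ab<->abg cycle exceeds that of the
#    abd<->abgd cycle (gamma removal is faster on the delta-bearing
#    substrate), while for PP2A the two are equal;
#  - the ordered conformer is a much better phosphatase substrate than
#    alpha (>= 20x specificity constant);
#  - PP1 removes delta far faster than PP2A does, so fixing the whole
#    phosphatase pool to PP1 abolishes delta-bearing states while a free
#    PP1/PP2A split leaves them attainable;
#  - kinase specificity constants sit roughly an order of magnitude above
#    the phosphatase ones, so nanomolar kinase levels can balance micromolar
#    phosphatase pools (as the physiological enzyme-concentration boxes
#    assume), while the phosphatase constants keep the 0.1 umol/L in vitro
#    dephosphorylation on its tens-of-minutes timescale;
#  - the beta- and gamma-cycle balance points lie close enough together that
#    the lumped 3P+4P PKA response is switch-like (Hill coefficient near 2),
#    with a steeper response for PP1 than for PP2A (beta removal by PP1 is
#    somewhat faster), and substrate sits near the kinase Km so the
#    steepness is sequential rather than zero-order.
.preset_scheme <- function() {
  list(
    PKA  = list(a = c(80, 2e-5), b = c(40, 2e-5), g = c(40, 2e-5)),
    RSK2 = list(a = c(2.0, 1e-5)),
    PKCe = list(d = c(40, 2e-5)),
    PP1  = list(g_free = c(1.5, 1e-5), g_delta = c(3.0, 1e-5),
                d = c(24, 5e-6), b = c(1.2, 1.5e-5),
                a = c(0.15, 2e-5), aprime = c(2.0, 1e-5)),
    PP2A = list(g_free = c(1.5, 1e-5), g_delta = c(1.5, 1e-5),
                d = c(1.2, 2e-5), b = c(0.8, 1.5e-5),
                a = c(0.12, 8e-5), aprime = c(2.0, 1e-5))
  )
}

.scheme_key <- function(enzyme, site, sub) {
  if (enzyme %in% c("PP1", "PP2A")) {
    if (site == "a" && sub == "aprime") return("aprime")
    if (site == "g") {
      return(if (grepl("d", sub)) "g_delta" else "g_free")
    }
  }
  site
}

#' Ground-truth parameter preset
#'
#' Returns the package's reference parameter set for a model variant.  The
#' numeric values are package defaults chosen inside the qualitative
#' constraints of the measured biochemistry (see the vignette); they are the
#' ground truth that the synthetic-data generator simulates from, so every
#' calibration test can be scored against a known answer.
#'
#' @inheritParams enumerate_forms
#' @return `phos_params` object.
#' @export
phos_preset <- function(variant = "M4") {
  net <- phos_network(variant)
  rx <- net$reactions
  sch <- .preset_scheme()
  kcat <- Km <- rep(NA_real_, nrow(rx))
  for (i in seq_len(nrow(rx))) {
    if (rx$direction[i] == "isomerization") next
    enzyme <- rx$enzyme[i]
    # kinases act on the ordered conformer with the same kinetics as on `a`
    key <- .scheme_key(enzyme, rx$site[i], rx$sub[i])
    p <- sch[[enzyme]][[key]]
    kcat[i] <- p[1]
    Km[i] <- p[2]
  }
  vp <- switch(net$variant,
    M1 = list(),
    M2 = list(f_act = 10, K_act = 0.05),
    M3 = list(k_A = 1.0, K_A = 2e-6, lambda = 0.1),
    M4 = list(k_iso_F = 5e-3, k_iso_R = 1e-5)
  )
  phos_params(net, kcat, Km, vp)
}

#' Default enzyme levels of the preset experiments
#'
#' The in vitro reference conditions: 20 umol/L substrate, 0.1 umol/L
#' phosphatase for dephosphorylation time courses.
#' @export
preset_enzymes <- function() enzyme_levels()

#' Specificity constant kcat/Km of a reaction
#'
#' @param params `phos_params`.
#' @param reaction_id reaction identifier (e.g. `"PP1:abg>ab"`).
#' @return kcat/Km in 1/(mol/L)/s.
#' @export
specificity_constant <- function(params, reaction_id) {
  i <- match(reaction_id, params$rates$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id, call. = FALSE)
  params$rates$kcat[i] / params$rates$Km[i]
}

# ---- flat-file round trip ---------------------------------------------------

#' Write a parameter set to a flat key=value text file
#' @param params `phos_params`.
#' @param path output file path.
#' @export
write_phos_params <- function(params, path) {
  lines <- c(paste0("variant=", params$variant))
  r <- params$rates
  for (i in seq_len(nrow(r))) {
    if (r$direction[i] == "isomerization") next
    lines <- c(lines,
               sprintf("%s|kcat=%.17g", r$id[i], r$kcat[i]),
               sprintf("%s|Km=%.17g", r$id[i], r$Km[i]))
  }
  for (nm in names(params$variant_params)) {
    lines <- c(lines, sprintf("%s=%.17g", nm, params$variant_params[[nm]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set written by [write_phos_params()]
#' @param path file path.
#' @return `phos_params` object.
#' @export
read_phos_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  variant <- vals[keys == "variant"]
  net <- phos_network(variant)
  rx <- net$reactions
  kcat <- Km <- rep(NA_real_, nrow(rx))
  vp <- list()
  for (j in seq_along(keys)) {
    if (keys[j] == "variant") next
    if (grepl("|", keys[j], fixed = TRUE)) {
      parts <- strsplit(keys[j], "|", fixed = TRUE)[[1]]
      i <- match(parts[1], rx$id)
      if (is.na(i)) stop("unknown reaction in parameter file: ", parts[1])
      if (parts[2] == "kcat") kcat[i] <- as.numeric(vals[j])
      else Km[i] <- as.numeric(vals[j])
    } else {
      vp[[keys[j]]] <- as.numeric(vals[j])
    }
  }
  phos_params(net, kcat, Km, vp)
}
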