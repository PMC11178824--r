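# Inference of enzyme concentrations from steady-state phospho-
# distributions, heart-failure predictions and maximally achievable
# fractions (MAFs) under constrained enzyme boxes.  The phosphatase pool is
# parameterized as (total, PP1 share): PP2A is total minus PP1, so the
# PP1/PP2A split can vary freely or be clamped.

#' Enzyme concentration box
#'
#' @param PKA,PKCe,RSK2 `c(lo, hi)` bounds, mol/L.
#' @param PPtot `c(lo, hi)` bounds (or equal lo = hi to fix) for the total
#'   phosphatase concentration.
#' @param pp1_share `c(lo, hi)` bounds on the PP1 fraction of the
#'   phosphatase total (`c(1, 1)` clamps all phosphatase to PP1,
#'   `c(0, 0)` to PP2A).
#' @return object of class `phos_box`.
#' @export
enzyme_box <- function(PKA = c(5e-10, 5e-7), PKCe = c(0, 2e-7),
                       RSK2 = c(0, 2e-7), PPtot = c(1e-10, 1e-6),
                       pp1_share = c(0, 1)) {
  box <- list(PKA = PKA, PKCe = PKCe, RSK2 = RSK2, PPtot = PPtot,
              pp1_share = pp1_share)
  for (nm in names(box)) {
    b <- box[[nm]]
    if (length(b) != 2 || b[1] > b[2] || b[1] < 0) {
      stop("invalid bounds for ", nm, call. = FALSE)
    }
  }
  structure(box, class = "phos_box")
}

#' Named condition presets for enzyme-level inference
#'
#' Encodes the physiologically constrained enzyme ranges used for fitting
#' tissue phospho-distributions and for MAF optimization:
#' `donor_fit` (PKA 5e-10..5e-7, PKCe/RSK2 0..2e-7, phosphatases
#' 1e-10..1e-6 with free PP1/PP2A split); `hf_fit` (same, but total
#' phosphatase fixed to twice the donor-fit total); `donor_maf`
#' (PKA 0..1.36e-6, total phosphatase fixed at 1e-6); `hf_maf`
#' (PKA 0..2.89e-7, total fixed at 2e-6); `hf_maf_restricted`
#' (additionally PKCe/RSK2 0..1.5e-7); `hf_maf_pp1_clamped` /
#' `hf_maf_pp2a_clamped` (restricted, with the whole pool forced to PP1 or
#' PP2A).
#'
#' @param name preset name.
#' @param donor_pp_total donor-fit total phosphatase (mol/L) used to derive
#'   the heart-failure total (default 1e-6).
#' @return `phos_box`.
#' @export
condition_preset <- function(name = c("donor_fit", "hf_fit", "donor_maf",
                                      "hf_maf", "hf_maf_restricted",
                                      "hf_maf_pp1_clamped",
                                      "hf_maf_pp2a_clamped"),
                             donor_pp_total = 1e-6) {
  name <- match.arg(name)
  hf_total <- 2 * donor_pp_total
  switch(name,
    donor_fit = enzyme_box(),
    hf_fit = enzyme_box(PPtot = c(hf_total, hf_total)),
    donor_maf = enzyme_box(PKA = c(0, 1.36e-6),
                           PPtot = c(donor_pp_total, donor_pp_total)),
    hf_maf = enzyme_box(PKA = c(0, 2.89e-7),
                        PPtot = c(hf_total, hf_total)),
    hf_maf_restricted = enzyme_box(PKA = c(0, 2.89e-7),
                                   PKCe = c(0, 1.5e-7),
                                   RSK2 = c(0, 1.5e-7),
                                   PPtot = c(hf_total, hf_total)),
    hf_maf_pp1_clamped = enzyme_box(PKA = c(0, 2.89e-7),
                                    PKCe = c(0, 1.5e-7),
                                    RSK2 = c(0, 1.5e-7),
                                    PPtot = c(hf_total, hf_total),
                                    pp1_share = c(1, 1)),
    hf_maf_pp2a_clamped = enzyme_box(PKA = c(0, 2.89e-7),
                                     PKCe = c(0, 1.5e-7),
                                     RSK2 = c(0, 1.5e-7),
                                     PPtot = c(hf_total, hf_total),
                                     pp1_share = c(0, 0))
  )
}

# search-space encoding: log10 for concentrations (zero lower bounds are
# floored at 1e-12 mol/L, far below any kinetic effect), linear for the
# PP1 share.
.box_encode <- function(box) {
  floor_c <- 1e-12
  dims <- list()
  for (nm in c("PKA", "PKCe", "RSK2", "PPtot")) {
    b <- box[[nm]]
    if (b[2] > b[1]) {
      dims[[nm]] <- list(kind = "log", lower = log10(max(b[1], floor_c)),
                         upper = log10(b[2]))
    }
  }
  b <- box$pp1_share
  if (b[2] > b[1]) {
    dims[["pp1_share"]] <- list(kind = "lin", lower = b[1], upper = b[2])
  }
  dims
}

.box_decode <- function(box, dims, theta) {
  val <- list(PKA = box$PKA[1], PKCe = box$PKCe[1], RSK2 = box$RSK2[1],
              PPtot = box$PPtot[1], pp1_share = box$pp1_share[1])
  for (i in seq_along(dims)) {
    nm <- names(dims)[i]
    val[[nm]] <- if (dims[[i]]$kind == "log") 10^theta[i] else theta[i]
  }
  pp1 <- val$pp1_share * val$PPtot
  enzyme_levels(PKA = val$PKA, RSK2 = val$RSK2, PKCe = val$PKCe,
                PP1 = pp1, PP2A = val$PPtot - pp1)
}

.box_search <- function(box, objective_of_levels, n_starts, seed,
                        hj_max_iter = 50, hj_tol = 1e-5, hj_rho = 0.2,
                        hj_max_evals = 300) {
  dims <- .box_encode(box)
  lower <- vapply(dims, `[[`, numeric(1), "lower")
  upper <- vapply(dims, `[[`, numeric(1), "upper")
  fn <- function(theta) objective_of_levels(.box_decode(box, dims, theta))
  if (!length(dims)) {
    lv <- .box_decode(box, dims, numeric(0))
    return(list(levels = lv, value = objective_of_levels(lv)))
  }
  starts <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      stats::runif(length(dims), lower, upper)
    })
  })
  best <- NULL
  for (x0 in starts) {
    res <- hooke_jeeves(fn, x0, lower, upper, max_iter = hj_max_iter,
                        tol = hj_tol, rho = hj_rho,
                        max_evals = hj_max_evals)
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(levels = .box_decode(box, dims, best$par), value = best$value)
}

#' Fit enzyme concentrations to a steady-state phospho-distribution
#'
#' For every kinetic parameter set, Hooke-Jeeves search (iteration limit
#' 50, tolerance 1e-5, rho 0.2; multi-start) minimizes the sum of squared
#' differences between the simulated steady-state 0P-4P distribution and
#' the target, over the enzyme concentrations allowed by the box.
#'
#' @param target numeric 5-vector of 0P-4P fractions (sums to 1).
#' @param object kinetic parameter sets (`phos_params`, ensemble, fit or
#'   list).
#' @param box `phos_box` (e.g. [condition_preset()]).
#' @param substrate_molar total substrate (default 20e-6).
#' @param rate_mode `"mm"` or `"tqssa"`.
#' @param n_starts multi-starts per parameter set (default 4).
#' @param seed integer seed for the start draws.
#' @param sse_flag fits with SSE above this are flagged (default 0.02).
#' @return data frame, one row per parameter set: fitted enzyme levels,
#'   `pp_total`, `sse`, `flagged`.
#' @export
fit_enzyme_levels <- function(target, object, box = condition_preset(),
                              substrate_molar = 20e-6, rate_mode = "mm",
                              n_starts = 4, seed = 1, sse_flag = 0.02) {
  stopifnot(length(target) == 5, abs(sum(target) - 1) < 1e-6)
  sets <- .as_params_list(object)
  net <- phos_network(sets[[1]]$variant)
  y0 <- .initial_state(net, c(`0P` = 1), substrate_molar)
  rows <- lapply(seq_along(sets), function(i) {
    obj <- function(levels) {
      ss <- steady_state(sets[[i]], levels, y0, rate_mode = rate_mode)
      sum((band_projection(ss$state, net) - target)^2)
    }
    res <- .box_search(box, obj, n_starts, seed + i)
    lv <- unclass(res$levels)
    data.frame(set = i, PKA = lv["PKA"], RSK2 = lv["RSK2"],
               PKCe = lv["PKCe"], PP1 = lv["PP1"], PP2A = lv["PP2A"],
               pp_total = lv["PP1"] + lv["PP2A"], sse = res$value,
               flagged = res$value > sse_flag, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Heart-failure enzyme perturbation
#'
#' Applies the literature heart-failure remodeling to a donor enzyme
#' vector: PKA halved, PP1 and PP2A doubled, other enzymes unchanged --
#' together a fourfold decrease in the PKA/phosphatase ratio.
#'
#' @param donor_levels `phos_enzymes`.
#' @return perturbed `phos_enzymes`.
#' @export
predict_hf <- function(donor_levels) {
  x <- unname(unclass(donor_levels))
  enzyme_levels(PKA = x[1] * 0.5, RSK2 = x[2], PKCe = x[3],
                PP1 = x[4] * 2, PP2A = x[5] * 2)
}

#' PKA to total-phosphatase concentration ratio
#' @param levels `phos_enzymes`.
#' @export
pka_ppase_ratio <- function(levels) {
  x <- unclass(levels)
  pp <- x["PP1"] + x["PP2A"]
  if (pp <= 0) stop("total phosphatase concentration is zero",
                    call. = FALSE)
  unname(x["PKA"] / pp)
}

#' Maximally achievable fraction (MAF) of a phosphorylation state
#'
#' For every kinetic parameter set, multi-start Hooke-Jeeves maximizes the
#' steady-state fraction of the named form (or delta-lumped group) over the
#' enzyme box of a condition preset.
#'
#' @param target form name (e.g. `"abgd"`) or delta-lumped group name
#'   (e.g. `"abg+abgd"`).
#' @param object kinetic parameter sets.
#' @param box `phos_box` (e.g. [condition_preset()]).
#' @param substrate_molar total substrate (default 20e-6).
#' @param rate_mode `"mm"` or `"tqssa"`.
#' @param n_starts multi-starts per parameter set (default 8).
#' @param seed integer seed.
#' @param hj_max_iter Hooke-Jeeves iteration limit (default 50).
#' @param hj_max_evals objective-evaluation cap per start (default 300).
#' @return data frame, one row per parameter set: `maf` and the argmax
#'   enzyme vector.
#' @export
maximize_state <- function(target, object,
                           box = condition_preset("donor_maf"),
                           substrate_molar = 20e-6, rate_mode = "mm",
                           n_starts = 8, seed = 1, hj_max_iter = 50,
                           hj_max_evals = 300) {
  sets <- .as_params_list(object)
  net <- phos_network(sets[[1]]$variant)
  y0 <- .initial_state(net, c(`0P` = 1), substrate_molar)
  lump_names <- names(lump_delta(y0 + 1e-30, net))
  if (target %in% net$forms) {
    value_of <- function(s) {
      s <- pmax(s, 0)
      if (target == "a" && "aprime" %in% net$forms) {
        # the ordered conformer is the same chemical species as `a`
        (s[match("a", net$forms)] + s[match("aprime", net$forms)]) / sum(s)
      } else s[match(target, net$forms)] / sum(s)
    }
  } else if (target %in% lump_names) {
    value_of <- function(s) lump_delta(s, net)[[target]]
  } else stop("unknown target state or group: ", target, call. = FALSE)
  rows <- lapply(seq_along(sets), function(i) {
    obj <- function(levels) {
      ss <- steady_state(sets[[i]], levels, y0, rate_mode = rate_mode)
      -value_of(ss$state)
    }
    res <- .box_search(box, obj, n_starts, seed + i,
                       hj_max_iter = hj_max_iter,
                       hj_max_evals = hj_max_evals)
    lv <- unclass(res$levels)
    data.frame(set = i, maf = -res$value, PKA = lv["PKA"],
               RSK2 = lv["RSK2"], PKCe = lv["PKCe"], PP1 = lv["PP1"],
               PP2A = lv["PP2A"], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Run an inference function under the tQSSA rate mode
#'
#' Convenience wrapper substituting the total quasi-steady-state rate law
#' (valid when substrate and enzyme concentrations are comparable) into any
#' inference routine that accepts `rate_mode` and `substrate_molar`.
#'
#' @param fun inference function (e.g. [fit_enzyme_levels()],
#'   [maximize_state()]).
#' @param ... arguments passed through to `fun`.
#' @param substrate_molar lowered substrate total (default 1e-6).
#' @export
run_with_tqssa <- function(fun, ..., substrate_molar = 1e-6) {
  fun(..., substrate_molar = substrate_molar, rate_mode = "tqssa")
}
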