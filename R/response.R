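# Steady-state dose-response analysis over parameter ensembles:
# Hill-equation quantification, delta-lumped views, specificity ratios and
# the PP1<->PP2A parameter-swap control.

.as_params_list <- function(object) {
  if (inherits(object, "phos_params")) return(list(object))
  if (inherits(object, "phos_ensemble")) {
    return(lapply(seq_len(nrow(object$theta)),
                  function(i) ensemble_params(object, i)))
  }
  if (inherits(object, "phos_fit")) return(.as_params_list(object$ensemble))
  if (is.list(object) && all(vapply(object, inherits, TRUE, "phos_params"))) {
    return(object)
  }
  stop("expected phos_params, phos_ensemble, phos_fit or a list of ",
       "parameter sets", call. = FALSE)
}

#' Steady-state dose-response over a parameter ensemble
#'
#' Titrates one enzyme over a log-spaced grid at fixed background levels,
#' computes the steady state for every parameter set and grid point, and
#' projects onto bands, delta-lumped groups, or raw state fractions.
#'
#' @param object `phos_params`, `phos_ensemble`, `phos_fit` or list of
#'   parameter sets.
#' @param titrated enzyme being titrated (default `"PKA"`).
#' @param grid concentrations, mol/L (log-spaced).
#' @param background `phos_enzymes` of fixed enzyme levels.
#' @param lumping `"bands"`, `"delta_lumped"` or `"state"`.
#' @param substrate_molar total substrate (default 20e-6).
#' @param rate_mode `"mm"` or `"tqssa"`.
#' @return object of class `phos_doseresponse`: `values` array
#'   (set x point x group), `mean`/`sd` matrices over converged sets,
#'   `converged` flags.
#' @export
dose_response <- function(object, titrated = "PKA", grid,
                          background = enzyme_levels(PP1 = 1e-7),
                          lumping = c("bands", "delta_lumped", "state"),
                          substrate_molar = 20e-6, rate_mode = "mm") {
  lumping <- match.arg(lumping)
  sets <- .as_params_list(object)
  net <- phos_network(sets[[1]]$variant)
  y0 <- .initial_state(net, c(`0P` = 1), substrate_molar)
  proj <- switch(lumping,
                 bands = function(s) band_projection(s, net),
                 delta_lumped = function(s) lump_delta(s, net),
                 state = function(s) stats::setNames(s / sum(s), net$forms))
  groups <- names(proj(y0 + 1e-30))
  values <- array(NA_real_, c(length(sets), length(grid), length(groups)),
                  dimnames = list(NULL, NULL, groups))
  converged <- matrix(TRUE, length(sets), length(grid))
  base <- as.list(unclass(background))
  for (i in seq_along(sets)) {
    for (j in seq_along(grid)) {
      base[[titrated]] <- grid[j]
      ss <- steady_state(sets[[i]], do.call(enzyme_levels, base), y0,
                         rate_mode = rate_mode)
      values[i, j, ] <- proj(ss$state)
      converged[i, j] <- ss$converged
    }
  }
  vals_ok <- values
  vals_ok[!converged] <- NA          # recycles over the group dimension
  structure(list(titrated = titrated, grid = grid,
                 background = background, lumping = lumping,
                 values = values, converged = converged,
                 mean = apply(vals_ok, c(2, 3), mean, na.rm = TRUE),
                 sd = apply(vals_ok, c(2, 3), stats::sd, na.rm = TRUE)),
            class = "phos_doseresponse")
}

#' @export
print.phos_doseresponse <- function(x, ...) {
  cat("phos_doseresponse: ", x$titrated, " over ",
      signif(min(x$grid), 2), " - ", signif(max(x$grid), 2), " mol/L (",
      length(x$grid), " points, ", dim(x$values)[1], " sets, ",
      x$lumping, ")\n", sep = "")
  invisible(x)
}

#' Tabulate a dose-response as a data frame
#' @param x `phos_doseresponse`.
#' @param ... unused.
#' @export
as.data.frame.phos_doseresponse <- function(x, ...) {
  groups <- dimnames(x$values)[[3]]
  do.call(rbind, lapply(seq_along(groups), function(g) {
    data.frame(conc_molar = x$grid, group = groups[g],
               mean_fraction = x$mean[, g], sd_fraction = x$sd[, g],
               n_sets = colSums(x$converged))
  }))
}

#' Fit the Hill equation to a dose-response curve
#'
#' Least squares of `y = y_min + (y_max - y_min) x^n / (EC50^n + x^n)` with
#' free baseline and plateau (simulated plateaus fall short of 1), using a
#' deterministic multi-start over Hill exponents 0.5, 1, 2 and 4.
#'
#' @param concentrations dose grid, mol/L (`> 0`).
#' @param responses response fractions.
#' @return object of class `phos_hill` with `n_H`, `EC50`, `y_min`,
#'   `y_max`, `residual` and a `flagged` indicator for poor (non-sigmoidal)
#'   fits.
#' @export
hill_fit <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses),
            length(concentrations) >= 6, all(concentrations > 0))
  if (max(responses) - min(responses) < 1e-6) {
    stop("response is constant; Hill fit undefined", call. = FALSE)
  }
  df <- data.frame(x = concentrations, y = responses)
  half <- (max(responses) + min(responses)) / 2
  ec0 <- concentrations[which.min(abs(responses - half))]
  best <- NULL
  for (n0 in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ ymin + (ymax - ymin) * x^n / (ec^n + x^n),
                        data = df,
                        start = list(ymin = max(min(responses), 0),
                                     ymax = min(max(responses), 1),
                                     n = n0, ec = ec0),
                        lower = c(0, 0, 0.05,
                                  min(concentrations) / 100),
                        upper = c(1, 1, 20, max(concentrations) * 100),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Hill fit failed", call. = FALSE)
  co <- as.list(stats::coef(best$fit))
  amplitude <- max(responses) - min(responses)
  structure(list(n_H = co$n, EC50 = co$ec, y_min = co$ymin,
                 y_max = co$ymax, residual = best$rss,
                 flagged = best$rss > 0.05 * amplitude^2 *
                   length(responses)),
            class = "phos_hill")
}

#' @export
print.phos_hill <- function(x, ...) {
  cat("Hill fit: n_H = ", signif(x$n_H, 3), ", EC50 = ",
      signif(x$EC50, 3), " mol/L, plateau ", signif(x$y_max, 3),
      if (x$flagged) "  [flagged: poor fit]", "\n", sep = "")
  invisible(x)
}

#' Hill fits of one lumped group across an ensemble dose-response
#'
#' @param dr `phos_doseresponse`.
#' @param group group name (e.g. `"abg+abgd"` for a delta-lumped response).
#' @return list of `phos_hill`, one per parameter set.
#' @export
hill_fit_ensemble <- function(dr, group) {
  stopifnot(group %in% dimnames(dr$values)[[3]])
  lapply(seq_len(dim(dr$values)[1]), function(i) {
    hill_fit(dr$grid, dr$values[i, , group])
  })
}

#' Specificity ratio of a phosphorylation-dephosphorylation cycle
#'
#' `(kcat/Km)_kinase / (kcat/Km)_phosphatase` for the forward and backward
#' reactions of one cycle: a measure of how much the cycle is biased toward
#' phosphorylation at equal enzyme concentrations.
#'
#' @param params `phos_params`.
#' @param kinase_reaction,phosphatase_reaction reaction ids, e.g.
#'   `"PKA:ab>abg"` and `"PP1:abg>ab"`.
#' @return dimensionless ratio.
#' @export
specificity_ratio <- function(params, kinase_reaction,
                              phosphatase_reaction) {
  specificity_constant(params, kinase_reaction) /
    specificity_constant(params, phosphatase_reaction)
}

#' Exchange cycle parameters between the two phosphatases
#'
#' Swaps the kcat/Km of the named substrate-to-product conversions between
#' PP1 and PP2A (default: the two reactions consuming the fully
#' phosphorylated form, `abgd>abd` and `abgd>abg`).  Applying the swap
#' twice restores the original parameter set.
#'
#' @param params `phos_params`.
#' @param reactions substrate>product conversion labels to exchange.
#' @return modified `phos_params`.
#' @export
swap_cycle_parameters <- function(params,
                                  reactions = c("abgd>abd", "abgd>abg")) {
  r <- params$rates
  for (conv in reactions) {
    i1 <- match(paste0("PP1:", conv), r$id)
    i2 <- match(paste0("PP2A:", conv), r$id)
    if (is.na(i1) || is.na(i2)) {
      stop("reaction not found for both phosphatases: ", conv,
           call. = FALSE)
    }
    for (field in c("kcat", "Km")) {
      tmp <- r[[field]][i1]
      r[[field]][i1] <- r[[field]][i2]
      r[[field]][i2] <- tmp
    }
  }
  params$rates <- r
  params
}

#' Switch metrics of a sigmoidal lumped response
#'
#' The midpoint is the concentration where the response reaches half its
#' fitted plateau; the function also evaluates the response at twice the
#' midpoint and the transition width in decades between 10% and 90% of
#' plateau.  Responses with no half-plateau crossing are flagged.
#'
#' @param concentrations dose grid, mol/L.
#' @param responses response fractions (one curve).
#' @return list with `midpoint`, `value_at_2x`, `width_decades`,
#'   `plateau`, `flagged`.
#' @export
switch_metrics <- function(concentrations, responses) {
  hf <- tryCatch(hill_fit(concentrations, responses),
                 error = function(e) NULL)
  if (is.null(hf)) {
    return(list(midpoint = NA, value_at_2x = NA, width_decades = NA,
                plateau = NA, flagged = TRUE))
  }
  plateau <- hf$y_max
  lx <- log10(concentrations)
  fi <- stats::approxfun(lx, responses)
  crossing <- function(level) {
    s <- responses - level
    i <- which(s[-1] * s[-length(s)] <= 0 & s[-1] != s[-length(s)])
    if (!length(i)) return(NA_real_)
    i <- i[1]
    stats::uniroot(function(z) fi(z) - level,
                   c(lx[i], lx[i + 1]))$root
  }
  mid <- crossing(plateau / 2)
  if (is.na(mid)) {
    return(list(midpoint = NA, value_at_2x = NA, width_decades = NA,
                plateau = plateau, flagged = TRUE))
  }
  l10 <- crossing(0.1 * plateau)
  l90 <- crossing(0.9 * plateau)
  v2 <- if (mid + log10(2) <= max(lx)) fi(mid + log10(2)) else NA_real_
  list(midpoint = 10^mid, value_at_2x = v2,
       width_decades = if (is.na(l10) || is.na(l90)) NA else l90 - l10,
       plateau = plateau, flagged = FALSE)
}
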