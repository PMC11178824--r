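# The central model-fitting interface: phos_fit() calibrates a model
# variant against a set of experiments and returns a classed object with
# the usual modelling methods.

#' Fit a phosphorylation-network model to experimental datasets
#'
#' Ensemble calibration of a model variant: `n_runs` independent
#' genetic-algorithm searches over the freed kinetic constants, each
#' refined by Hooke-Jeeves pattern search, against the weighted
#' sum-of-squares objective of [objective_wsse()].  Multiple independent
#' parameter sets are retained (rather than a single optimum) because many
#' individual constants are not uniquely identifiable; ensemble predictions
#' carry that uncertainty.
#'
#' @param datasets a `phos_dataset` or list of them.
#' @param variant model variant (`"M1"`..`"M4"`).
#' @param free enzymes whose kinetic constants are searched
#'   (default `c("PP1", "PP2A")`); variant constants are freed whenever the
#'   variant has any.
#' @param groups optionally, specific tie groups to free; see
#'   [phos_parmap()].
#' @param base `phos_params` supplying fixed values for constants not
#'   searched (default [phos_preset()] of the variant).
#' @param weights per-dataset objective weights.
#' @param n_runs ensemble size (default 10).
#' @param seed base seed.
#' @param ga_generations,ga_population,hj_max_iter,hj_tol,hj_rho,hj_max_evals
#'   search settings, see [ensemble_calibrate()].
#' @param rtol integration tolerance during fitting.
#' @param bounds bound overrides, see [phos_parmap()].
#' @return object of class `phos_fit`.
#' @seealso [summary.phos_fit()], [coef.phos_fit()], [predict.phos_fit()],
#'   [residuals.phos_fit()], [plot.phos_fit()]
#' @export
phos_fit <- function(datasets, variant = "M4", free = c("PP1", "PP2A"),
                     groups = NULL, base = phos_preset(variant),
                     weights = 1, n_runs = 10, seed = 1,
                     ga_generations = 250, ga_population = 25,
                     hj_max_iter = 50, hj_tol = 1e-5, hj_rho = 0.2,
                     hj_max_evals = 2000, rtol = 1e-6, bounds = list()) {
  if (inherits(datasets, "phos_dataset")) datasets <- list(datasets)
  stopifnot(base$variant == .normalize_variant(variant))
  parmap <- phos_parmap(base, enzymes = free, groups = groups,
                        bounds = bounds)
  objective <- phos_objective(datasets, weights)
  ens <- ensemble_calibrate(objective, parmap, n_runs = n_runs, seed = seed,
                            ga_generations = ga_generations,
                            ga_population = ga_population,
                            hj_max_iter = hj_max_iter, hj_tol = hj_tol,
                            hj_rho = hj_rho, hj_max_evals = hj_max_evals,
                            rtol = rtol)
  structure(list(ensemble = ens, objective = objective,
                 variant = .normalize_variant(variant), free = free,
                 call = match.call()),
            class = "phos_fit")
}

#' Number of residuals entering a fit's objective
#' @param fit `phos_fit`.
#' @keywords internal
.n_residuals <- function(fit) {
  sum(vapply(fit$objective$datasets, function(ds) {
    length(.observable_cols(ds)) * nrow(ds$summary)
  }, numeric(1)))
}

#' @export
print.phos_fit <- function(x, ...) {
  cat("Phosphorylation-network model fit (variant ", x$variant, ")\n",
      sep = "")
  cat("  datasets: ", length(x$objective$datasets),
      "; free constants: ", length(x$ensemble$parmap$names),
      " (", paste(x$free, collapse = ", "),
      if (length(x$ensemble$parmap$base$variant_params))
        " + variant constants", ")\n", sep = "")
  cat("  ensemble: ", nrow(x$ensemble$theta), " sets, objective ",
      signif(min(x$ensemble$objective), 4), " (best) to ",
      signif(max(x$ensemble$objective), 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.phos_fit <- function(object, i = 1, log10 = FALSE, ...) {
  th <- object$ensemble$theta[i, ]
  if (log10) th else 10^th
}

#' Summary of an ensemble fit
#'
#' Reports per-parameter ensemble medians and coefficients of variation on
#' the linear scale, plus the specificity constants (kcat/Km) of every
#' freed reaction group, whose ensemble variability is typically much lower
#' than that of kcat or Km individually.
#'
#' @param object `phos_fit`.
#' @param ... unused.
#' @export
summary.phos_fit <- function(object, ...) {
  ens <- object$ensemble
  vals <- 10^ens$theta
  cv <- function(x) stats::sd(x) / mean(x)
  par_tab <- data.frame(
    parameter = colnames(ens$theta),
    median = apply(vals, 2, stats::median),
    cv = apply(vals, 2, cv)
  )
  # specificity constants per tied kcat/Km pair
  nm <- colnames(ens$theta)
  kcat_cols <- grep("\\.kcat$", nm)
  spec_tab <- NULL
  if (length(kcat_cols)) {
    groups <- sub("\\.kcat$", "", nm[kcat_cols])
    spec <- sapply(groups, function(g) {
      vals[, paste0(g, ".kcat")] / vals[, paste0(g, ".Km")]
    })
    spec_tab <- data.frame(
      group = groups,
      median_spec = apply(spec, 2, stats::median),
      cv_spec = apply(spec, 2, cv)
    )
  }
  out <- list(variant = object$variant, n_sets = nrow(ens$theta),
              objective = ens$objective, parameters = par_tab,
              specificity = spec_tab, flagged = ens$flagged)
  class(out) <- "summary.phos_fit"
  out
}

#' @export
print.summary.phos_fit <- function(x, ...) {
  cat("Ensemble fit summary (variant ", x$variant, "): ", x$n_sets,
      " sets\n", sep = "")
  cat("  objective: best ", signif(min(x$objective), 4), ", median ",
      signif(stats::median(x$objective), 4), "\n", sep = "")
  cat("\nParameters (ensemble median, CV):\n")
  print(transform(x$parameters, median = signif(median, 3),
                  cv = signif(cv, 2)), row.names = FALSE)
  if (!is.null(x$specificity)) {
    cat("\nSpecificity constants kcat/Km (ensemble median, CV):\n")
    print(transform(x$specificity, median_spec = signif(median_spec, 3),
                    cv_spec = signif(cv_spec, 2)), row.names = FALSE)
  }
  invisible(x)
}

#' Steady-state predictions from a fitted model
#'
#' Computes the steady-state phospho-distribution under given enzyme levels
#' for every ensemble member.
#'
#' @param object `phos_fit`.
#' @param enzymes `phos_enzymes`.
#' @param substrate_molar total substrate (default 20e-6).
#' @param type `"bands"`, `"lumped"` or `"state"`.
#' @param rate_mode `"mm"` or `"tqssa"`.
#' @param ... unused.
#' @return matrix, one row per ensemble member.
#' @export
predict.phos_fit <- function(object, enzymes,
                             substrate_molar = 20e-6,
                             type = c("bands", "lumped", "state"),
                             rate_mode = "mm", ...) {
  type <- match.arg(type)
  net <- phos_network(object$variant)
  y0 <- .initial_state(net, c(`0P` = 1), substrate_molar)
  t(vapply(seq_len(nrow(object$ensemble$theta)), function(i) {
    ss <- steady_state(ensemble_params(object$ensemble, i), enzymes, y0,
                       rate_mode = rate_mode)
    switch(type,
           bands = band_projection(ss$state, net),
           lumped = lump_delta(ss$state, net),
           state = ss$state / sum(ss$state))
  }, numeric(switch(type, bands = 5, lumped = 4, state = net$n_forms))))
}

#' Weighted residuals of a fitted model
#'
#' @param object `phos_fit`.
#' @param i ensemble member (default best).
#' @param ... unused.
#' @return list of matrices of `(obs - sim)/sd`, one per dataset.
#' @export
residuals.phos_fit <- function(object, i = 1, ...) {
  params <- ensemble_params(object$ensemble, i)
  lapply(object$objective$datasets, function(ds) {
    cols <- .observable_cols(ds)
    sim <- .simulate_dataset(params, ds)
    obs <- as.matrix(ds$summary[cols])
    sdm <- as.matrix(ds$summary[paste0("sd_", cols)])
    (obs - sim[, seq_along(cols), drop = FALSE]) / sdm
  })
}

#' Simulate model trajectories from a fitted model
#'
#' Re-simulates every fitted experiment with one ensemble member's
#' parameters, returning noiseless predicted observables aligned with each
#' dataset's summary table.
#'
#' @param object `phos_fit`.
#' @param nsim number of ensemble members to use, starting from the best.
#' @param seed unused (simulations are deterministic); kept for the generic.
#' @param ... unused.
#' @return list (one element per member) of lists of prediction matrices.
#' @export
simulate.phos_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lapply(seq_len(nsim), function(i) {
    params <- ensemble_params(object$ensemble, i)
    lapply(object$objective$datasets, .simulate_dataset, params = params)
  })
}

#' Plot data and ensemble fits for one dataset
#'
#' Base-graphics overlay of the observed summary points (with SD bars) and
#' the per-member model curves.
#'
#' @param x `phos_fit`.
#' @param which dataset index (default 1).
#' @param members ensemble members to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.phos_fit <- function(x, which = 1, members = NULL, ...) {
  ds <- x$objective$datasets[[which]]
  cols <- .observable_cols(ds)
  key <- switch(ds$type,
                bands_timecourse = , occupancy_timecourse = "time_s",
                dose_response = "conc_molar",
                initial_rate = "substrate_molar",
                distribution = NULL)
  if (is.null(key)) stop("no plot method for distribution datasets")
  xv <- ds$summary[[key]]
  obs <- as.matrix(ds$summary[cols])
  graphics::matplot(xv, obs, pch = 19, col = seq_along(cols),
                    xlab = key, ylab = "fraction",
                    log = if (key == "conc_molar") "x" else "", ...)
  if (is.null(members)) members <- seq_len(nrow(x$ensemble$theta))
  for (i in members) {
    sim <- .simulate_dataset(ensemble_params(x$ensemble, i), ds)
    graphics::matlines(xv, sim[, seq_along(cols)], lty = 1,
                       col = grDevices::adjustcolor(seq_along(cols), 0.4))
  }
  graphics::legend("topright", legend = cols, col = seq_along(cols),
                   pch = 19, bty = "n")
  invisible(x)
}

#' Pin mono-site kinetic constants from initial-rate data
#'
#' Fits the Michaelis-Menten equation to an initial-rate dataset and writes
#' the resulting kcat (`Vmax` divided by the assay enzyme concentration)
#' and Km into the matching site-context group of a parameter set.  This is
#' the first stage of the reference calibration: mono-site constants are
#' determined directly, the remaining constants by ensemble search.
#'
#' @param base `phos_params` to update.
#' @param ir `phos_dataset` of type `"initial_rate"` for a
#'   mono-phosphorylated substrate.
#' @return updated `phos_params`.
#' @export
pin_monosite_params <- function(base, ir) {
  stopifnot(ir$type == "initial_rate")
  enzyme <- ir$meta$enzyme
  form <- ir$meta$phospho_form
  e_conc <- ir$meta$enzymes[[enzyme]]
  mm <- fit_mm_initial_rates(ir)
  r <- base$rates
  rows_E <- which(r$enzyme == enzyme)
  keys <- vapply(rows_E, function(i) .scheme_key(enzyme, r$site[i],
                                                 r$sub[i]), "")
  # for a mono form the removed site is its single occupied site
  target_key <- .scheme_key(enzyme, .form_sites(form)[1], form)
  rows <- rows_E[keys == target_key]
  if (!length(rows)) stop("no reactions match the assay substrate",
                          call. = FALSE)
  r$kcat[rows] <- mm$Vmax / e_conc
  r$Km[rows] <- mm$Km
  base$rates <- r
  base
}

#' Reference phosphatase calibration
#'
#' The package's standard two-stage calibration of one phosphatase's
#' kinetics against the reference experiment suite
#' ([gen_calibration_suite()]): mono-site constants (`a`, `d`) are pinned
#' by Michaelis-Menten fits to the initial-rate assays, then the remaining
#' constants (gamma removal on both delta strata, beta removal, and -- for
#' the structural-transition variant -- the ordered-conformer kinetics and
#' isomerization rates) are calibrated by ensemble search against the
#' dephosphorylation time courses.
#'
#' @param truth ground-truth `phos_params` used to generate the data.
#' @param variant variant to fit (defaults to the truth's variant; fitting
#'   a reduced variant to richer data is the model-selection use case).
#' @param phosphatase `"PP1"` or `"PP2A"`.
#' @param noise [noise_model()] for the synthetic data.
#' @param seed integer seed (data generation and searches).
#' @param n_runs,ga_generations,ga_population,hj_max_evals,rtol search
#'   scale, see [ensemble_calibrate()].
#' @return `phos_fit` (the generated suite is attached as
#'   `attr(, "suite")`).
#' @export
calibrate_phosphatase <- function(truth = phos_preset("M4"),
                                  variant = truth$variant,
                                  phosphatase = "PP1",
                                  noise = noise_model(), seed = 1,
                                  n_runs = 10, ga_generations = 50,
                                  ga_population = 25, hj_max_evals = 2500,
                                  rtol = 1e-5) {
  variant <- .normalize_variant(variant)
  suite <- gen_calibration_suite(truth, phosphatase, noise, seed)
  base <- phos_preset(variant)
  base <- pin_monosite_params(base, suite$ir_a)
  base <- pin_monosite_params(base, suite$ir_d)
  groups <- paste0(phosphatase, ".", c("g_free", "g_delta", "b"))
  if (variant == "M4") {
    groups <- c(groups, paste0(phosphatase, ".aprime"))
  }
  fit <- phos_fit(list(suite$dephos_34$bands, suite$dephos_ab$bands,
                       suite$dephos_abg$bands),
                  variant = variant, free = phosphatase, groups = groups,
                  base = base, n_runs = n_runs, seed = seed,
                  ga_generations = ga_generations,
                  ga_population = ga_population,
                  hj_max_evals = hj_max_evals, rtol = rtol)
  attr(fit, "suite") <- suite
  fit
}
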