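# Parameter estimation: free-parameter mapping, weighted-SSE objective,
# genetic-algorithm global search, Hooke-Jeeves local refinement, ensemble
# generation and artifact filtering.  All rate constants are searched on the
# log10 scale because they span orders of magnitude.

.default_bounds <- list(
  kcat = c(1e-3, 1e3), Km = c(1e-7, 1e-3),
  k_iso_F = c(1e-6, 1), k_iso_R = c(1e-8, 1),
  f_act = c(1e-2, 1e2), K_act = c(1e-3, 1),
  k_A = c(1e-3, 1e3), K_A = c(1e-8, 1e-4), lambda = c(1e-2, 1e1)
)

#' Free-parameter mapping for calibration
#'
#' Defines which kinetic constants are searched.  Reactions of one enzyme
#' that share a site context (e.g. delta removal from every delta-bearing
#' form) are tied to a single kcat and Km, mirroring the site-specific
#' parameterization of the model; variant constants (isomerization rates
#' etc.) are appended.  Everything not freed keeps its value from `base`.
#'
#' @param base `phos_params` supplying the network, the fixed values and the
#'   variant.
#' @param enzymes character vector of enzymes whose constants are freed
#'   (subset of `r PHOS_ENZYMES`).
#' @param groups optionally, specific `"ENZYME.key"` tie groups to free
#'   (e.g. `c("PP1.b", "PP1.aprime")`); the default frees every group of
#'   the named enzymes.  Constants whose groups are not freed keep their
#'   `base` values (e.g. mono-site constants pinned beforehand by
#'   initial-rate fits).
#' @param variant_free free the variant-specific constants too (default
#'   `TRUE` when the variant has any).
#' @param bounds named list overriding the default search bounds
#'   (linear scale, `c(lo, hi)` per field).
#' @return object of class `phos_parmap`.
#' @export
phos_parmap <- function(base, enzymes = c("PP1", "PP2A"), groups = NULL,
                        variant_free = TRUE, bounds = list()) {
  stopifnot(inherits(base, "phos_params"))
  bnd <- utils::modifyList(.default_bounds, bounds)
  rx <- base$rates
  entries <- list()
  for (E in enzymes) {
    rows_E <- which(rx$enzyme == E)
    if (!length(rows_E)) stop("enzyme ", E, " not in network", call. = FALSE)
    keys <- vapply(rows_E, function(i) .scheme_key(E, rx$site[i], rx$sub[i]),
                   "")
    for (key in unique(keys)) {
      if (!is.null(groups) && !paste(E, key, sep = ".") %in% groups) next
      rows <- rows_E[keys == key]
      for (field in c("kcat", "Km")) {
        entries[[paste(E, key, field, sep = ".")]] <-
          list(kind = "rate", rows = rows, field = field,
               bounds = bnd[[field]])
      }
    }
  }
  if (variant_free) {
    for (nm in names(base$variant_params)) {
      entries[[nm]] <- list(kind = "vp", name = nm,
                            bounds = bnd[[nm]] %||% c(1e-6, 1e3))
    }
  }
  lower <- log10(vapply(entries, function(e) e$bounds[1], numeric(1)))
  upper <- log10(vapply(entries, function(e) e$bounds[2], numeric(1)))
  structure(list(base = base, entries = entries,
                 names = names(entries), lower = lower, upper = upper),
            class = "phos_parmap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize a parameter set from a log10 search vector
#'
#' @param parmap `phos_parmap`.
#' @param theta numeric vector of log10 parameter values, aligned with
#'   `parmap$names`.
#' @return `phos_params`.
#' @export
parmap_apply <- function(parmap, theta) {
  stopifnot(length(theta) == length(parmap$entries))
  params <- parmap$base
  val <- 10^theta
  for (i in seq_along(parmap$entries)) {
    e <- parmap$entries[[i]]
    if (e$kind == "rate") {
      params$rates[[e$field]][e$rows] <- val[i]
    } else {
      params$variant_params[[e$name]] <- val[i]
    }
  }
  params
}

#' Log10 vector of the base (ground-truth) values of a mapping
#' @inheritParams parmap_apply
#' @export
parmap_truth <- function(parmap) {
  vapply(parmap$entries, function(e) {
    v <- if (e$kind == "rate") parmap$base$rates[[e$field]][e$rows[1]]
         else parmap$base$variant_params[[e$name]]
    log10(v)
  }, numeric(1))
}

# ---- objective --------------------------------------------------------------

# map a stored initial state onto the form set of the fitting variant
# (e.g. data generated under the 9-state variant fitted with an 8-state
# one); forms absent from the target variant must carry zero concentration.
.meta_y0 <- function(meta, net) {
  y0 <- stats::setNames(numeric(net$n_forms), net$forms)
  src <- meta$y0
  common <- intersect(names(src), net$forms)
  y0[common] <- src[common]
  dropped <- setdiff(names(src), net$forms)
  if (any(src[dropped] > 0)) {
    stop("initial state populates forms absent from variant ",
         net$variant, call. = FALSE)
  }
  y0
}

# Predicted summary-aligned observables for one dataset under `params`.
# Returns a matrix with one column per observable column of ds$summary.
.simulate_dataset <- function(params, ds, rtol = 1e-6) {
  net <- phos_network(params$variant)
  meta <- ds$meta
  rate_mode <- meta$rate_mode %||% "mm"
  enz <- do.call(enzyme_levels, as.list(meta$enzymes %||% meta$enzymes_base))
  if (ds$type %in% c("bands_timecourse", "occupancy_timecourse")) {
    times <- meta$times
    tc <- integrate_adaptive(params, enz, .meta_y0(meta, net), max(times),
                             times = sort(unique(c(0, times))),
                             rtol = rtol, rate_mode = rate_mode)
    keep <- match(times, tc$times)
    proj <- if (ds$type == "bands_timecourse") band_projection
            else site_occupancy
    t(apply(tc$states[keep, , drop = FALSE], 1, proj, network = net))
  } else if (ds$type == "initial_rate") {
    grid <- meta$substrate_grid
    i_form <- match(meta$phospho_form, net$forms)
    cbind(rate = vapply(grid, function(s) {
      if (s == 0) return(0)
      y0 <- stats::setNames(numeric(net$n_forms), net$forms)
      y0[i_form] <- s
      tc <- integrate_adaptive(params, enz, y0, meta$quench_s,
                               times = c(0, meta$quench_s), rtol = rtol,
                               rate_mode = rate_mode)
      (s - tc$states[2, i_form]) / meta$quench_s
    }, numeric(1)))
  } else if (ds$type == "dose_response") {
    base <- as.list(meta$enzymes_base)
    t(vapply(meta$grid, function(conc) {
      base[[meta$titrated]] <- conc
      ss <- steady_state(params, do.call(enzyme_levels, base),
                         .meta_y0(meta, net),
                         rate_mode = rate_mode)
      band_projection(ss$state, net)
    }, numeric(5)))
  } else if (ds$type == "distribution") {
    ss <- steady_state(params, enz, .meta_y0(meta, net),
                       rate_mode = rate_mode)
    matrix(band_projection(ss$state, net), 1)
  } else stop("unknown dataset type: ", ds$type)
}

.observable_cols <- function(ds) {
  switch(ds$type,
    bands_timecourse = .fraction_cols,
    occupancy_timecourse = paste0("occ_", PHOS_SITES),
    initial_rate = "rate",
    dose_response = .fraction_cols,
    distribution = .fraction_cols)
}

#' Objective specification
#'
#' Bundles datasets with per-experiment weights.  Weights default to 1;
#' per-point custom weights may be supplied as a `weight` column in a
#' dataset's summary table (they multiply the 1/sd^2 weights).
#'
#' @param datasets list of `phos_dataset` objects.
#' @param weights numeric vector, one per dataset (recycled).
#' @return object of class `phos_objective`.
#' @export
phos_objective <- function(datasets, weights = 1) {
  if (inherits(datasets, "phos_dataset")) datasets <- list(datasets)
  weights <- rep_len(weights, length(datasets))
  structure(list(datasets = datasets, weights = weights),
            class = "phos_objective")
}

#' Weighted sum-of-squares objective
#'
#' For each experiment `e`, `SSE_e = sum(((y_obs - y_sim)/sd)^2)`; the
#' objective is `sum_e w_e * SSE_e / N_e` with `N_e` the number of residuals
#' in the experiment (the per-experiment normalization).  Simulation
#' failures return a large finite penalty (1e12) rather than an error, so
#' stochastic searches remain total functions.
#'
#' @param theta log10 parameter vector.
#' @param objective `phos_objective`.
#' @param parmap `phos_parmap`.
#' @param rtol integration tolerance used during fitting.
#' @return scalar objective value (`>= 0`).
#' @export
objective_wsse <- function(theta, objective, parmap, rtol = 1e-6) {
  params <- parmap_apply(parmap, theta)
  total <- 0
  for (k in seq_along(objective$datasets)) {
    ds <- objective$datasets[[k]]
    sim <- tryCatch(.simulate_dataset(params, ds, rtol = rtol),
                    error = function(e) NULL)
    if (is.null(sim) || any(!is.finite(sim))) return(1e12)
    cols <- .observable_cols(ds)
    obs <- as.matrix(ds$summary[cols])
    sdm <- as.matrix(ds$summary[paste0("sd_", cols)])
    w <- if ("weight" %in% names(ds$summary)) ds$summary$weight else 1
    r2 <- ((obs - sim[, seq_along(cols), drop = FALSE]) / sdm)^2 * w
    total <- total + objective$weights[k] * sum(r2) / length(r2)
  }
  total
}

# builds the closure handed to the searches
.make_objective_fn <- function(objective, parmap, rtol = 1e-6) {
  function(theta) objective_wsse(theta, objective, parmap, rtol)
}

# ---- searches ---------------------------------------------------------------

#' Genetic-algorithm global search
#'
#' Real-coded GA on the (log10) box: tournament selection (k = 2), uniform
#' crossover (per-gene probability 0.5), per-gene Gaussian mutation
#' (SD 0.1 decade, probability 0.2), elitism 1.  The best-so-far objective
#' is non-increasing over generations.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper finite bounds.
#' @param population population size (default 25).
#' @param generations number of generations (default 250).
#' @param seed integer seed.
#' @return list with `par`, `value`, `history` (best per generation).
#' @export
genetic_search <- function(fn, lower, upper, population = 25,
                           generations = 250, seed = 1) {
  n <- length(lower)
  stopifnot(length(upper) == n, all(upper >= lower))
  .with_seed(seed, {
    pop <- matrix(stats::runif(population * n, rep(lower, each = population),
                               rep(upper, each = population)),
                  population, n)
    fit <- apply(pop, 1, fn)
    history <- numeric(generations)
    for (g in seq_len(generations)) {
      ord <- order(fit)
      newpop <- matrix(NA_real_, population, n)
      newpop[1, ] <- pop[ord[1], ]          # elitism
      for (i in 2:population) {
        pick <- function() {
          c2 <- sample.int(population, 2)
          c2[which.min(fit[c2])]
        }
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        child <- ifelse(stats::runif(n) < 0.5, p1, p2)
        mut <- stats::runif(n) < 0.2
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, 0.1)
        newpop[i, ] <- pmin(pmax(child, lower), upper)
      }
      pop <- newpop
      fit <- c(fit[ord[1]], apply(pop[-1, , drop = FALSE], 1, fn))
      history[g] <- min(fit)
    }
    best <- which.min(fit)
    list(par = pop[best, ], value = fit[best], history = cummin(history))
  })
}

#' Hooke-Jeeves pattern search
#'
#' Classical exploratory/pattern search on the (log10) box.  The step is
#' contracted by `rho` after a failed poll; iteration stops when the step
#' falls below `tol` or after `max_iter` iterations.  The returned objective
#' never exceeds the starting value.
#'
#' @inheritParams genetic_search
#' @param x0 start vector (within bounds).
#' @param max_iter iteration limit (default 50).
#' @param tol step-size tolerance (default 1e-5).
#' @param rho step contraction factor (default 0.2).
#' @param step0 initial step in decades (default 0.2).
#' @param max_evals cap on objective evaluations (default 2000); the
#'   search stops at the cap with its best point so far.
#' @return list with `par`, `value`, `iterations`, `evals`.
#' @export
hooke_jeeves <- function(fn, x0, lower, upper, max_iter = 50, tol = 1e-5,
                         rho = 0.2, step0 = 0.2, max_evals = 2000) {
  clip <- function(x) pmin(pmax(x, lower), upper)
  evals <- 0L
  fcount <- function(x) { evals <<- evals + 1L; fn(x) }
  budget_left <- function() evals < max_evals
  explore <- function(x, fx, step) {
    for (i in seq_along(x)) {
      if (!budget_left()) break
      for (dir in c(1, -1)) {
        cand <- x
        cand[i] <- cand[i] + dir * step
        cand <- clip(cand)
        fc <- fcount(cand)
        if (fc < fx) { x <- cand; fx <- fc; break }
        if (!budget_left()) break
      }
    }
    list(x = x, f = fx)
  }
  x <- clip(x0)
  fx <- fcount(x)
  step <- step0
  iter <- 0
  while (iter < max_iter && step >= tol && budget_left()) {
    iter <- iter + 1
    ex <- explore(x, fx, step)
    if (ex$f < fx) {
      # pattern move along the successful direction
      while (budget_left()) {
        xp <- clip(ex$x + (ex$x - x))
        fp <- fcount(xp)
        ep <- explore(xp, fp, step)
        if (ep$f < ex$f) { x <- ex$x; ex <- ep } else break
      }
      x <- ex$x
      fx <- ex$f
    } else {
      step <- step * rho
    }
  }
  list(par = x, value = fx, iterations = iter, evals = evals)
}

# ---- ensemble ---------------------------------------------------------------

#' Ensemble calibration: repeated global + local search
#'
#' Runs `n_runs` independent genetic-algorithm searches, each refined by
#' Hooke-Jeeves, with recorded seeds.  Individual run failures are recorded
#' and skipped, not fatal.
#'
#' @param objective `phos_objective`.
#' @param parmap `phos_parmap`.
#' @param n_runs number of independent runs (`>= 2`).
#' @param seed base seed; run `i` uses `seed + i - 1`.
#' @param ga_generations,ga_population GA settings (defaults 250 / 25).
#' @param hj_max_iter,hj_tol,hj_rho Hooke-Jeeves settings (50, 1e-5, 0.2).
#' @param rtol integration tolerance during fitting.
#' @return object of class `phos_ensemble`: log10 parameter matrix (one row
#'   per run, sorted by objective), objective values, seeds, filter flags.
#' @export
ensemble_calibrate <- function(objective, parmap, n_runs = 10, seed = 1,
                               ga_generations = 250, ga_population = 25,
                               hj_max_iter = 50, hj_tol = 1e-5,
                               hj_rho = 0.2, hj_max_evals = 2000,
                               rtol = 1e-6) {
  stopifnot(n_runs >= 2)
  fn <- .make_objective_fn(objective, parmap, rtol)
  seeds <- seed + seq_len(n_runs) - 1L
  theta <- matrix(NA_real_, n_runs, length(parmap$names),
                  dimnames = list(NULL, parmap$names))
  value <- rep(NA_real_, n_runs)
  failed <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    res <- tryCatch({
      ga <- genetic_search(fn, parmap$lower, parmap$upper,
                           population = ga_population,
                           generations = ga_generations, seed = seeds[i])
      hj <- hooke_jeeves(fn, ga$par, parmap$lower, parmap$upper,
                         max_iter = hj_max_iter, tol = hj_tol,
                         rho = hj_rho, max_evals = hj_max_evals)
      if (hj$value <= ga$value) hj else ga
    }, error = function(e) NULL)
    if (is.null(res)) failed[i] <- TRUE
    else { theta[i, ] <- res$par; value[i] <- res$value }
  }
  ok <- !failed
  ord <- order(value[ok])
  structure(list(parmap = parmap,
                 theta = theta[ok, , drop = FALSE][ord, , drop = FALSE],
                 objective = value[ok][ord], seeds = seeds[ok][ord],
                 failed_seeds = seeds[failed],
                 flagged = rep(FALSE, sum(ok)),
                 settings = list(ga_generations = ga_generations,
                                 ga_population = ga_population,
                                 hj_max_iter = hj_max_iter,
                                 hj_tol = hj_tol, hj_rho = hj_rho)),
            class = "phos_ensemble")
}

#' @export
print.phos_ensemble <- function(x, ...) {
  cat("phos_ensemble: ", nrow(x$theta), " parameter sets (",
      sum(x$flagged), " flagged), objective ",
      signif(min(x$objective), 4), " - ", signif(max(x$objective), 4),
      "\n", sep = "")
  invisible(x)
}

#' Parameter set of one ensemble member
#' @param ensemble `phos_ensemble`.
#' @param i member index (rows are sorted by objective; default best).
#' @export
ensemble_params <- function(ensemble, i = 1) {
  parmap_apply(ensemble$parmap, ensemble$theta[i, ])
}

#' Flag ensemble members with fitting artifacts
#'
#' For every experiment, the observed summary curve is interpolated with an
#' Akima spline on a dense grid (piecewise-linear fallback below 5 points,
#' recorded), each member's simulation is evaluated on that grid, and the
#' SSE against the interpolant is computed.  A member is flagged when its
#' SSE exceeds `mean + cutoff_sd * SD` (across members) for any experiment;
#' with zero SD across members nothing is flagged.  Flags are annotations;
#' no member is deleted.
#'
#' @param ensemble `phos_ensemble`.
#' @param datasets list of `phos_dataset` (time-course or dose-response).
#' @param cutoff_sd cutoff in SD units (default 0.5).
#' @param n_dense dense-grid size (default 101).
#' @return the ensemble with updated `flagged` and an `filter_sse` matrix.
#' @export
filter_ensemble <- function(ensemble, datasets, cutoff_sd = 0.5,
                            n_dense = 101) {
  if (inherits(datasets, "phos_dataset")) datasets <- list(datasets)
  n_set <- nrow(ensemble$theta)
  sse <- matrix(NA_real_, n_set, length(datasets))
  interp_info <- character(length(datasets))
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    cols <- .observable_cols(ds)
    key <- switch(ds$type,
                  bands_timecourse = , occupancy_timecourse = "time_s",
                  dose_response = "conc_molar",
                  stop("filter_ensemble supports time-course and ",
                       "dose-response datasets"))
    xobs <- ds$summary[[key]]
    xd <- seq(min(xobs), max(xobs), length.out = n_dense)
    use_akima <- length(xobs) >= 5
    interp_info[k] <- if (use_akima) "akima" else "linear"
    yobs <- sapply(cols, function(cc) {
      ylin <- stats::approx(xobs, ds$summary[[cc]], xd)$y
      if (!use_akima) return(ylin)
      yak <- suppressWarnings(pracma::akimaInterp(xobs, ds$summary[[cc]],
                                                  xd))
      # the Akima scheme is undefined near the grid ends; patch those
      # segments with the linear interpolant
      bad <- !is.finite(yak)
      yak[bad] <- ylin[bad]
      yak
    })
    meta_dense <- ds$meta
    if (key == "time_s") meta_dense$times <- xd else meta_dense$grid <- xd
    ds_dense <- ds
    ds_dense$meta <- meta_dense
    for (i in seq_len(n_set)) {
      sim <- tryCatch(
        .simulate_dataset(ensemble_params(ensemble, i), ds_dense),
        error = function(e) NULL)
      sse[i, k] <- if (is.null(sim)) Inf
                   else sum((yobs - sim[, seq_along(cols)])^2)
    }
  }
  flags <- rep(FALSE, n_set)
  for (k in seq_along(datasets)) {
    bad <- !is.finite(sse[, k])
    flags <- flags | bad
    ok <- sse[is.finite(sse[, k]), k]
    m <- mean(ok)
    s <- stats::sd(ok)
    if (!is.finite(s) || s == 0) next
    flags <- flags | (is.finite(sse[, k]) & sse[, k] > m + cutoff_sd * s)
  }
  ensemble$flagged <- flags
  ensemble$filter_sse <- sse
  ensemble$filter_interp <- interp_info
  ensemble
}

# ---- Michaelis-Menten initial-rate fit --------------------------------------

#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Nonlinear least squares of `v = Vmax * s / (Km + s)` with a deterministic
#' multi-start over five log-spaced Km starting values; the best fit is
#' returned with standard errors.  Fewer than four distinct substrate
#' concentrations, or a grid that does not span the fitted Km, produce an
#' identifiability warning flag.
#'
#' @param x `phos_dataset` of type `"initial_rate"`, or a data frame with
#'   columns `substrate_molar` and `rate`.
#' @return list with `Vmax`, `Km`, `se_Vmax`, `se_Km`, `flags`.
#' @export
fit_mm_initial_rates <- function(x) {
  df <- if (inherits(x, "phos_dataset")) x$data else x
  df <- df[df$substrate_molar > 0 | df$rate != 0, , drop = FALSE]
  if (all(df$rate <= 0)) stop("no positive rates to fit", call. = FALSE)
  flags <- character(0)
  if (length(unique(df$substrate_molar)) < 4) {
    flags <- c(flags, "fewer than 4 distinct substrate concentrations")
    warning("fewer than 4 distinct substrate concentrations",
            call. = FALSE)
  }
  s_rng <- range(df$substrate_molar[df$substrate_molar > 0])
  km_starts <- 10^seq(log10(s_rng[1]), log10(s_rng[2]), length.out = 5)
  best <- NULL
  for (km0 in km_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(rate ~ Vmax * substrate_molar /
                          (Km + substrate_molar),
                        data = df,
                        start = list(Vmax = max(df$rate), Km = km0),
                        lower = c(0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Michaelis-Menten fit failed", call. = FALSE)
  co <- summary(best$fit)$coefficients
  Km <- co["Km", "Estimate"]
  if (Km > s_rng[2] || Km < s_rng[1] ||
      co["Km", "Std. Error"] > Km) {
    flags <- c(flags, "Km poorly constrained by the substrate grid")
  }
  list(Vmax = co["Vmax", "Estimate"], Km = Km,
       se_Vmax = co["Vmax", "Std. Error"], se_Km = co["Km", "Std. Error"],
       flags = flags, fit = best$fit)
}
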