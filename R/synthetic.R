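# Synthetic-data generation from a known ground truth.  The generator
# emulates the in vitro experimental designs: PhosTag band-fraction time
# courses, antibody site-occupancy readouts, initial-rate assays, 60-min
# steady-state dose-responses and steady-state phospho-distributions, with
# replicate Gaussian noise applied on the fraction scale (additive,
# truncated to [0,1], renormalized per time point), because PhosTag
# quantification divides band signal by lane total.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Noise model for synthetic fractions
#'
#' @param sd_fraction absolute SD on the fraction scale (default 0.03).
#' @param n_replicates number of replicates (default 3).
#' @export
noise_model <- function(sd_fraction = 0.03, n_replicates = 3) {
  stopifnot(sd_fraction >= 0, n_replicates >= 1)
  list(sd_fraction = sd_fraction, n_replicates = n_replicates)
}

# add truncated, renormalized Gaussian noise to a matrix of fractions
# (rows = points); returns one replicate
.noisy_fractions <- function(frac, sd) {
  if (sd == 0) return(frac)
  noisy <- frac + matrix(stats::rnorm(length(frac), 0, sd),
                         nrow(frac), ncol(frac))
  noisy <- pmin(pmax(noisy, 0), 1)
  sweep(noisy, 1, pmax(rowSums(noisy), .Machine$double.eps), "/")
}

.summarize_reps <- function(reps, key_col, value_cols, sd_floor = 0.01) {
  keys <- unique(reps[[key_col]])
  out <- data.frame(key = keys)
  names(out) <- key_col
  for (cc in value_cols) {
    m <- tapply(reps[[cc]], reps[[key_col]], mean)[as.character(keys)]
    s <- tapply(reps[[cc]], reps[[key_col]], stats::sd)[as.character(keys)]
    s[is.na(s)] <- 0
    out[[cc]] <- as.numeric(m)
    out[[paste0("sd_", cc)]] <- pmax(as.numeric(s), sd_floor)
  }
  out
}

.initial_state <- function(network, composition, total) {
  y0 <- stats::setNames(numeric(network$n_forms), network$forms)
  bad <- setdiff(names(composition), network$forms)
  if (length(bad)) stop("unknown forms in initial composition: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  y0[names(composition)] <- composition / sum(composition) * total
  y0
}

#' Synthetic dephosphorylation time course
#'
#' Emulates the reference experiment: a 50/50 mixture of `abd` and `abgd`
#' (3P/4P) at 20 umol/L is dephosphorylated by 0.1 umol/L phosphatase and
#' sampled over 60 min.  Returns noisy replicate band fractions together
#' with a site-occupancy dataset; the noiseless truth and the generating
#' parameters travel in the metadata.
#'
#' @param params ground-truth `phos_params` (e.g. [phos_preset()]).
#' @param phosphatase `"PP1"` or `"PP2A"`.
#' @param noise a [noise_model()].
#' @param seed integer seed (datasets are byte-identical for equal seeds).
#' @param initial named initial composition (fractions; default
#'   `c(abd = 0.5, abgd = 0.5)`).
#' @param substrate_molar total substrate (default 20e-6).
#' @param phosphatase_molar phosphatase concentration (default 0.1e-6).
#' @param times_s sampling times, s.
#' @param rate_mode `"mm"` or `"tqssa"`.
#' @return list with elements `bands` and `occupancy`, both `phos_dataset`.
#' @export
gen_dephos_timecourse <- function(params, phosphatase = "PP1",
                                  noise = noise_model(), seed = 1,
                                  initial = c(abd = 0.5, abgd = 0.5),
                                  substrate_molar = 20e-6,
                                  phosphatase_molar = 0.1e-6,
                                  times_s = c(0, 120, 300, 600, 900, 1200,
                                              1800, 2400, 3000, 3600),
                                  rate_mode = "mm") {
  if (!phosphatase %in% c("PP1", "PP2A")) {
    stop("phosphatase must be PP1 or PP2A", call. = FALSE)
  }
  net <- phos_network(params$variant)
  y0 <- .initial_state(net, initial, substrate_molar)
  enz <- do.call(enzyme_levels,
                 stats::setNames(list(phosphatase_molar), phosphatase))
  tc <- integrate_adaptive(params, enz, y0, max(times_s), times = times_s,
                           rate_mode = rate_mode)
  truth_bands <- t(apply(tc$states, 1, band_projection, network = net))
  truth_occ <- t(apply(tc$states, 1, site_occupancy, network = net))
  meta_common <- list(
    name = paste0("dephos_", phosphatase),
    variant = params$variant, rate_mode = rate_mode,
    y0 = y0, enzymes = unclass(enz), times = times_s, seed = seed,
    sd_fraction = noise$sd_fraction, n_replicates = noise$n_replicates
  )
  reps <- .with_seed(seed, {
    b <- list(); o <- list()
    for (r in seq_len(noise$n_replicates)) {
      fb <- .noisy_fractions(truth_bands, noise$sd_fraction)
      fo <- .noisy_fractions(truth_occ, noise$sd_fraction)
      b[[r]] <- data.frame(time_s = times_s, replicate = r,
                           stats::setNames(as.data.frame(fb),
                                           .fraction_cols))
      o[[r]] <- data.frame(time_s = times_s, replicate = r,
                           stats::setNames(as.data.frame(fo),
                                           paste0("occ_", PHOS_SITES)))
    }
    list(bands = do.call(rbind, b), occ = do.call(rbind, o))
  })
  meta_b <- c(meta_common, list(observable = "bands",
                                truth = as.data.frame(truth_bands)))
  meta_o <- c(meta_common, list(observable = "occupancy",
                                truth = as.data.frame(truth_occ)))
  # per-point SDs are floored at the noise model's nominal SD: empirical
  # SDs from a handful of replicates are too unstable to serve as weights
  floor_sd <- max(0.01, noise$sd_fraction)
  list(
    bands = phos_dataset("bands_timecourse", reps$bands,
                         .summarize_reps(reps$bands, "time_s",
                                         .fraction_cols, floor_sd),
                         meta_b),
    occupancy = phos_dataset("occupancy_timecourse", reps$occ,
                             .summarize_reps(reps$occ, "time_s",
                                             paste0("occ_", PHOS_SITES),
                                             floor_sd),
                             meta_o)
  )
}

#' Synthetic initial-rate (Michaelis-Menten) dataset
#'
#' Incubates a mono-phosphorylated (or unphosphorylated) substrate with one
#' enzyme and quenches early; the rate is product formed divided by quench
#' time.  A quench long enough to consume more than 15% of the largest
#' substrate concentration is recorded as a warning in the metadata.
#'
#' @inheritParams gen_dephos_timecourse
#' @param enzyme enzyme name.
#' @param phospho_form substrate form (e.g. `"a"`, `"d"`, `"0P"`).
#' @param substrate_grid substrate concentrations, mol/L.
#' @param quench_s quench time, s.
#' @param enzyme_molar enzyme concentration (default 0.1e-6).
#' @return `phos_dataset` of type `"initial_rate"` (rates in mol/L/s,
#'   multiplicative replicate noise of SD `noise$sd_fraction`).
#' @export
gen_initial_rate_dataset <- function(params, enzyme, phospho_form,
                                     substrate_grid, quench_s,
                                     noise = noise_model(), seed = 1,
                                     enzyme_molar = 0.1e-6,
                                     rate_mode = "mm") {
  if (!enzyme %in% PHOS_ENZYMES) stop("unknown enzyme: ", enzyme,
                                      call. = FALSE)
  net <- phos_network(params$variant)
  enz <- do.call(enzyme_levels, stats::setNames(list(enzyme_molar), enzyme))
  i_form <- match(phospho_form, net$forms)
  if (is.na(i_form)) stop("unknown form: ", phospho_form, call. = FALSE)
  truth_rate <- vapply(substrate_grid, function(s) {
    if (s == 0) return(0)
    y0 <- stats::setNames(numeric(net$n_forms), net$forms)
    y0[i_form] <- s
    tc <- integrate_adaptive(params, enz, y0, quench_s,
                             times = c(0, quench_s), rate_mode = rate_mode)
    (s - tc$states[2, i_form]) / quench_s
  }, numeric(1))
  s_max <- max(substrate_grid)
  consumed <- truth_rate[which.max(substrate_grid)] * quench_s / s_max
  warn <- consumed > 0.15
  reps <- .with_seed(seed, {
    do.call(rbind, lapply(seq_len(noise$n_replicates), function(r) {
      fac <- if (noise$sd_fraction > 0) {
        pmax(1 + stats::rnorm(length(truth_rate), 0, noise$sd_fraction), 0)
      } else rep(1, length(truth_rate))
      data.frame(substrate_molar = substrate_grid, replicate = r,
                 rate = truth_rate * fac)
    }))
  })
  summ <- .summarize_reps(reps, "substrate_molar", "rate",
                          sd_floor = max(1e-12,
                                         max(0.01, noise$sd_fraction) *
                                           max(truth_rate)))
  meta <- list(name = paste0("mm_", enzyme, "_", phospho_form),
               variant = params$variant, rate_mode = rate_mode,
               enzyme = enzyme, enzymes = unclass(enz),
               phospho_form = phospho_form, quench_s = quench_s,
               substrate_grid = substrate_grid, seed = seed,
               sd_fraction = noise$sd_fraction,
               n_replicates = noise$n_replicates,
               quench_warning = warn, truth_rate = truth_rate)
  phos_dataset("initial_rate", reps, summ, meta)
}

#' Synthetic steady-state PKA dose-response dataset
#'
#' Steady-state band fractions of 20 umol/L initially unphosphorylated
#' substrate incubated with a fixed phosphatase level and a grid of PKA
#' concentrations, optionally with a fixed background kinase (e.g. 100
#' nmol/L RSK2 or PKCe).  Non-converged steady states are flagged.
#'
#' @inheritParams gen_dephos_timecourse
#' @param pka_grid PKA concentrations, mol/L (log-spaced).
#' @param phosphatase `"PP1"` or `"PP2A"`.
#' @param phosphatase_molar fixed phosphatase concentration (default 0.5e-6).
#' @param background named vector of background kinase concentrations,
#'   e.g. `c(RSK2 = 1e-7)`; `NULL` for none.
#' @return `phos_dataset` of type `"dose_response"`.
#' @export
gen_dose_response_dataset <- function(params, pka_grid,
                                      phosphatase = "PP1",
                                      phosphatase_molar = 0.5e-6,
                                      background = NULL,
                                      noise = noise_model(), seed = 1,
                                      substrate_molar = 20e-6,
                                      rate_mode = "mm") {
  net <- phos_network(params$variant)
  y0 <- .initial_state(net, c(`0P` = 1), substrate_molar)
  base <- stats::setNames(as.list(numeric(5)), PHOS_ENZYMES)
  base[[phosphatase]] <- phosphatase_molar
  for (nm in names(background)) base[[nm]] <- background[[nm]]
  truth <- matrix(NA_real_, length(pka_grid), 5)
  converged <- logical(length(pka_grid))
  for (i in seq_along(pka_grid)) {
    base$PKA <- pka_grid[i]
    ss <- steady_state(params, do.call(enzyme_levels, base), y0,
                       rate_mode = rate_mode)
    truth[i, ] <- band_projection(ss$state, net)
    converged[i] <- ss$converged
  }
  reps <- .with_seed(seed, {
    do.call(rbind, lapply(seq_len(noise$n_replicates), function(r) {
      fb <- .noisy_fractions(truth, noise$sd_fraction)
      data.frame(conc_molar = pka_grid, replicate = r,
                 stats::setNames(as.data.frame(fb), .fraction_cols))
    }))
  })
  meta <- list(name = paste0("dose_PKA_", phosphatase),
               variant = params$variant, rate_mode = rate_mode,
               y0 = y0, titrated = "PKA", grid = pka_grid,
               enzymes_base = unlist(base), seed = seed,
               sd_fraction = noise$sd_fraction,
               n_replicates = noise$n_replicates,
               converged = converged,
               truth = as.data.frame(truth))
  phos_dataset("dose_response", reps,
               .summarize_reps(reps, "conc_molar", .fraction_cols,
                               max(0.01, noise$sd_fraction)), meta)
}

#' Synthetic steady-state phospho-distribution dataset
#'
#' Steady-state 0P-4P distribution generated by a known enzyme vector, the
#' synthetic stand-in for tissue phospho-distribution data.  The truth
#' vector is stored in the metadata for recovery tests.
#'
#' @inheritParams gen_dephos_timecourse
#' @param enzymes `phos_enzymes` ground-truth enzyme vector.
#' @return `phos_dataset` of type `"distribution"`.
#' @export
gen_distribution_dataset <- function(params, enzymes,
                                     noise = noise_model(), seed = 1,
                                     substrate_molar = 20e-6,
                                     rate_mode = "mm") {
  net <- phos_network(params$variant)
  y0 <- .initial_state(net, c(`0P` = 1), substrate_molar)
  ss <- steady_state(params, enzymes, y0, rate_mode = rate_mode)
  truth <- band_projection(ss$state, net)
  reps <- .with_seed(seed, {
    do.call(rbind, lapply(seq_len(noise$n_replicates), function(r) {
      fb <- .noisy_fractions(matrix(truth, 1), noise$sd_fraction)
      data.frame(replicate = r,
                 stats::setNames(as.data.frame(fb), .fraction_cols))
    }))
  })
  reps_sum <- data.frame(point = 1)
  for (cc in .fraction_cols) {
    reps_sum[[cc]] <- mean(reps[[cc]])
    reps_sum[[paste0("sd_", cc)]] <- max(stats::sd(reps[[cc]]), 0.01,
                                         noise$sd_fraction)
  }
  meta <- list(name = "distribution", variant = params$variant,
               rate_mode = rate_mode, y0 = y0,
               enzymes = unclass(enzymes), seed = seed,
               sd_fraction = noise$sd_fraction,
               n_replicates = noise$n_replicates,
               converged = ss$converged, truth = as.numeric(truth))
  phos_dataset("distribution", reps, reps_sum, meta)
}

#' Reference calibration suite for one phosphatase
#'
#' Generates the package's standard set of calibration experiments from a
#' ground-truth parameter set: the 3P/4P dephosphorylation time course
#' (band fractions plus site occupancies), a 2P (`ab`) and a 3P (`abg`)
#' dephosphorylation time course, and initial-rate assays for the
#' mono-phosphorylated substrates `a` and `d`.  The delta assay uses a
#' strongly reduced enzyme concentration and a short quench so that
#' initial rates remain valid for the fast delta kinetics.
#'
#' @inheritParams gen_dephos_timecourse
#' @return list with elements `dephos_34` (list of `bands`, `occupancy`),
#'   `dephos_ab`, `dephos_abg` (same), `ir_a`, `ir_d`.
#' @export
gen_calibration_suite <- function(params, phosphatase = "PP1",
                                  noise = noise_model(), seed = 1,
                                  rate_mode = "mm") {
  grid <- c(2.5, 5, 10, 20, 40) * 1e-6
  list(
    dephos_34 = gen_dephos_timecourse(params, phosphatase, noise,
                                      seed = seed, rate_mode = rate_mode),
    dephos_ab = gen_dephos_timecourse(params, phosphatase, noise,
                                      seed = seed + 1,
                                      initial = c(ab = 1),
                                      rate_mode = rate_mode),
    dephos_abg = gen_dephos_timecourse(params, phosphatase, noise,
                                       seed = seed + 4,
                                       initial = c(abg = 1),
                                       times_s = c(0, 60, 120, 300, 600,
                                                   900, 1200, 1800, 2400,
                                                   3600),
                                       rate_mode = rate_mode),
    ir_a = gen_initial_rate_dataset(params, phosphatase, "a", grid,
                                    quench_s = 120, noise = noise,
                                    seed = seed + 2,
                                    rate_mode = rate_mode),
    ir_d = gen_initial_rate_dataset(params, phosphatase, "d", grid,
                                    quench_s = 20, noise = noise,
                                    seed = seed + 3, enzyme_molar = 2e-9,
                                    rate_mode = rate_mode)
  )
}
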