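# Stable 31-bit string hash (polynomial, mod 2^31 - 1). Used to derive
# per-jar RNG substreams that do not depend on iteration order.
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

jar_seed <- function(master_seed, treatment, replicate) {
  key <- stable_hash(paste(treatment, replicate, sep = "\r"))
  as.integer((as.numeric(master_seed) * 48271 + key) %% 2147483647)
}

# True (noise-free) measurable quantities of one jar state, on a dry
# mineral-soil basis. Concentrations are g C per kg of fraction (or soil)
# mass; fraction delta13C is the C-weighted mean of the source end-members.
true_measurables <- function(state, design) {
  input <- design$soil_mass_g
  cmass <- design$coarse_mass_frac * input
  fmass <- (1 - design$coarse_mass_frac) * input
  poc <- state$poc_new + state$poc_old
  maoc <- state$maoc_new + state$maoc_old
  bulk <- poc + maoc
  wmean_delta <- function(c_new, c_old, d_new, d_old, d_empty) {
    tot <- c_new + c_old
    if (tot <= 0) return(d_empty)
    (c_new * d_new + c_old * d_old) / tot
  }
  d_old_bulk_mix <- function() {
    tot <- state$poc_old + state$maoc_old
    if (tot <= 0) return(design$delta_old_maoc)
    (state$poc_old * design$delta_old_poc +
       state$maoc_old * design$delta_old_maoc) / tot
  }
  list(
    input_mass_g = input, coarse_mass_g = cmass, fine_mass_g = fmass,
    coarse_c_gkg = 1000 * poc / cmass,
    fine_c_gkg = 1000 * maoc / fmass,
    bulk_c_gkg = 1000 * bulk / input,
    coarse_d13c = wmean_delta(state$poc_new, state$poc_old,
                              design$delta_litter, design$delta_old_poc,
                              design$delta_old_poc),
    fine_d13c = wmean_delta(state$maoc_new, state$maoc_old,
                            design$delta_litter, design$delta_old_maoc,
                            design$delta_old_maoc),
    bulk_d13c = wmean_delta(state$poc_new + state$maoc_new,
                            state$poc_old + state$maoc_old,
                            design$delta_litter, d_old_bulk_mix(),
                            d_old_bulk_mix()))
}

#' Turn a true jar state into a noisy observation
#'
#' Emulates the measurement chain: particle-size fractionation recovers a
#' drawn multiplicative share of the input mass (mass loss is assumed
#' proportional, so concentrations are unbiased); organic-C concentrations
#' get multiplicative relative noise; \eqn{\delta^{13}}C values get
#' additive noise. Bulk C and bulk \eqn{\delta^{13}}C are measured on a
#' separate milled aliquot, independently of the fractions, so summed-pool
#' C recovery scatters around 100% rather than closing exactly.
#'
#' Uses the current RNG state; seed upstream (or via
#' [generate_experiment()], which derives per-jar substreams).
#'
#' @param state One row of [simulate_pools()] output (list or one-row
#'   data frame with the pool columns).
#' @param design The [experiment_design()].
#' @param noise A [noise_model()]; `noise_off()` reproduces the true values
#'   exactly.
#' @return One-row tibble in the observation-table layout (see
#'   [generate_experiment()]).
#' @export
observe <- function(state, design, noise = noise_model()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  tv <- true_measurables(state, design)
  recovery <- noise$mass_recovery_mean +
    if (noise$mass_recovery_sd > 0) stats::rnorm(1, 0, noise$mass_recovery_sd) else 0
  jitter_c <- function(x) x * (1 + if (noise$cv_concentration > 0)
    stats::rnorm(1, 0, noise$cv_concentration) else 0)
  jitter_d <- function(x) x + if (noise$sd_delta > 0)
    stats::rnorm(1, 0, noise$sd_delta) else 0
  tibble::tibble(
    treatment = state$treatment,
    replicate = if (!is.null(state$replicate)) state$replicate else NA_integer_,
    month = state$month,
    coarse_mass_g = recovery * tv$coarse_mass_g,
    fine_mass_g = recovery * tv$fine_mass_g,
    input_mass_g = tv$input_mass_g,
    coarse_c_gkg = jitter_c(tv$coarse_c_gkg),
    fine_c_gkg = jitter_c(tv$fine_c_gkg),
    bulk_c_gkg = jitter_c(tv$bulk_c_gkg),
    coarse_d13c = jitter_d(tv$coarse_d13c),
    fine_d13c = jitter_d(tv$fine_d13c),
    bulk_d13c = jitter_d(tv$bulk_d13c))
}

#' Generate a complete synthetic incubation dataset
#'
#' Simulates true pool trajectories, then draws noisy per-jar observations
#' for every treatment x replicate at each post-start occasion, plus
#' control observations at month 0 (the isotopic reference the mixing
#' model requires). Litter DRIFT spectra are generated for each
#' litter-amended treatment ([generate_spectrum()]), four spectral
#' replicates each. Each jar and each spectrum draws from its own RNG
#' substream derived by stable hashing of (treatment, replicate), so the
#' output is identical no matter how the loops are reordered.
#'
#' @param design An [experiment_design()].
#' @param config A [simulation_config()]; its `noise` and `seed` drive the
#'   observation layer.
#' @return A list with `observations` (tibble, one row per jar x
#'   occasion), `spectra` (tibble: treatment, replicate, cn_ratio, nested
#'   wavenumber/absorbance columns unnested into long form), and `states`
#'   (the true trajectories from [simulate_pools()]).
#' @export
generate_experiment <- function(design = experiment_design(),
                                config = simulation_config()) {
  states <- simulate_pools(design, config)
  labels <- vapply(design$treatments, `[[`, character(1), "label")
  control <- labels[vapply(design$treatments, `[[`, logical(1), "is_control")]

  obs <- list()
  for (tr in labels) {
    tr_states <- states[states$treatment == tr, ]
    months <- config$months[config$months > 0]
    if (tr %in% control) months <- config$months  # control anchors t0
    for (rep in seq_len(design$replicates)) {
      set.seed(jar_seed(config$seed, tr, rep))
      for (m in months) {
        st <- as.list(tr_states[tr_states$month == m, ])
        st$replicate <- as.integer(rep)
        obs[[length(obs) + 1L]] <- observe(st, design, config$noise)
      }
    }
  }
  observations <- dplyr::bind_rows(obs)

  spectra <- list()
  for (tr in design$treatments) {
    if (tr$is_control) next
    for (rep in 1:4) {
      set.seed(jar_seed(config$seed, paste0("spectrum:", tr$label), rep))
      sp <- generate_spectrum(tr$cn_ratio)
      spectra[[length(spectra) + 1L]] <- tibble::tibble(
        treatment = tr$label, replicate = as.integer(rep),
        cn_ratio = tr$cn_ratio, wavenumber_cm1 = sp$wavenumber,
        absorbance = sp$absorbance)
    }
  }
  list(observations = observations,
       spectra = dplyr::bind_rows(spectra),
       states = states)
}

#' Read and write observation tables
#'
#' The on-disk dialect is plain CSV with one row per jar x occasion and
#' columns `treatment, replicate, month, coarse_mass_g, fine_mass_g,
#' input_mass_g, coarse_c_gkg, fine_c_gkg, bulk_c_gkg, coarse_d13c,
#' fine_d13c, bulk_d13c`. \eqn{\delta^{13}}C values far outside the
#' plausible soil range (-35 to -5 permil) trigger a warning on read.
#'
#' @param observations Observation tibble.
#' @param path File path.
#' @return `read_observations()` returns the tibble; `write_observations()`
#'   returns `path` invisibly.
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(observations, path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("treatment", "replicate", "month", "coarse_mass_g",
              "fine_mass_g", "input_mass_g", "coarse_c_gkg", "fine_c_gkg",
              "bulk_c_gkg", "coarse_d13c", "fine_d13c", "bulk_d13c")
  missing <- setdiff(needed, names(obs))
  if (length(missing)) stop("observation table lacks columns: ",
                            paste(missing, collapse = ", "))
  deltas <- unlist(obs[c("coarse_d13c", "fine_d13c", "bulk_d13c")])
  if (any(deltas < -35 | deltas > -5, na.rm = TRUE))
    warning("delta13C values outside the plausible [-35, -5] permil window")
  obs
}

#' Save or load a run configuration
#'
#' Serialises an [experiment_design()] plus [simulation_config()] pair to
#' a plain-text YAML key-value file and restores it. Round-trips exactly.
#'
#' @param design,config The objects to save.
#' @param path File path.
#' @return `read_run_config()` returns `list(design, config)`.
#' @export
write_run_config <- function(design, config, path) {
  treatments <- lapply(design$treatments, function(tr) unclass(tr))
  d <- unclass(design); d$treatments <- treatments
  cf <- unclass(config); cf$noise <- unclass(config$noise)
  yaml::write_yaml(list(design = d, config = cf), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  treatments <- lapply(raw$design$treatments, function(tr) {
    if (isTRUE(tr$is_control)) control_batch(tr$label)
    else litter_batch(tr$label, tr$c_pct, tr$n_pct, tr$delta13c,
                      tr$mineral_n_g)
  })
  d <- raw$design
  design <- experiment_design(
    soil_mass_g = d$soil_mass_g, soil_c_gkg = d$soil_c_gkg,
    soil_n_gkg = d$soil_n_gkg, litter_mass_g = d$litter_mass_g,
    treatments = treatments, replicates = d$replicates,
    delta_litter = d$delta_litter, delta_old_maoc = d$delta_old_maoc,
    delta_old_poc = d$delta_old_poc,
    initial_old_split = d$initial_old_split,
    coarse_mass_frac = d$coarse_mass_frac)
  cf <- raw$config
  config <- simulation_config(
    k_poc_new = cf$k_poc_new, k_poc_old = cf$k_poc_old,
    k_maoc_new = cf$k_maoc_new, k_maoc_old = cf$k_maoc_old,
    h_transfer = cf$h_transfer, alpha_priming = cf$alpha_priming,
    alpha_priming_poc = cf$alpha_priming_poc,
    cn_reference = cf$cn_reference,
    mineral_n_offset = cf$mineral_n_offset,
    noise = noise_model(cf$noise$cv_concentration, cf$noise$sd_delta,
                        cf$noise$mass_recovery_mean,
                        cf$noise$mass_recovery_sd),
    seed = cf$seed, months = cf$months)
  list(design = design, config = config)
}
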