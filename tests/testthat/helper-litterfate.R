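# Shared fixtures, built in code.

zero_noise_config <- function(...) {
  simulation_config(noise = noise_off(), seed = 11L, ...)
}

# A trimmed design: control plus two litters, 2 replicates.
small_design <- function(replicates = 2) {
  experiment_design(
    treatments = list(control_batch("CON"),
                      litter_batch("CN50", 44.17, 0.89),
                      litter_batch("CN124", 43.43, 0.35)),
    replicates = replicates)
}

# g C per jar -> g C per kg dry soil under a design
per_kg <- function(g_per_jar, design) 1000 * g_per_jar / design$soil_mass_g

# Merge estimated partition against simulator truth for round-trip checks.
roundtrip_errors <- function(design, config) {
  ds <- generate_experiment(design, config)
  ref <- reference_from_control(ds$observations,
                                delta_litter = design$delta_litter)
  part <- partition_pools(ds$observations, ref)
  joined <- merge(as.data.frame(part), as.data.frame(ds$states),
                  by = c("treatment", "month"),
                  suffixes = c(".est", ".true"))
  vapply(c("poc_new", "poc_old", "maoc_new", "maoc_old"), function(p) {
    est <- joined[[paste0(p, ".est")]] * design$soil_mass_g / 1000
    tru <- joined[[paste0(p, ".true")]]
    max(abs(est - tru) / pmax(abs(tru), 1e-12))
  }, numeric(1))
}

# Random spectrum on the instrument grid for band-scan property tests.
random_spectrum <- function() {
  grid <- seq(4000, 400, by = -4)
  drift_spectrum(grid, abs(stats::rnorm(length(grid))) +
                   stats::runif(1, 0, 2) *
                   exp(-((grid - stats::runif(1, 500, 3900)) / 40)^2))
}

# Exhaustive in-window scan, the oracle band_max is checked against.
scan_band_max <- function(spec, window) {
  best <- -Inf
  for (i in seq_along(spec$wavenumber)) {
    w <- spec$wavenumber[i]
    if (w >= window[1] && w <= window[2] && spec$absorbance[i] > best)
      best <- spec$absorbance[i]
  }
  best
}

# Letters/p-value consistency check for compact letter displays: shared
# letter <=> adjusted p >= alpha, verified for every pair.
cld_consistent <- function(tk) {
  shares <- function(a, b) {
    la <- strsplit(tk$letters[[a]], "")[[1]]
    lb <- strsplit(tk$letters[[b]], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  for (i in seq_len(nrow(tk$pairwise))) {
    g1 <- tk$pairwise$group1[i]; g2 <- tk$pairwise$group2[i]
    sig <- tk$pairwise$p_adj[i] < tk$alpha
    if (sig == shares(g1, g2)) return(FALSE)
  }
  TRUE
}
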