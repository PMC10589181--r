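#' Two-source mixing model: fraction of C4-derived carbon
#'
#' The workhorse of natural-abundance \eqn{\delta^{13}}C partitioning:
#' \deqn{f_{C4} = \frac{\delta^{13}C_{sample} - \delta^{13}C_{ref}}
#'                     {\delta^{13}C_{litter} - \delta^{13}C_{ref}},}
#' where the reference is the corresponding unamended-control signature at
#' the start of the incubation and the litter end-member is the C4 plant
#' material. Measurement noise can push the raw ratio slightly outside
#' \[0, 1\]; such values are clipped and a warning reports how many were
#' clipped beyond numerical tolerance.
#'
#' @param delta_sample Sample \eqn{\delta^{13}}C, permil (vectorised).
#' @param delta_ref Reference (native-soil) end-member, permil.
#' @param delta_litter C4 litter end-member, permil.
#' @param clip If `FALSE`, return the raw ratio unclipped.
#' @param tol Excursions beyond \[0, 1\] larger than this count as clips.
#' @return Numeric vector of C4-derived fractions in \[0, 1\] (or raw
#'   ratios when `clip = FALSE`).
#' @examples
#' f_c4(-20.2, delta_ref = -26.2, delta_litter = -14.2)  # 0.5
#' @export
f_c4 <- function(delta_sample, delta_ref, delta_litter, clip = TRUE,
                 tol = 1e-9) {
  if (any(delta_litter == delta_ref))
    stop("mixing equation undefined: delta_litter (", delta_litter,
         ") equals delta_ref (", delta_ref, ")")
  f <- (delta_sample - delta_ref) / (delta_litter - delta_ref)
  if (!clip) return(f)
  n_out <- sum(f < -tol | f > 1 + tol, na.rm = TRUE)
  if (n_out > 0)
    warning(n_out, " f_C4 value(s) outside [0, 1] were clipped")
  pmin(1, pmax(0, f))
}

#' Isotopic reference signatures for partitioning
#'
#' Bundles the end-members the mixing model needs: the unamended control's
#' bulk, POC and MAOC \eqn{\delta^{13}}C at the start of the incubation,
#' and the litter signature. `reference_from_control()` extracts them from
#' an observation table by averaging the control jars at the reference
#' occasion.
#'
#' @param delta_ref_bulk,delta_ref_poc,delta_ref_maoc Control signatures,
#'   permil. The POC reference is expected at or below the MAOC reference
#'   (a warning flags the reverse).
#' @param delta_litter C4 litter signature, permil.
#' @return A `reference_signature` object.
#' @export
reference_signature <- function(delta_ref_bulk, delta_ref_poc,
                                delta_ref_maoc, delta_litter) {
  refs <- c(delta_ref_bulk, delta_ref_poc, delta_ref_maoc)
  if (any(delta_litter == refs))
    stop("delta_litter coincides with a reference signature")
  if (delta_ref_poc > delta_ref_maoc)
    warning("POC reference is heavier than the MAOC reference; ",
            "expected the opposite")
  structure(list(delta_ref_bulk = delta_ref_bulk,
                 delta_ref_poc = delta_ref_poc,
                 delta_ref_maoc = delta_ref_maoc,
                 delta_litter = delta_litter),
            class = "reference_signature")
}

#' @rdname reference_signature
#' @param observations Observation table (see [generate_experiment()]).
#' @param control_label Treatment label of the unamended control.
#' @param month Reference occasion (default 0, the start).
#' @export
reference_from_control <- function(observations, control_label = "CON",
                                   month = 0, delta_litter = -14.2) {
  ctl <- observations[observations$treatment == control_label &
                        observations$month == month, ]
  if (nrow(ctl) == 0)
    stop("no rows for control '", control_label, "' at month ", month)
  reference_signature(mean(ctl$bulk_d13c), mean(ctl$coarse_d13c),
                      mean(ctl$fine_d13c), delta_litter)
}

#' Partition observations into the four source-resolved pools
#'
#' Converts fraction C concentrations to g C per kg soil using constant
#' mass proportions -- each fraction's share of recovered (coarse + fine)
#' mass is frozen at its treatment's first-occasion mean, removing
#' fractionation-yield noise from the pool time series -- then splits each
#' fraction into new (litter-derived) and old (native) C with the mixing
#' model, using the POC reference for the coarse fraction, the MAOC
#' reference for the fine fraction, and the bulk reference for bulk SOC.
#'
#' @param observations Observation table, any number of rows.
#' @param ref A [reference_signature()].
#' @return Tibble with one row per observation: pools `poc_new, poc_old,
#'   maoc_new, maoc_old` and `bulk_total` (plus `bulk_new`, `bulk_old`) in
#'   g C per kg soil, the C4 fractions `f_c4_poc, f_c4_maoc, f_c4_bulk`,
#'   and the diagnostics `c_recovery_pct` and `mass_recovery_pct`.
#' @export
partition_pools <- function(observations, ref) {
  stopifnot(inherits(ref, "reference_signature"))
  obs <- tibble::as_tibble(observations)
  props <- obs |>
    dplyr::group_by(.data$treatment) |>
    dplyr::filter(.data$month == min(.data$month)) |>
    dplyr::summarise(prop_coarse = mean(.data$coarse_mass_g /
                                          (.data$coarse_mass_g + .data$fine_mass_g)),
                     .groups = "drop")
  out <- obs |>
    dplyr::left_join(props, by = "treatment") |>
    dplyr::mutate(
      poc_total = .data$coarse_c_gkg * .data$prop_coarse,
      maoc_total = .data$fine_c_gkg * (1 - .data$prop_coarse),
      bulk_total = .data$bulk_c_gkg,
      f_c4_poc = f_c4(.data$coarse_d13c, ref$delta_ref_poc, ref$delta_litter),
      f_c4_maoc = f_c4(.data$fine_d13c, ref$delta_ref_maoc, ref$delta_litter),
      f_c4_bulk = f_c4(.data$bulk_d13c, ref$delta_ref_bulk, ref$delta_litter),
      poc_new = .data$f_c4_poc * .data$poc_total,
      poc_old = .data$poc_total - .data$poc_new,
      maoc_new = .data$f_c4_maoc * .data$maoc_total,
      maoc_old = .data$maoc_total - .data$maoc_new,
      bulk_new = .data$f_c4_bulk * .data$bulk_total,
      bulk_old = .data$bulk_total - .data$bulk_new,
      mass_recovery_pct = 100 * (.data$coarse_mass_g + .data$fine_mass_g) /
        .data$input_mass_g)
  out$c_recovery_pct <- c_recovery(out)
  out[, c("treatment", "replicate", "month", "poc_new", "poc_old",
          "maoc_new", "maoc_old", "poc_total", "maoc_total", "bulk_total",
          "bulk_new", "bulk_old", "f_c4_poc", "f_c4_maoc", "f_c4_bulk",
          "c_recovery_pct", "mass_recovery_pct")]
}

#' Summed-pool carbon recovery
#'
#' Quality-control diagnostic: the four partitioned pools summed, as a
#' percentage of independently measured bulk SOC. Near 100 is good;
#' scatter reflects that fractions and bulk are measured on different
#' aliquots.
#'
#' @param partition Partition table (see [partition_pools()]) or anything
#'   with the four pool columns and `bulk_total`.
#' @return Numeric vector, percent.
#' @export
c_recovery <- function(partition) {
  if (any(partition$bulk_total <= 0, na.rm = TRUE))
    stop("bulk_total must be > 0 to compute C recovery")
  100 * (partition$poc_new + partition$poc_old + partition$maoc_new +
           partition$maoc_old) / partition$bulk_total
}

#' Fractionation mass recovery
#'
#' Recovered (coarse + fine) mass as a percentage of the input mass.
#'
#' @param observations Observation table with `coarse_mass_g`,
#'   `fine_mass_g` and `input_mass_g`.
#' @return Numeric vector, percent.
#' @export
mass_recovery <- function(observations) {
  if (any(observations$input_mass_g <= 0, na.rm = TRUE))
    stop("input_mass_g must be > 0")
  100 * (observations$coarse_mass_g + observations$fine_mass_g) /
    observations$input_mass_g
}

#' Relative change of a pool against its reporting baseline
#'
#' Loss-type pools (bulk SOC, POC and MAOC old pools, new POC) are
#' reported as percent change relative to their initial amount (the
#' control's fraction at the start, or initial bulk including added
#' litter); newly formed MAOC is instead reported as percent of the
#' initially added litter C, since it starts at zero.
#'
#' @param pool_value Pool amount, g C per kg soil.
#' @param baseline_value Baseline amount in the same units: the initial
#'   pool for change-type bases, or added litter C for
#'   `"added_litter_c"`.
#' @param basis One of `"control_t0_fraction"`, `"control_t0_bulk"`,
#'   `"added_litter_c"`.
#' @return Percent change (or percent of added C), vectorised.
#' @export
relative_change <- function(pool_value, baseline_value,
                            basis = c("control_t0_fraction",
                                      "control_t0_bulk",
                                      "added_litter_c")) {
  basis <- match.arg(basis)
  if (any(baseline_value <= 0, na.rm = TRUE))
    stop("baseline_value must be > 0")
  if (basis == "added_litter_c") 100 * pool_value / baseline_value
  else 100 * (pool_value - baseline_value) / baseline_value
}

#' Per-jar relative pool changes at one occasion
#'
#' Computes the standard reporting quantities for each litter-amended jar
#' at the chosen occasion: change in bulk SOC relative to the initial
#' amount (native + added litter C), changes in POC_new (relative to the
#' added litter C, which all starts as POC), POC_old and MAOC_old
#' (relative to the control's initial fraction means), and MAOC_new as a
#' percentage of added litter C.
#'
#' @param partition Partition table from [partition_pools()].
#' @param design The [experiment_design()] (supplies added litter C).
#' @param month Occasion to report (default: the last).
#' @param control_label Unamended control label, excluded from the output
#'   and used for baselines.
#' @return Tibble: treatment, replicate, `d_soc`, `d_poc_new`,
#'   `d_poc_old`, `d_maoc_new`, `d_maoc_old` (percent).
#' @export
pool_changes <- function(partition, design, month = NULL,
                         control_label = "CON") {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(month)) month <- max(partition$month)
  ctl0 <- partition[partition$treatment == control_label &
                      partition$month == min(partition$month), ]
  if (nrow(ctl0) == 0) stop("control baseline rows not found")
  base_poc <- mean(ctl0$poc_total)
  base_maoc <- mean(ctl0$maoc_total)
  base_bulk_native <- mean(ctl0$bulk_total)

  batches <- design$treatments
  names(batches) <- vapply(batches, `[[`, character(1), "label")
  rows <- partition[partition$month == month &
                      partition$treatment != control_label, ]
  added <- vapply(rows$treatment, function(tr) {
    b <- batches[[tr]]
    if (is.null(b) || b$is_control) return(NA_real_)
    1000 * design$litter_mass_g * b$c_pct / 100 / design$soil_mass_g
  }, numeric(1))
  tibble::tibble(
    treatment = rows$treatment,
    replicate = rows$replicate,
    month = rows$month,
    d_soc = relative_change(rows$bulk_total, base_bulk_native + added,
                            "control_t0_bulk"),
    d_poc_new = relative_change(rows$poc_new, added, "control_t0_fraction"),
    d_poc_old = relative_change(rows$poc_old, base_poc,
                                "control_t0_fraction"),
    d_maoc_new = relative_change(rows$maoc_new, added, "added_litter_c"),
    d_maoc_old = relative_change(rows$maoc_old, base_maoc,
                                 "control_t0_fraction"))
}

#' Treatment-level summary with an overall average row
#'
#' Means and SDs over replicates for every numeric column, per treatment,
#' plus an `Average` row holding the unweighted mean of the treatment
#' means (the convention used for the overall row of incubation summary
#' tables) and the pooled across-jar SD.
#'
#' @param changes Per-jar table with a `treatment` column and numeric
#'   value columns (e.g. from [pool_changes()]).
#' @return Tibble with one row per treatment plus `Average`; for each
#'   value column `<col>_mean` and `<col>_sd`.
#' @export
summarize_treatments <- function(changes) {
  value_cols <- setdiff(names(changes)[vapply(changes, is.numeric,
                                              logical(1))],
                        c("replicate", "month"))
  if (length(value_cols) == 0) stop("no numeric value columns to summarise")
  per <- changes |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols),
                                   list(mean = ~mean(.x), sd = ~stats::sd(.x))),
                     .groups = "drop")
  avg <- tibble::tibble(treatment = "Average")
  for (col in value_cols) {
    avg[[paste0(col, "_mean")]] <- mean(per[[paste0(col, "_mean")]])
    avg[[paste0(col, "_sd")]] <- stats::sd(changes[[col]])
  }
  dplyr::bind_rows(per, avg)
}
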