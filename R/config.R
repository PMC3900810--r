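#' Configuration for composition database construction
#'
#' Collects the tunable constants of the four-step assignment hierarchy.
#'
#' @param fat_threshold Fat content (g/100 g) at or below which a food is
#'   considered to hold only a trace of fat and is assigned zero TFA by the
#'   zero rule. Default 0.1, the resolution at which national food tables
#'   report fat.
#' @param similarity_threshold Maximum nutrient distance (see
#'   [nutrient_distance()]) at which two foods count as nutritionally
#'   "similar". Default 0.25 (a 25% relative deviation in the worst
#'   component).
#' @param similarity_floor Floor (in the unit of each component) applied to
#'   the denominator of the relative deviation, so that near-zero nutrient
#'   values do not blow up the distance. Default 1.
#' @param step2_thresholded Logical; if `TRUE` (default) the Step 2 non-meat
#'   transfers (same-category, same-group) only accept a donor within
#'   `similarity_threshold`; if `FALSE` they take the nearest donor
#'   unconditionally.
#' @param part_adjacency List of length-2 character vectors naming pairs of
#'   meat cuts regarded as "similar parts" (symmetric), e.g.
#'   `list(c("loin", "sirloin"))`. Expert judgment enters the hierarchy as
#'   data here, not as code.
#' @param species_adjacency List of length-2 character vectors naming pairs
#'   of animal types regarded as similar and of the same species (symmetric).
#'
#' @return A list of class `tfa_db_config`.
#' @export
db_config <- function(fat_threshold = 0.1,
                      similarity_threshold = 0.25,
                      similarity_floor = 1,
                      step2_thresholded = TRUE,
                      part_adjacency = list(),
                      species_adjacency = list()) {
  stopifnot(fat_threshold >= 0, similarity_threshold > 0, similarity_floor > 0)
  structure(
    list(fat_threshold = fat_threshold,
         similarity_threshold = similarity_threshold,
         similarity_floor = similarity_floor,
         step2_thresholded = isTRUE(step2_thresholded),
         part_adjacency = part_adjacency,
         species_adjacency = species_adjacency),
    class = "tfa_db_config")
}

#' Configuration for intake estimation
#'
#' @param energy_per_gram_fat Energy conversion factor for fat, kcal per gram
#'   (Atwater). Used to express fat-derived intake as a percentage of total
#'   energy. Default 9.
#' @param outlier_k Multiplier k for the mean +/- k SD outlier exclusion of
#'   subjects, applied within sex on both the g/day and %-energy scales.
#'   Default 3.
#' @param missing_tfa What to do when a consumed food has no TFA assignment:
#'   `"error"` (default) or `"zero"` (treat as contributing no TFA, used for
#'   reduced-database comparisons).
#'
#' @return A list of class `tfa_intake_config`.
#' @export
intake_config <- function(energy_per_gram_fat = 9,
                          outlier_k = 3,
                          missing_tfa = c("error", "zero")) {
  missing_tfa <- match.arg(missing_tfa)
  stopifnot(energy_per_gram_fat > 0, outlier_k > 0)
  structure(
    list(energy_per_gram_fat = energy_per_gram_fat,
         outlier_k = outlier_k,
         missing_tfa = missing_tfa),
    class = "tfa_intake_config")
}

#' Configuration for stratified summaries
#'
#' @param urban_density_threshold Population density (persons/km^2) at or
#'   above which an area is classified urban. Default 1000, which cleanly
#'   separates typical city densities (several thousand) from provincial
#'   ones (a few hundred).
#' @param who_threshold_pct_energy Intake threshold as % of total energy used
#'   by [frequency_above()]; the conventional public-health ceiling is 1% of
#'   energy. Default 1.
#' @param gday_bin_edges Interior bin edges (g/day) of the intake
#'   distribution table.
#' @param pct_energy_bin_edges Interior bin edges (% energy) of the intake
#'   distribution table.
#'
#' @return A list of class `tfa_summary_config`.
#' @export
summary_config <- function(urban_density_threshold = 1000,
                           who_threshold_pct_energy = 1,
                           gday_bin_edges = c(1, 1.5, 2, 2.5, 3),
                           pct_energy_bin_edges = c(0.5, 0.75, 1, 1.25, 1.5)) {
  stopifnot(urban_density_threshold > 0)
  structure(
    list(urban_density_threshold = urban_density_threshold,
         who_threshold_pct_energy = who_threshold_pct_energy,
         gday_bin_edges = gday_bin_edges,
         pct_energy_bin_edges = pct_energy_bin_edges),
    class = "tfa_summary_config")
}
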