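#' Estimate a substitution rate
#'
#' The rate is the number of observed changes at third codon positions,
#' divided by the number of considered third codon positions, divided by the
#' time in years over which the changes were observed.  No multiple-hit
#' correction is applied: over the decade-scale intervals this package
#' targets, expected per-site divergence is far below saturation, and back
#' mutations are a documented caveat rather than a correction.
#'
#' @param k_changes Observed third-position substitutions (integer >= 0).
#' @param L_sites Considered third-position sites (> 0).
#' @param t_years Elapsed time in years (> 0).
#' @param comparison_id Label for the comparison.
#' @return A one-row data.frame of class `rate_estimate` with columns
#'   `comparison_id`, `k_changes`, `L_sites`, `t_years`, `rate`.
#' @export
estimate_rate <- function(k_changes, L_sites, t_years,
                          comparison_id = "comparison") {
  if (L_sites <= 0) stop("L_sites must be > 0")
  if (t_years <= 0) stop("t_years must be > 0")
  if (k_changes < 0) stop("k_changes must be >= 0")
  out <- data.frame(comparison_id = comparison_id,
                    k_changes = as.integer(k_changes),
                    L_sites = as.integer(L_sites),
                    t_years = as.numeric(t_years),
                    rate = k_changes / L_sites / t_years,
                    stringsAsFactors = FALSE)
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Elapsed years between two ISO dates
#'
#' Convenience for configs that give sampling dates rather than elapsed time
#' (365.25 days per year).
#'
#' @param from,to Dates in `YYYY-MM-DD` form.
#' @return Numeric years.
#' @export
years_between <- function(from, to) {
  as.numeric(difftime(as.Date(to), as.Date(from), units = "days")) / 365.25
}

#' Run one rate comparison
#'
#' Orchestrates the per-comparison analysis: per-library coverage masks at
#' `min_depth` are intersected; CDSs not entirely covered in every library are
#' dropped; variants are restricted to fully masked spans; third-position
#' changes are counted within the retained CDSs and divided by the considered
#' third-position sites and the elapsed years.  Variant effects and the
#' substitution spectrum are computed on the mask-filtered variants.
#'
#' @param genome Reference [Biostrings::DNAStringSet].
#' @param cds Reference CDS `GRanges`.
#' @param variants Variant data.frame for this isolate vs the reference.
#' @param tracks List of `depth_track` objects, one per sequencing library.
#' @param t_years Elapsed years for this comparison.
#' @param comparison_id Label.
#' @param min_depth Coverage threshold (default 5).
#' @param genetic_code Genetic code table id (default `"4"`).
#' @param denominator `"intersection"` (third positions of retained CDSs that
#'   also lie in the all-libraries mask; default) or `"all-third"` (all third
#'   positions of retained CDSs).
#' @param cpmap Optional precomputed `codon_map` (avoids rebuilding in loops).
#' @return List with `estimate` (a `rate_estimate`), `effects`, `spectrum`,
#'   `mask`, `retained_cds`, `n_variants_in`, `n_variants_retained`.
#' @export
run_rate_comparison <- function(genome, cds, variants, tracks, t_years,
                                comparison_id = "comparison",
                                min_depth = 5L, genetic_code = "4",
                                denominator = c("intersection", "all-third"),
                                cpmap = NULL) {
  denominator <- match.arg(denominator)
  if (is.null(cpmap)) cpmap <- build_codon_position_map(genome, cds)
  masks <- lapply(tracks, build_coverage_mask, min_depth = min_depth)
  mask <- intersect_masks(masks)
  retained <- select_fully_covered_cds(cpmap$cds, mask)
  if (length(retained) == 0L) {
    stop("no CDS entirely covered at depth >= ", min_depth,
         " in all libraries for comparison ", comparison_id)
  }
  filt <- filter_variants_by_mask(variants, mask)
  k <- count_third_position_changes(filt, cpmap, retained)
  L <- count_third_position_sites(cpmap, retained,
                                  mask = if (denominator == "intersection")
                                    mask else NULL)
  est <- estimate_rate(k, L, t_years, comparison_id)
  effects <- classify_variant_effect(filt, cpmap, genome, genetic_code)
  spec <- substitution_spectrum(filt)
  list(estimate = est, effects = effects, spectrum = spec, mask = mask,
       retained_cds = retained, n_variants_in = nrow(variants),
       n_variants_retained = nrow(filt))
}
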