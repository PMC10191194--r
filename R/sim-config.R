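#' Configuration for the synthetic microcosm study generator
#'
#' Bundles all knobs of the synthetic-data generators into one validated
#' list. Defaults mirror the design of a nine-isolate ectomycorrhizal
#' microcosm experiment: 9 fungal isolate conditions plus an uninoculated
#' plant control, 3 transcriptome replicates per condition, 4-5 isotope and
#' growth replicates per isolate, and expressed-transcript set sizes of
#' 24,615 (plant) and 12,959 (fungus).
#'
#' @param n_isolates Number of fungal isolate conditions.
#' @param n_transcriptome_reps Replicates per condition in the count matrix.
#' @param n_isotope_reps Symbiosis (ERM + leaf) plates per isolate.
#' @param n_flm_reps Free-living mycelium control plates per isolate.
#' @param n_plant_transcripts,n_fungal_transcripts Transcripts simulated per
#'   organism (before expression filtering).
#' @param n_planted_pos,n_planted_neg Number of transcripts per organism whose
#'   log mean expression is made linearly dependent on (respectively,
#'   opposite to) the standardized per-isolate carbon acquisition.
#' @param planted_effect Slope of log mean expression per unit of
#'   standardized carbon acquisition (dimensionless).
#' @param nb_dispersion Negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param size_factor_range Length-2 interval from which per-sample library
#'   size multipliers are drawn uniformly.
#' @param baseline_atom_pct Natural-abundance 13C atom percent used for
#'   free-living mycelium (default 1.08, the standard 13C abundance).
#' @param leaf_enrichment_range Length-2 interval of leaf 13C atom percent
#'   after pulse labelling; lower bound must exceed `baseline_atom_pct`.
#' @param isotope_noise_sd Gaussian measurement noise SD on atom percent
#'   values (0 gives exactly invertible data).
#' @param growth_noise_cv Coefficient of variation of the multiplicative
#'   measurement noise on growth measurements (0 gives noise-free data).
#' @param seed Master RNG seed; each data family (isotope, growth, counts,
#'   annotations) uses an independent stream derived from it.
#'
#' @return A list of class `mycoflux_config`.
#' @examples
#' cfg <- sim_config(n_plant_transcripts = 500, n_fungal_transcripts = 300)
#' cfg$n_isolates
#' @export
sim_config <- function(n_isolates = 9,
                       n_transcriptome_reps = 3,
                       n_isotope_reps = 5,
                       n_flm_reps = 3,
                       n_plant_transcripts = 24615,
                       n_fungal_transcripts = 12959,
                       n_planted_pos = 200,
                       n_planted_neg = 200,
                       planted_effect = 2,
                       nb_dispersion = 0.1,
                       size_factor_range = c(0.5, 2),
                       baseline_atom_pct = 1.08,
                       leaf_enrichment_range = c(2.5, 4.5),
                       isotope_noise_sd = 0.02,
                       growth_noise_cv = 0.1,
                       seed = 1L) {
  counts <- c(
    n_isolates = n_isolates, n_transcriptome_reps = n_transcriptome_reps,
    n_isotope_reps = n_isotope_reps, n_flm_reps = n_flm_reps,
    n_plant_transcripts = n_plant_transcripts,
    n_fungal_transcripts = n_fungal_transcripts
  )
  if (any(counts < 1)) {
    rlang::abort(paste0(
      "all design counts must be >= 1; offending: ",
      paste(names(counts)[counts < 1], collapse = ", ")
    ))
  }
  if (n_planted_pos < 0 || n_planted_neg < 0) {
    rlang::abort("planted transcript counts must be non-negative")
  }
  n_min <- min(n_plant_transcripts, n_fungal_transcripts)
  if (n_planted_pos + n_planted_neg > n_min) {
    rlang::abort("n_planted_pos + n_planted_neg exceeds the transcripts available per organism")
  }
  stopifnot(
    length(size_factor_range) == 2, all(size_factor_range > 0),
    diff(size_factor_range) >= 0,
    length(leaf_enrichment_range) == 2, diff(leaf_enrichment_range) >= 0
  )
  if (leaf_enrichment_range[1] <= baseline_atom_pct) {
    rlang::abort("leaf_enrichment_range lower bound must exceed baseline_atom_pct (leaves must be enriched)")
  }
  if (nb_dispersion < 0 || isotope_noise_sd < 0 || growth_noise_cv < 0) {
    rlang::abort("dispersion and noise parameters must be non-negative")
  }
  structure(
    list(
      n_isolates = as.integer(n_isolates),
      n_transcriptome_reps = as.integer(n_transcriptome_reps),
      n_isotope_reps = as.integer(n_isotope_reps),
      n_flm_reps = as.integer(n_flm_reps),
      n_plant_transcripts = as.integer(n_plant_transcripts),
      n_fungal_transcripts = as.integer(n_fungal_transcripts),
      n_planted_pos = as.integer(n_planted_pos),
      n_planted_neg = as.integer(n_planted_neg),
      planted_effect = planted_effect,
      nb_dispersion = nb_dispersion,
      size_factor_range = size_factor_range,
      baseline_atom_pct = baseline_atom_pct,
      leaf_enrichment_range = leaf_enrichment_range,
      isotope_noise_sd = isotope_noise_sd,
      growth_noise_cv = growth_noise_cv,
      seed = as.integer(seed)
    ),
    class = "mycoflux_config"
  )
}

#' @export
print.mycoflux_config <- function(x, ...) {
  cat("<mycoflux_config>\n")
  cat(sprintf(
    "  design: %d isolates x %d transcriptome reps (+ control), %d isotope reps, %d FLM reps\n",
    x$n_isolates, x$n_transcriptome_reps, x$n_isotope_reps, x$n_flm_reps
  ))
  cat(sprintf(
    "  transcripts: %d plant, %d fungal (%d + %d planted per organism, effect %.2f)\n",
    x$n_plant_transcripts, x$n_fungal_transcripts,
    x$n_planted_pos, x$n_planted_neg, x$planted_effect
  ))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Independent, reproducible RNG stream per data family. The multiplier keeps
# the derived seed inside 32-bit integer range for any master seed.
stream_seed <- function(seed, stream = c("isotope", "growth", "counts", "annotations")) {
  stream <- match.arg(stream)
  offset <- c(isotope = 11L, growth = 23L, counts = 37L, annotations = 53L)[[stream]]
  (abs(as.integer(seed)) %% 1000003L) * 2039L + offset
}

default_isolate_labels <- function(n) sprintf("iso%02d", seq_len(n))
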