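#' Simulate raw fungal growth measurements with known trait means
#'
#' Generates the raw per-plate measurements from which growth traits are
#' derived: colony dry biomass, colony areas at week 2 and week 4, the
#' original agar inoculation-block area, colonized vs total root-tip counts,
#' Hartig net depth, mantle thickness, and mycelium percent carbon.
#' Measurements on fungus-only plates (biomass, areas, %C) and on symbiosis
#' plates (root-tip counts, Hartig net depth, mantle thickness) follow the
#' usual microcosm design.
#'
#' True per-isolate trait values are drawn once per isolate from realistic
#' ranges (biomass 0.1-1.3 mg, mycelium C 36-42%, hyphal density derived
#' from biomass and area, colonization 40-95%, Hartig net depth 4-17 um,
#' mantle 20-65 um); raw measurements are constructed to be exactly
#' consistent with those traits, then perturbed by multiplicative Gaussian
#' noise with coefficient of variation `cfg$growth_noise_cv` (tip counts use
#' binomial sampling). With zero noise, [derive_growth_traits()] recovers
#' the configured truth exactly.
#'
#' @param cfg A [sim_config()] object.
#' @param days Days between the week-2 marking ("plant contact") and harvest
#'   used to construct areas from the true radial growth rate.
#' @param total_tips Total lateral root tips in contact with mycelium per
#'   symbiosis plate.
#' @return A list of class `growth_sim`: `raw` (tibble of per-plate
#'   measurements) and `truth` (tibble of the per-isolate true trait values;
#'   for colonization the truth is the realized percentage after rounding
#'   tip counts to integers).
#' @examples
#' gs <- sim_growth(sim_config(growth_noise_cv = 0))
#' head(gs$raw)
#' @export
sim_growth <- function(cfg, days = 14, total_tips = 50L) {
  stopifnot(inherits(cfg, "mycoflux_config"), days >= 1, total_tips >= 1)
  isolates <- default_isolate_labels(cfg$n_isolates)
  old <- .Random.seed_exists()
  set.seed(stream_seed(cfg$seed, "growth"))
  on.exit(.restore_seed(old), add = TRUE)

  n <- cfg$n_isolates
  truth <- tibble::tibble(
    isolate = isolates,
    biomass_mg = stats::runif(n, 0.1, 1.3),
    pct_c = stats::runif(n, 36, 42),
    colony_area_wk4 = stats::runif(n, 10, 30),
    radial_growth_rate = stats::runif(n, 4, 21),
    colonization_pct = 100 * round(stats::runif(n, 0.40, 0.95) * total_tips) / total_tips,
    hartig_depth_um = stats::runif(n, 4, 17),
    mantle_thickness_um = stats::runif(n, 20, 65)
  ) |>
    dplyr::mutate(
      hyphal_density = .data$biomass_mg / .data$colony_area_wk4,
      colony_area_wk2 = .data$colony_area_wk4 / (1 + .data$radial_growth_rate * days / 100)
    )

  cv <- cfg$growth_noise_cv
  jitter_mult <- function(mu, n_rep) {
    if (cv == 0) return(rep(mu, n_rep))
    pmax(stats::rnorm(n_rep, mu, cv * mu), mu * 0.05)
  }

  raw <- purrr::map(seq_len(n), function(i) {
    tr <- truth[i, ]
    n_rep <- cfg$n_isotope_reps
    a4 <- jitter_mult(tr$colony_area_wk4, n_rep)
    a2 <- pmin(jitter_mult(tr$colony_area_wk2, n_rep), a4)
    colonized <- if (cv == 0) {
      rep(round(tr$colonization_pct / 100 * total_tips), n_rep)
    } else {
      stats::rbinom(n_rep, total_tips, tr$colonization_pct / 100)
    }
    fungus_only <- tibble::tibble(
      isolate = tr$isolate,
      replicate = sprintf("f%d", seq_len(n_rep)),
      plate_type = "fungus_only",
      biomass_mg = jitter_mult(tr$biomass_mg, n_rep),
      colony_area_wk2 = a2,
      colony_area_wk4 = a4,
      agar_block_area = 0.25,
      colonized_tips = NA_integer_,
      total_tips_in_contact = NA_integer_,
      hartig_depth_um = NA_real_,
      mantle_thickness_um = NA_real_,
      pct_c = jitter_mult(tr$pct_c, n_rep)
    )
    symbiosis <- tibble::tibble(
      isolate = tr$isolate,
      replicate = sprintf("r%d", seq_len(n_rep)),
      plate_type = "symbiosis",
      biomass_mg = NA_real_,
      colony_area_wk2 = NA_real_,
      colony_area_wk4 = NA_real_,
      agar_block_area = NA_real_,
      colonized_tips = as.integer(colonized),
      total_tips_in_contact = as.integer(total_tips),
      hartig_depth_um = jitter_mult(tr$hartig_depth_um, n_rep),
      mantle_thickness_um = jitter_mult(tr$mantle_thickness_um, n_rep),
      pct_c = NA_real_
    )
    dplyr::bind_rows(fungus_only, symbiosis)
  }) |>
    dplyr::bind_rows()

  structure(list(raw = raw, truth = truth, days = days), class = "growth_sim")
}
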