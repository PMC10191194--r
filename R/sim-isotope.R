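#' Simulate a 13C pulse-labelling isotope dataset with known carbon transfer
#'
#' Generates per-plate 13C atom percent measurements for the three tissue
#' roles of the mixing model -- extra-radical mycelium (ERM) and leaves from
#' symbiosis plates, free-living mycelium (FLM) from fungus-only plates --
#' such that inverting the mixing model on noise-free draws recovers the
#' generating per-isolate carbon amounts exactly. Colony dry-biomass and
#' percent-carbon statistics needed to convert mixing fractions into
#' absolute mg C are generated alongside.
#'
#' Each symbiosis plate gets its own leaf enrichment value; the plate's ERM
#' atom percent is placed on the two-pool mixing line between the FLM
#' baseline and that leaf value at the isolate's true mixing fraction.
#' Gaussian measurement noise (`cfg$isotope_noise_sd`) is added to every
#' atom percent; draws outside (0, 100) are resampled. With
#' `inject_outliers = TRUE` one gross ERM outlier per isolate is appended
#' (flagged in the `injected_outlier` column) to exercise the IQR filter.
#'
#' @param cfg A [sim_config()] object.
#' @param true_c Optional numeric vector of per-isolate host-derived carbon
#'   (mg C) to plant as ground truth. Defaults to fixed fractions
#'   (0.10-0.80) of each colony's carbon capacity (biomass x %C), giving
#'   mixing fractions spread over a realistic 10-80% band.
#' @param colonies Optional tibble of colony statistics (`isolate`,
#'   `mean_biomass`, `mean_pct_c`); generated when `NULL`.
#' @param inject_outliers Append one gross ERM outlier per isolate?
#'
#' @return A list of class `isotope_sim` with elements `samples` (tibble:
#'   `isolate`, `tissue`, `replicate`, `atom_pct_13c`, `injected_outlier`),
#'   `colonies` (tibble: `isolate`, `mean_biomass`, `mean_pct_c`), and
#'   `true_c` (named mg C vector, the ground truth).
#' @examples
#' sim <- sim_isotope(sim_config(isotope_noise_sd = 0))
#' head(sim$samples)
#' sim$true_c
#' @export
sim_isotope <- function(cfg, true_c = NULL, colonies = NULL, inject_outliers = FALSE) {
  stopifnot(inherits(cfg, "mycoflux_config"))
  isolates <- default_isolate_labels(cfg$n_isolates)

  old <- .Random.seed_exists()
  set.seed(stream_seed(cfg$seed, "isotope"))
  on.exit(.restore_seed(old), add = TRUE)

  if (is.null(colonies)) {
    colonies <- tibble::tibble(
      isolate = isolates,
      # magnitudes typical of four-week Pisolithus colonies on low-glucose agar
      mean_biomass = stats::runif(cfg$n_isolates, 0.6, 1.3),
      mean_pct_c = stats::runif(cfg$n_isolates, 36, 42)
    )
  }
  stopifnot(all(c("isolate", "mean_biomass", "mean_pct_c") %in% names(colonies)))
  capacity <- (colonies$mean_pct_c / 100) * colonies$mean_biomass # mg C in colony

  if (is.null(true_c)) {
    frac <- seq(0.10, 0.80, length.out = cfg$n_isolates)
    true_c <- frac * capacity
  }
  if (length(true_c) != cfg$n_isolates) {
    rlang::abort("true_c must have one value per isolate")
  }
  if (any(true_c < 0)) rlang::abort("true_c must be non-negative")
  names(true_c) <- isolates
  mix_frac <- true_c / capacity # %C_symbiosis / 100
  if (any(mix_frac > 1)) {
    rlang::abort("true_c exceeds colony carbon capacity (mixing fraction > 1)")
  }

  rnoisy <- function(mu) {
    if (cfg$isotope_noise_sd == 0) return(mu)
    out <- stats::rnorm(length(mu), mu, cfg$isotope_noise_sd)
    bad <- out <= 0 | out >= 100
    while (any(bad)) {
      out[bad] <- stats::rnorm(sum(bad), mu[bad], cfg$isotope_noise_sd)
      bad <- out <= 0 | out >= 100
    }
    out
  }

  # one labelling level per isolate (plates of an isolate share the chamber
  # pulse); within-isolate spread comes from measurement noise only
  leaf_levels <- stats::runif(
    cfg$n_isolates,
    cfg$leaf_enrichment_range[1], cfg$leaf_enrichment_range[2]
  )

  per_isolate <- purrr::map(seq_along(isolates), function(i) {
    leaf_true <- rep(leaf_levels[i], cfg$n_isotope_reps)
    erm_true <- cfg$baseline_atom_pct + mix_frac[i] * (leaf_true - cfg$baseline_atom_pct)
    flm_true <- rep(cfg$baseline_atom_pct, cfg$n_flm_reps)
    tibble::tibble(
      isolate = isolates[i],
      tissue = c(
        rep("ERM", cfg$n_isotope_reps),
        rep("leaf", cfg$n_isotope_reps),
        rep("FLM", cfg$n_flm_reps)
      ),
      replicate = c(
        sprintf("r%d", seq_len(cfg$n_isotope_reps)),
        sprintf("r%d", seq_len(cfg$n_isotope_reps)),
        sprintf("f%d", seq_len(cfg$n_flm_reps))
      ),
      atom_pct_13c = rnoisy(c(erm_true, leaf_true, flm_true)),
      injected_outlier = FALSE
    )
  })
  samples <- dplyr::bind_rows(per_isolate)

  if (inject_outliers) {
    outliers <- samples |>
      dplyr::filter(.data$tissue == "ERM") |>
      dplyr::group_by(.data$isolate) |>
      dplyr::summarise(
        atom_pct_13c = {
          q <- stats::quantile(.data$atom_pct_13c, c(0.25, 0.75), type = 7)
          iqr <- max(q[2] - q[1], 0.05)
          unname(q[2] + 10 * iqr)
        },
        .groups = "drop"
      ) |>
      dplyr::mutate(
        tissue = "ERM", replicate = "outlier", injected_outlier = TRUE
      )
    samples <- dplyr::bind_rows(samples, outliers) |>
      dplyr::arrange(match(.data$isolate, isolates))
  }

  structure(
    list(samples = samples, colonies = colonies, true_c = true_c),
    class = "isotope_sim"
  )
}

# Save/restore .Random.seed so generators do not disturb the caller's RNG
# state beyond their own stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
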