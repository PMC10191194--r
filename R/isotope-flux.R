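#' Interquartile-range outlier filter
#'
#' Flags values outside the Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]`, with
#' quartiles computed by linear interpolation (quantile type 7). The filter
#' is applied once, never re-iterated, and the fences are closed: values on
#' the boundary are kept, so a constant vector loses nothing.
#'
#' @param values Numeric vector, all finite.
#' @param k Fence multiplier (conventional 1.5).
#' @return List with `kept` (values inside the fences, original order) and
#'   `removed` (integer indices of the removed values). With fewer than 4
#'   values, quartiles are too unstable to trust: everything is kept, with
#'   a warning.
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100))
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) == 0) rlang::abort("iqr_filter: empty input")
  if (!is.numeric(values) || any(!is.finite(values))) {
    rlang::abort("iqr_filter: values must be finite numerics")
  }
  if (length(values) < 4) {
    rlang::warn("iqr_filter: fewer than 4 values; keeping all")
    return(list(kept = values, removed = integer(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- which(values < q[1] - k * iqr | values > q[2] + k * iqr)
  list(kept = if (length(out)) values[-out] else values, removed = out)
}

#' Percentage of fungal carbon derived from the plant host
#'
#' Two-pool isotope mixing fraction: the ERM (extra-radical mycelium)
#' 13C atom percent is modelled as a mixture of unlabelled fungal carbon at
#' the FLM (free-living mycelium) baseline and host-fixed carbon at the
#' leaf enrichment level,
#' \deqn{\%C_{symbiosis} = \frac{^{13}C_{ERM} - ^{13}C_{FLM}}
#'   {^{13}C_{leaf} - ^{13}C_{FLM}} \times 100.}
#'
#' Values slightly below 0 or above 100 can arise from measurement noise;
#' they are returned unmodified (clamping would bias isolate means) and can
#' be flagged downstream.
#'
#' @param erm ERM 13C atom percent (vectorized).
#' @param flm_mean Mean FLM 13C atom percent (baseline).
#' @param leaf Leaf 13C atom percent of the same plate (vectorized).
#' @param tol Minimum leaf - FLM enrichment; a smaller denominator is
#'   degenerate and raises an error.
#' @return Percentage(s) of fungal C derived from the host.
#' @examples
#' pct_c_symbiosis(erm = 1.3, flm_mean = 1.1, leaf = 3.1) # 10%
#' @export
pct_c_symbiosis <- function(erm, flm_mean, leaf, tol = 1e-6) {
  if (any(abs(leaf - flm_mean) < tol)) {
    rlang::abort("denominator degenerate: leaf not enriched above baseline")
  }
  (erm - flm_mean) / (leaf - flm_mean) * 100
}

#' Absolute host-derived carbon retained in the fungal colony
#'
#' Converts a mixing percentage into mg of host-derived carbon using the
#' colony's average percent carbon and dry biomass:
#' `(pct_sym/100) * (mean_pct_c/100) * mean_biomass`. Both percentages are
#' treated as fractions so the result carries the biomass unit (mg C).
#' Respired or exuded carbon is not part of this quantity: it measures only
#' what is retained in hyphal tissue.
#'
#' @param pct_sym Percentage of fungal C derived from the host (vectorized).
#' @param mean_pct_c Average percent carbon of the dried mycelium.
#' @param mean_biomass Average dry biomass of the fungus-only colonies (mg).
#' @return Host-derived carbon in mg.
#' @examples
#' c_symbiosis(10, mean_pct_c = 40, mean_biomass = 1.0) # 0.04 mg C
#' @export
c_symbiosis <- function(pct_sym, mean_pct_c, mean_biomass) {
  stopifnot(is.numeric(pct_sym), is.numeric(mean_pct_c), is.numeric(mean_biomass))
  (pct_sym / 100) * (mean_pct_c / 100) * mean_biomass
}

#' Run the full isotope-to-carbon pipeline
#'
#' Per isolate: IQR-filters atom percent values within each tissue role,
#' averages the surviving FLM values into the baseline, pairs each
#' surviving ERM replicate with a leaf value (same plate by default), and
#' emits per-replicate mixing percentages and absolute carbon amounts plus
#' per-isolate means and standard errors.
#'
#' @param samples Tibble with columns `isolate`, `tissue` (one of "ERM",
#'   "FLM", "leaf"), `replicate`, `atom_pct_13c`.
#' @param colonies Tibble with columns `isolate`, `mean_biomass` (mg),
#'   `mean_pct_c` (percent C of dry mycelium).
#' @param k IQR fence multiplier passed to [iqr_filter()].
#' @param leaf_pairing `"plate"` pairs each ERM replicate with the leaf
#'   value from the same plate (isolate + replicate); `"isolate_mean"` uses
#'   the isolate's mean leaf value for every ERM replicate.
#' @return Object of class `carbon_flux`: list with `replicates` (tibble:
#'   `isolate`, `replicate`, `atom_pct_erm`, `atom_pct_leaf`, `flm_mean`,
#'   `pct_c_symbiosis`, `c_symbiosis_mg`, `flagged` for out-of-[0,100]
#'   mixing values), `isolates` (per-isolate mean and SE of both
#'   quantities, with n), and `removed` (tibble of IQR-removed samples).
#'   [generics::tidy()] returns the replicate table, [generics::glance()]
#'   the isolate summary.
#' @examples
#' sim <- sim_isotope(sim_config(isotope_noise_sd = 0))
#' flux <- carbon_flux(sim$samples, sim$colonies)
#' glance(flux)
#' @export
carbon_flux <- function(samples, colonies, k = 1.5,
                        leaf_pairing = c("plate", "isolate_mean")) {
  leaf_pairing <- match.arg(leaf_pairing)
  req <- c("isolate", "tissue", "replicate", "atom_pct_13c")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    rlang::abort(paste0("samples missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(samples$tissue %in% c("ERM", "FLM", "leaf"))) {
    rlang::abort('tissue must be one of "ERM", "FLM", "leaf"')
  }
  if (any(samples$atom_pct_13c <= 0 | samples$atom_pct_13c >= 100)) {
    rlang::abort("atom_pct_13c must lie in (0, 100)")
  }
  stopifnot(all(c("isolate", "mean_biomass", "mean_pct_c") %in% names(colonies)))

  has_all <- samples |>
    dplyr::distinct(.data$isolate, .data$tissue) |>
    dplyr::count(.data$isolate)
  incomplete <- has_all$isolate[has_all$n < 3]
  if (length(incomplete)) {
    rlang::abort(paste0(
      "isolate(s) lacking ERM, FLM or leaf samples: ",
      paste(incomplete, collapse = ", ")
    ))
  }

  # IQR filter within isolate x tissue role, applied once
  filtered <- samples |>
    dplyr::group_by(.data$isolate, .data$tissue) |>
    dplyr::mutate(.remove = if (dplyr::n() < 4) {
      rep(FALSE, dplyr::n()) # too few values for stable quartiles
    } else {
      res <- iqr_filter(.data$atom_pct_13c, k = k)
      seq_along(.data$atom_pct_13c) %in% res$removed
    }) |>
    dplyr::ungroup()
  removed <- dplyr::filter(filtered, .data$.remove) |> dplyr::select(-".remove")
  kept <- dplyr::filter(filtered, !.data$.remove) |> dplyr::select(-".remove")

  flm_means <- kept |>
    dplyr::filter(.data$tissue == "FLM") |>
    dplyr::group_by(.data$isolate) |>
    dplyr::summarise(flm_mean = mean(.data$atom_pct_13c), .groups = "drop")

  erm <- kept |>
    dplyr::filter(.data$tissue == "ERM") |>
    dplyr::select("isolate", "replicate", atom_pct_erm = "atom_pct_13c")
  leaf <- kept |>
    dplyr::filter(.data$tissue == "leaf") |>
    dplyr::select("isolate", "replicate", atom_pct_leaf = "atom_pct_13c")

  if (leaf_pairing == "plate") {
    # orphans that never had a leaf sample in the input are a design error;
    # pairs broken by outlier removal are silently dropped (the plate is out)
    all_leaf <- samples |>
      dplyr::filter(.data$tissue == "leaf") |>
      dplyr::select("isolate", "replicate")
    orphans <- dplyr::anti_join(erm, all_leaf, by = c("isolate", "replicate"))
    if (nrow(orphans) > 0) {
      rlang::abort(paste0(
        "ERM replicates without a matching leaf sample: ",
        paste(paste(orphans$isolate, orphans$replicate, sep = "/"), collapse = ", ")
      ))
    }
    paired <- dplyr::inner_join(erm, leaf, by = c("isolate", "replicate"))
  } else {
    leaf_means <- leaf |>
      dplyr::group_by(.data$isolate) |>
      dplyr::summarise(atom_pct_leaf = mean(.data$atom_pct_leaf), .groups = "drop")
    paired <- dplyr::left_join(erm, leaf_means, by = "isolate")
  }

  missing_colony <- setdiff(unique(paired$isolate), colonies$isolate)
  if (length(missing_colony)) {
    rlang::abort(paste0(
      "missing colony stats for isolate(s): ",
      paste(missing_colony, collapse = ", ")
    ))
  }

  replicates <- paired |>
    dplyr::left_join(flm_means, by = "isolate") |>
    dplyr::left_join(colonies, by = "isolate") |>
    dplyr::mutate(
      pct_c_symbiosis = pct_c_symbiosis(
        .data$atom_pct_erm, .data$flm_mean, .data$atom_pct_leaf
      ),
      c_symbiosis_mg = c_symbiosis(
        .data$pct_c_symbiosis, .data$mean_pct_c, .data$mean_biomass
      ),
      flagged = .data$pct_c_symbiosis < 0 | .data$pct_c_symbiosis > 100
    ) |>
    dplyr::select(
      "isolate", "replicate", "atom_pct_erm", "atom_pct_leaf", "flm_mean",
      "pct_c_symbiosis", "c_symbiosis_mg", "flagged"
    )

  se <- function(x) stats::sd(x) / sqrt(length(x))
  isolate_summary <- replicates |>
    dplyr::group_by(.data$isolate) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pct_c_symbiosis = mean(.data$pct_c_symbiosis),
      se_pct_c_symbiosis = se(.data$pct_c_symbiosis),
      mean_c_symbiosis_mg = mean(.data$c_symbiosis_mg),
      se_c_symbiosis_mg = se(.data$c_symbiosis_mg),
      .groups = "drop"
    )

  structure(
    list(replicates = replicates, isolates = isolate_summary, removed = removed),
    class = "carbon_flux"
  )
}

#' @export
print.carbon_flux <- function(x, ...) {
  cat(sprintf(
    "<carbon_flux> %d isolates, %d replicate measurements (%d removed as outliers)\n",
    nrow(x$isolates), nrow(x$replicates), nrow(x$removed)
  ))
  print(x$isolates)
  invisible(x)
}

#' @rdname carbon_flux
#' @param x A `carbon_flux` object.
#' @param ... Unused.
#' @method tidy carbon_flux
#' @export
tidy.carbon_flux <- function(x, ...) x$replicates

#' @rdname carbon_flux
#' @method glance carbon_flux
#' @export
glance.carbon_flux <- function(x, ...) x$isolates
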