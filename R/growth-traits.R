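#' Elementary growth-trait calculations
#'
#' @description
#' `colonization_pct()` -- percentage of lateral root tips in contact with
#' mycelium that bear a fungal mantle: `100 * colonized / total`.
#'
#' `hyphal_density()` -- colony dry biomass per unit colony area at harvest
#' (mg/cm2): `biomass_mg / area_wk4`.
#'
#' `radial_growth_rate()` -- percent area increase per day between the
#' week-2 marking (plant contact) and harvest, relative to the week-2 area:
#' `100 * (area_wk4 - area_wk2) / area_wk2 / days`.
#'
#' @param colonized,total Root-tip counts (`total >= 1`).
#' @param biomass_mg Colony dry biomass (mg).
#' @param area_wk2,area_wk4 Colony areas (cm2) at week 2 and week 4.
#' @param days Days between the two area measurements.
#' @param baseline Area the increase is expressed relative to: the week-2
#'   colony area (default) or the original agar inoculation block.
#' @param agar_block_area Agar block area (cm2), required when
#'   `baseline = "agar_block"`.
#' @return Numeric vector (all three are vectorized).
#' @examples
#' colonization_pct(7, 20) # 35
#' hyphal_density(1.0, 20) # 0.05
#' radial_growth_rate(10, 38, 14) # 20
#' @name growth_trait_calcs
NULL

#' @rdname growth_trait_calcs
#' @export
colonization_pct <- function(colonized, total) {
  if (any(total < 1)) rlang::abort("total root tips must be >= 1")
  if (any(colonized > total)) rlang::abort("colonized tips exceed total tips in contact")
  100 * colonized / total
}

#' @rdname growth_trait_calcs
#' @export
hyphal_density <- function(biomass_mg, area_wk4) {
  if (any(area_wk4 <= 0)) rlang::abort("colony area must be positive")
  biomass_mg / area_wk4
}

#' @rdname growth_trait_calcs
#' @export
radial_growth_rate <- function(area_wk2, area_wk4, days = 14,
                               baseline = c("week2", "agar_block"),
                               agar_block_area = NULL) {
  baseline <- match.arg(baseline)
  if (any(days < 1)) rlang::abort("days must be >= 1")
  ref <- if (baseline == "week2") {
    area_wk2
  } else {
    if (is.null(agar_block_area)) rlang::abort("agar_block_area required for agar_block baseline")
    agar_block_area
  }
  if (any(ref <= 0)) rlang::abort("baseline area must be positive")
  100 * (area_wk4 - area_wk2) / ref / days
}

#' Derive growth traits from raw plate measurements
#'
#' Turns raw per-plate measurements (see [sim_growth()] for the schema)
#' into the derived trait table: colonization percentage, hyphal density
#' and radial growth rate, plus pass-through biomass, percent C, Hartig net
#' depth and mantle thickness. Fungus-only plates contribute the biomass,
#' area and %C traits; symbiosis plates the root-tip and section traits.
#'
#' @param raw Tibble of raw measurements with columns `isolate`,
#'   `replicate`, `plate_type`, `biomass_mg`, `colony_area_wk2`,
#'   `colony_area_wk4`, `agar_block_area`, `colonized_tips`,
#'   `total_tips_in_contact`, `hartig_depth_um`, `mantle_thickness_um`,
#'   `pct_c`. Measurements not applicable to a plate type are `NA`.
#' @param days Days between week-2 marking and harvest.
#' @param rate_baseline Passed to [radial_growth_rate()].
#' @return Tibble of per-plate derived traits: `isolate`, `replicate`,
#'   `plate_type`, `colonization_pct`, `hyphal_density`,
#'   `radial_growth_rate`, `biomass_mg`, `pct_c`, `hartig_depth_um`,
#'   `mantle_thickness_um`.
#' @examples
#' gs <- sim_growth(sim_config(growth_noise_cv = 0))
#' derive_growth_traits(gs$raw)
#' @export
derive_growth_traits <- function(raw, days = 14, rate_baseline = "week2") {
  req <- c(
    "isolate", "replicate", "plate_type", "biomass_mg", "colony_area_wk2",
    "colony_area_wk4", "agar_block_area", "colonized_tips",
    "total_tips_in_contact", "hartig_depth_um", "mantle_thickness_um", "pct_c"
  )
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("raw growth table missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ok_area <- is.na(raw$colony_area_wk4) | is.na(raw$agar_block_area) |
    raw$colony_area_wk4 >= raw$agar_block_area
  if (!all(ok_area)) rlang::abort("colony_area_wk4 smaller than the agar block area")

  raw |>
    dplyr::mutate(
      colonization_pct = dplyr::if_else(
        is.na(.data$colonized_tips) | is.na(.data$total_tips_in_contact),
        NA_real_,
        colonization_pct(
          dplyr::coalesce(.data$colonized_tips, 0L),
          dplyr::coalesce(.data$total_tips_in_contact, 1L)
        )
      ),
      hyphal_density = dplyr::if_else(
        is.na(.data$biomass_mg) | is.na(.data$colony_area_wk4),
        NA_real_,
        .data$biomass_mg / dplyr::coalesce(.data$colony_area_wk4, 1)
      ),
      radial_growth_rate = dplyr::if_else(
        is.na(.data$colony_area_wk2) | is.na(.data$colony_area_wk4),
        NA_real_,
        100 * (.data$colony_area_wk4 - .data$colony_area_wk2) /
          dplyr::coalesce(.data$colony_area_wk2, 1) / days
      )
    ) |>
    dplyr::select(
      "isolate", "replicate", "plate_type", "colonization_pct",
      "hyphal_density", "radial_growth_rate", "biomass_mg", "pct_c",
      "hartig_depth_um", "mantle_thickness_um"
    )
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Fits a one-way fixed-effects ANOVA of a trait on group labels, runs
#' Tukey's HSD over all group pairs at family-wise level `alpha`
#' (Tukey-Kramer for unbalanced designs, via [stats::TukeyHSD()]), and
#' summarizes the pairwise results as a compact letter display built with
#' the insert-and-absorb algorithm: groups sharing no letter differ
#' significantly; groups sharing a letter do not.
#'
#' Letters are assigned in order of decreasing group mean, so the group
#' with the largest mean carries "a".
#'
#' @param data A data frame.
#' @param value,group Column names (tidy evaluation) of the numeric trait
#'   and the grouping factor.
#' @param alpha Family-wise error rate for the HSD test.
#' @return Object of class `growth_anova`: list with `anova` (tibble:
#'   `statistic` = F, `p.value`, `df`, `df.residual`), `tukey` (tibble of
#'   pairwise contrasts: `contrast`, `estimate`, `conf.low`, `conf.high`,
#'   `adj.p.value`), and `letters` (tibble: `group`, `mean`, `letters`).
#'   `tidy()` returns the pairwise table, `glance()` the ANOVA row.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 5), y = c(rnorm(5), rnorm(5, 10)))
#' fit <- anova_tukey(df, y, g)
#' fit$letters
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  df <- tibble::tibble(
    y = rlang::eval_tidy(value, data),
    g = as.character(rlang::eval_tidy(group, data))
  ) |>
    dplyr::filter(!is.na(.data$y), !is.na(.data$g))
  counts <- table(df$g)
  if (length(counts) < 2) rlang::abort("need at least 2 groups")
  if (any(counts < 2)) {
    rlang::abort(paste0(
      "group(s) with fewer than 2 replicates: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  df$g <- factor(df$g)
  fit <- stats::aov(y ~ g, data = df)
  an <- stats::anova(fit)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- tibble::tibble(
    contrast = rownames(hsd),
    estimate = hsd[, "diff"],
    conf.low = hsd[, "lwr"],
    conf.high = hsd[, "upr"],
    adj.p.value = hsd[, "p adj"]
  )

  groups <- levels(df$g)
  sig <- do.call(rbind, strsplit(pairs$contrast[pairs$adj.p.value < alpha], "-", fixed = TRUE))
  means <- tapply(df$y, df$g, mean)
  ord <- names(sort(means, decreasing = TRUE))
  letters_tbl <- tibble::tibble(
    group = ord,
    mean = as.numeric(means[ord]),
    letters = cld_insert_absorb(ord, sig)
  )

  structure(
    list(
      anova = tibble::tibble(
        statistic = an["g", "F value"], p.value = an["g", "Pr(>F)"],
        df = an["g", "Df"], df.residual = an["Residuals", "Df"]
      ),
      tukey = pairs,
      letters = letters_tbl,
      alpha = alpha
    ),
    class = "growth_anova"
  )
}

# Insert-and-absorb compact letter display. `groups` are group names in the
# order letters should be assigned (typically decreasing mean); `sig_pairs`
# is a 2-column character matrix of significantly different pairs (or NULL).
# Returns the letter string for each group, in the order of `groups`.
cld_insert_absorb <- function(groups, sig_pairs) {
  n <- length(groups)
  cols <- list(stats::setNames(rep(TRUE, n), groups))
  if (!is.null(sig_pairs) && length(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[r, 1]
      b <- sig_pairs[r, 2]
      new_cols <- list()
      for (col in cols) {
        if (col[[a]] && col[[b]]) {
          c1 <- col; c1[[a]] <- FALSE
          c2 <- col; c2[[b]] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns whose membership is a subset of another column's
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
            all(new_cols[[i]] <= new_cols[[j]]) &&
            !(all(new_cols[[i]] == new_cols[[j]]) && i < j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by the first (best-ranked) group they contain, then label
  first_member <- vapply(cols, function(col) min(match(names(col)[col], groups)), numeric(1))
  cols <- cols[order(first_member)]
  labels <- make_letter_labels(length(cols))
  vapply(groups, function(g) {
    paste(labels[vapply(cols, function(col) col[[g]], logical(1))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

make_letter_labels <- function(k) {
  base <- letters
  if (k <= length(base)) return(base[seq_len(k)])
  c(base, paste0(rep(base, each = length(base)), base))[seq_len(k)]
}

#' @export
print.growth_anova <- function(x, ...) {
  cat(sprintf(
    "<growth_anova> F(%d, %d) = %.3f, p = %.3g\n",
    x$anova$df, x$anova$df.residual, x$anova$statistic, x$anova$p.value
  ))
  print(x$letters)
  invisible(x)
}

#' @rdname anova_tukey
#' @param x A `growth_anova` object.
#' @param ... Unused.
#' @method tidy growth_anova
#' @export
tidy.growth_anova <- function(x, ...) x$tukey

#' @rdname anova_tukey
#' @method glance growth_anova
#' @export
glance.growth_anova <- function(x, ...) x$anova

#' PCA of log-transformed carbon-acquisition and growth traits
#'
#' Principal component analysis of per-isolate trait means: each numeric
#' variable is log-transformed (natural log of value + epsilon, with
#' epsilon = the variable's smallest positive value x 1e-3, to admit exact
#' zeros such as zero-biomass replicates), centered, and optionally scaled
#' to unit variance. Components carry a deterministic sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' Scaling defaults to `TRUE` because the traits carry incommensurate units
#' (mg, um, %/day); set `scale = FALSE` for a covariance-based PCA.
#'
#' @param data Data frame of one row per isolate; all numeric columns are
#'   used as variables, non-numeric columns (e.g. the isolate label) are
#'   carried into the scores table as identifiers. Variables with any
#'   missing value are dropped with a warning.
#' @param log_transform Log-transform before decomposition?
#' @param scale Scale variables to unit variance?
#' @return Object of class `trait_pca`: list with `scores` (tibble:
#'   identifier columns + PC1..PCk), `loadings` (tibble: `variable` +
#'   PC1..PCk), `var_explained` (numeric, sums to 1), and `sdev`.
#'   `tidy()` returns scores, loadings or eigenvalues via `matrix=`.
#' @examples
#' gs <- sim_growth(sim_config())
#' pca <- pca_traits(gs$truth)
#' pca$var_explained
#' @export
pca_traits <- function(data, log_transform = TRUE, scale = TRUE) {
  is_num <- vapply(data, is.numeric, logical(1))
  ids <- data[!is_num]
  x <- as.matrix(data[is_num])
  if (nrow(x) < 2) rlang::abort("need at least 2 isolates for PCA")
  has_na <- apply(x, 2, function(col) any(!is.finite(col)))
  if (any(has_na)) {
    rlang::warn(paste0(
      "dropping variable(s) with missing values: ",
      paste(colnames(x)[has_na], collapse = ", ")
    ))
    x <- x[, !has_na, drop = FALSE]
  }
  if (ncol(x) < 2) rlang::abort("need at least 2 complete variables for PCA")
  if (log_transform) {
    x <- apply(x, 2, function(col) {
      pos <- col[col > 0]
      if (!length(pos)) rlang::abort("cannot log-transform an all-zero variable")
      log(col + min(pos) * 1e-3)
    })
  }
  if (scale) {
    const <- apply(x, 2, stats::sd) == 0
    if (any(const)) {
      rlang::warn(paste0(
        "dropping constant variable(s): ", paste(colnames(x)[const], collapse = ", ")
      ))
      x <- x[, !const, drop = FALSE]
    }
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  # deterministic sign: largest |loading| per component positive
  for (j in seq_len(ncol(fit$rotation))) {
    i_max <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i_max, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  var_explained <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(tibble::as_tibble(ids), tibble::as_tibble(fit$x)),
      loadings = dplyr::bind_cols(
        tibble::tibble(variable = rownames(fit$rotation)),
        tibble::as_tibble(unclass(fit$rotation))
      ),
      var_explained = var_explained,
      sdev = fit$sdev
    ),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("<trait_pca>\n  variance explained: ",
    paste(sprintf("PC%d %.1f%%", seq_along(x$var_explained), 100 * x$var_explained),
      collapse = ", "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname pca_traits
#' @param x A `trait_pca` object.
#' @param matrix Which component to return: `"scores"`, `"loadings"`, or
#'   `"eigenvalues"`.
#' @param ... Unused.
#' @method tidy trait_pca
#' @export
tidy.trait_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble::tibble(
      component = seq_along(x$var_explained),
      std.dev = x$sdev,
      percent = x$var_explained,
      cumulative = cumsum(x$var_explained)
    )
  )
}

#' Pearson correlation between carbon acquisition and a growth trait
#'
#' Computes Pearson's r with its two-tailed t-test p-value between carbon
#' acquisition values and a trait. In `paired` mode the inputs are
#' replicate-level values from the same plates (e.g. C acquisition and
#' colonization from the one symbiosis plate); in averaged mode they are
#' per-isolate means, the appropriate pairing when the two quantities come
#' from different plates.
#'
#' @param c_values Numeric vector of carbon acquisition values.
#' @param trait_values Numeric vector of trait values, same length.
#' @param paired Logical flag recorded in the output (the arithmetic is the
#'   same; the flag documents what the rows are).
#' @return One-row tibble: `estimate` (r), `statistic` (t), `p.value`, `n`,
#'   `paired`.
#' @examples
#' trait_c_correlation(1:9, (1:9) * 2 + 3)
#' @export
trait_c_correlation <- function(c_values, trait_values, paired = FALSE) {
  if (length(c_values) != length(trait_values)) rlang::abort("input lengths differ")
  keep <- is.finite(c_values) & is.finite(trait_values)
  c_values <- c_values[keep]
  trait_values <- trait_values[keep]
  if (length(c_values) < 3) rlang::abort("need at least 3 paired values")
  if (stats::sd(c_values) == 0 || stats::sd(trait_values) == 0) {
    rlang::abort("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(c_values, trait_values, method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    p.value = ct$p.value,
    n = length(c_values),
    paired = paired
  )
}
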