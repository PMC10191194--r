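#' Schema-validated delimited-table readers
#'
#' @description
#' Readers for the pipeline's interchange tables. All accept tab- or
#' comma-delimited text (the delimiter is auto-detected from the header
#' line), validate required columns by name and type, and preserve row
#' order. Lines starting with `#` are treated as comments.
#'
#' * `read_isotope_samples()`: `isolate`, `tissue`, `replicate`,
#'   `atom_pct_13c`.
#' * `read_colony_stats()`: `isolate`, `mean_biomass`, `mean_pct_c`.
#' * `read_growth_records()`: the raw growth schema of
#'   [derive_growth_traits()].
#' * `read_sample_metadata()`: `sample`, `condition`, `replicate`.
#' * `read_annotations()`: `transcript`, `annotation`.
#' * `read_counts()`: transcripts as rows (first column `transcript`),
#'   samples as remaining columns; returns an integer matrix.
#' * `read_gene_table()`: `transcript`, `organism`.
#'
#' @param path Path to a delimited text file.
#' @return A tibble (or integer matrix for `read_counts()`).
#' @name readers
NULL

detect_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

read_checked <- function(path, numeric_cols, character_cols, integer_cols = character(0)) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  tbl <- readr::read_delim(
    path,
    delim = detect_delim(path), comment = "#",
    show_col_types = FALSE, progress = FALSE, trim_ws = TRUE
  )
  required <- c(numeric_cols, character_cols, integer_cols)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      basename(path), ": missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c(numeric_cols, integer_cols)) {
    v <- tbl[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad)) {
        rlang::abort(sprintf(
          "%s: non-numeric value in column '%s', row %d: '%s'",
          basename(path), col, bad[1], v[bad[1]]
        ))
      }
      tbl[[col]] <- conv
    }
    if (col %in% integer_cols) tbl[[col]] <- as.integer(tbl[[col]])
  }
  for (col in character_cols) tbl[[col]] <- as.character(tbl[[col]])
  tbl
}

#' @rdname readers
#' @export
read_isotope_samples <- function(path) {
  tbl <- read_checked(path, "atom_pct_13c", c("isolate", "tissue", "replicate"))
  bad <- !tbl$tissue %in% c("ERM", "FLM", "leaf")
  if (any(bad)) {
    rlang::abort(paste0("unknown tissue role(s): ", paste(unique(tbl$tissue[bad]), collapse = ", ")))
  }
  tbl
}

#' @rdname readers
#' @export
read_colony_stats <- function(path) {
  read_checked(path, c("mean_biomass", "mean_pct_c"), "isolate")
}

#' @rdname readers
#' @export
read_growth_records <- function(path) {
  read_checked(
    path,
    numeric_cols = c(
      "biomass_mg", "colony_area_wk2", "colony_area_wk4", "agar_block_area",
      "hartig_depth_um", "mantle_thickness_um", "pct_c"
    ),
    character_cols = c("isolate", "replicate", "plate_type"),
    integer_cols = c("colonized_tips", "total_tips_in_contact")
  )
}

#' @rdname readers
#' @export
read_sample_metadata <- function(path) {
  read_checked(path, character(0), c("sample", "condition", "replicate"))
}

#' @rdname readers
#' @export
read_annotations <- function(path) {
  read_checked(path, character(0), c("transcript", "annotation"))
}

#' @rdname readers
#' @export
read_gene_table <- function(path) {
  read_checked(path, character(0), c("transcript", "organism"))
}

#' @rdname readers
#' @export
read_counts <- function(path) {
  tbl <- read_checked(path, character(0), "transcript")
  m <- as.matrix(tbl[setdiff(names(tbl), "transcript")])
  if (!is.numeric(m)) rlang::abort(paste0(basename(path), ": non-numeric counts"))
  if (any(m %% 1 != 0) || any(m < 0)) {
    rlang::abort(paste0(basename(path), ": counts must be non-negative integers"))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- tbl$transcript
  if (anyDuplicated(rownames(m))) rlang::abort("duplicate transcript IDs in counts")
  m
}

#' Write a tibble or count matrix as TSV
#'
#' @param x Tibble, data frame, or matrix (matrices are written with a
#'   leading `transcript` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- dplyr::bind_cols(
      tibble::tibble(transcript = rownames(x)),
      tibble::as_tibble(x)
    )
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline from input tables to output directory
#'
#' Orchestrates the three stages in study order -- isotope flux, growth
#' traits, expression screen -- from on-disk input tables, writing every
#' stage's result tables plus a machine-readable JSON manifest (package
#' version, options, input hashes, per-stage record counts). Reruns on
#' identical inputs produce identical outputs.
#'
#' @param isotope_samples,colony_stats,growth_records,counts,sample_metadata,gene_table,annotations
#'   Paths to the input tables (see the `read_*` readers for schemas).
#'   `annotations` may be `NULL` to skip category tallies.
#' @param out_dir Output directory (created if needed).
#' @param isotope_k IQR fence multiplier for the isotope stage.
#' @param leaf_pairing Passed to [carbon_flux()].
#' @param days Passed to [derive_growth_traits()].
#' @param screen_mode Passed to [correlation_screen()].
#' @param control Control condition label.
#' @return Invisibly, a list with the in-memory stage results
#'   (`flux`, `traits`, `screen`, `tally`) and the manifest.
#' @export
run_pipeline <- function(isotope_samples, colony_stats, growth_records,
                         counts, sample_metadata, gene_table,
                         annotations = NULL, out_dir,
                         isotope_k = 1.5, leaf_pairing = "plate",
                         days = 14, screen_mode = "replicate",
                         control = "control") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  flux <- stage("isotope_flux", {
    samples <- read_isotope_samples(isotope_samples)
    colonies <- read_colony_stats(colony_stats)
    carbon_flux(samples, colonies, k = isotope_k, leaf_pairing = leaf_pairing)
  })
  write_tsv_table(flux$replicates, file.path(out_dir, "carbon_replicates.tsv"))
  write_tsv_table(flux$isolates, file.path(out_dir, "carbon_isolates.tsv"))

  growth <- stage("growth_traits", {
    raw <- read_growth_records(growth_records)
    traits <- derive_growth_traits(raw, days = days)
    trait_means <- traits |>
      dplyr::group_by(.data$isolate) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)),
        .groups = "drop"
      )
    c_tbl <- dplyr::left_join(
      flux$isolates[c("isolate", "mean_c_symbiosis_mg")], trait_means,
      by = "isolate"
    )
    pca <- pca_traits(c_tbl)
    list(traits = traits, trait_means = trait_means, pca = pca)
  })
  write_tsv_table(growth$traits, file.path(out_dir, "growth_traits.tsv"))
  write_tsv_table(tidy(growth$pca, "eigenvalues"), file.path(out_dir, "pca_eigenvalues.tsv"))
  write_tsv_table(tidy(growth$pca, "loadings"), file.path(out_dir, "pca_loadings.tsv"))

  screen <- stage("expression_screen", {
    cts <- read_counts(counts)
    meta <- read_sample_metadata(sample_metadata)
    genes <- read_gene_table(gene_table)
    filt <- filter_expressed(cts, meta, genes)
    sf <- size_factors(filt$counts)
    norm <- normalize_counts(filt$counts, sf)
    org <- genes$organism[match(rownames(norm), genes$transcript)]
    per_org <- lapply(c(plant = "plant", fungus = "fungus"), function(o) {
      sub <- norm[org == o, , drop = FALSE]
      if (nrow(sub) < 100) return(NULL)
      correlation_screen(sub, meta, flux$isolates |>
        dplyr::select("isolate", "mean_c_symbiosis_mg"),
      mode = screen_mode, control = control
      )
    })
    list(filter_report = filt$report, size_factors = sf, screens = per_org)
  })
  write_tsv_table(screen$filter_report, file.path(out_dir, "filter_report.tsv"))
  write_tsv_table(
    tibble::tibble(sample = names(screen$size_factors), size_factor = screen$size_factors),
    file.path(out_dir, "size_factors.tsv")
  )
  for (org in names(screen$screens)) {
    if (!is.null(screen$screens[[org]])) {
      write_tsv_table(
        tidy(screen$screens[[org]]),
        file.path(out_dir, paste0("screen_", org, ".tsv"))
      )
    }
  }

  tally <- NULL
  if (!is.null(annotations)) {
    tally <- stage("category_tally", {
      ann <- read_annotations(annotations)
      purrr::imap_dfr(
        purrr::compact(screen$screens),
        ~ dplyr::mutate(category_tally(.x, ann), organism = .y, .before = 1)
      )
    })
    write_tsv_table(tally, file.path(out_dir, "category_tally.tsv"))
  }

  manifest <- list(
    package = "mycoflux",
    version = as.character(utils::packageVersion("mycoflux")),
    options = list(
      isotope_k = isotope_k, leaf_pairing = leaf_pairing, days = days,
      screen_mode = screen_mode, control = control
    ),
    inputs = lapply(
      purrr::compact(list(
        isotope_samples = isotope_samples, colony_stats = colony_stats,
        growth_records = growth_records, counts = counts,
        sample_metadata = sample_metadata, gene_table = gene_table,
        annotations = annotations
      )),
      function(p) unname(tools::md5sum(p))
    ),
    stage_counts = list(
      isotope_replicates = nrow(flux$replicates),
      isotope_outliers_removed = nrow(flux$removed),
      transcripts_kept = sum(screen$filter_report$kept),
      transcripts_removed = sum(screen$filter_report$removed)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    flux = flux, growth = growth, screen = screen, tally = tally,
    manifest = manifest
  ))
}
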