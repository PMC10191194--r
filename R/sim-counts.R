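#' Simulate a transcripts-by-samples count matrix with planted C-responsive genes
#'
#' Draws negative-binomial read counts for plant and fungal transcripts
#' across isolate conditions (plus an uninoculated plant control) with
#' per-sample library-size factors, and plants two sets of transcripts per
#' organism whose log mean expression is linearly tied to the standardized
#' per-isolate carbon acquisition: positives with slope `planted_effect`,
#' negatives with slope `-planted_effect`. These planted sets are the
#' recoverable ground truth for the Pearson percentile screen.
#'
#' Base means are log-normal; a tenth of transcripts per organism are drawn
#' with very low means so that the expression filter has genuine work to do.
#' Fungal transcripts have zero counts in control samples (no fungus on
#' control plates).
#'
#' @param cfg A [sim_config()] object.
#' @param true_c Per-isolate carbon acquisition (mg C) driving the planted
#'   transcripts; defaults to the isotope generator's default truth shape
#'   (an increasing gradient across isolates).
#' @return A list of class `counts_sim`:
#'   \describe{
#'     \item{counts}{integer matrix, transcripts x samples.}
#'     \item{meta}{tibble: `sample`, `condition`, `replicate`.}
#'     \item{genes}{tibble: `transcript`, `organism` ("plant"/"fungus").}
#'     \item{truth}{list: `true_c`, `planted_pos_ids`, `planted_neg_ids`,
#'       `true_size_factors` (rescaled to geometric mean 1, the scale on
#'       which median-of-ratios factors are identified).}
#'   }
#' @examples
#' cs <- sim_counts(sim_config(n_plant_transcripts = 200, n_fungal_transcripts = 100))
#' dim(cs$counts)
#' @export
sim_counts <- function(cfg, true_c = NULL) {
  stopifnot(inherits(cfg, "mycoflux_config"))
  isolates <- default_isolate_labels(cfg$n_isolates)
  old <- .Random.seed_exists()
  set.seed(stream_seed(cfg$seed, "counts"))
  on.exit(.restore_seed(old), add = TRUE)

  if (is.null(true_c)) {
    true_c <- seq(0.05, 0.45, length.out = cfg$n_isolates)
  }
  stopifnot(length(true_c) == cfg$n_isolates)
  names(true_c) <- isolates
  z <- as.numeric(scale(true_c))
  if (any(!is.finite(z))) z <- rep(0, length(true_c)) # constant truth

  conditions <- c(isolates, "control")
  reps <- cfg$n_transcriptome_reps
  meta <- tibble::tibble(
    condition = rep(conditions, each = reps),
    replicate = rep(sprintf("r%d", seq_len(reps)), times = length(conditions))
  ) |>
    dplyr::mutate(sample = sprintf("s%02d", dplyr::row_number())) |>
    dplyr::select("sample", "condition", "replicate")

  gene_ids <- function(prefix, n) sprintf("%s%05d", prefix, seq_len(n))
  genes <- tibble::tibble(
    transcript = c(
      gene_ids("PT", cfg$n_plant_transcripts),
      gene_ids("FT", cfg$n_fungal_transcripts)
    ),
    organism = rep(c("plant", "fungus"),
      c(cfg$n_plant_transcripts, cfg$n_fungal_transcripts)
    )
  )

  n_samples <- nrow(meta)
  sf <- stats::runif(n_samples, cfg$size_factor_range[1], cfg$size_factor_range[2])
  sf <- sf / exp(mean(log(sf))) # identifiable scale: geometric mean 1
  names(sf) <- meta$sample

  base_means <- function(n) {
    mu <- stats::rlnorm(n, meanlog = log(100), sdlog = 1.2)
    n_low <- floor(n / 10)
    if (n_low > 0) mu[sample.int(n, n_low)] <- stats::runif(n_low, 0.05, 3)
    mu
  }

  pick_planted <- function(org_ids, mu) {
    # planted genes need a solid base mean so the signal is not lost to
    # count quantization
    eligible <- which(mu >= 20)
    need <- cfg$n_planted_pos + cfg$n_planted_neg
    if (length(eligible) < need) eligible <- order(mu, decreasing = TRUE)[seq_len(need)]
    chosen <- sample(eligible, need)
    list(
      pos = org_ids[chosen[seq_len(cfg$n_planted_pos)]],
      neg = org_ids[chosen[cfg$n_planted_pos + seq_len(cfg$n_planted_neg)]]
    )
  }

  cond_of <- meta$condition
  z_by_sample <- ifelse(cond_of == "control", 0, z[match(cond_of, isolates)])

  draw_counts <- function(mu_mat) {
    n <- length(mu_mat)
    if (cfg$nb_dispersion == 0) {
      matrix(stats::rpois(n, mu_mat), nrow = nrow(mu_mat))
    } else {
      matrix(stats::rnbinom(n, mu = mu_mat, size = 1 / cfg$nb_dispersion),
        nrow = nrow(mu_mat)
      )
    }
  }

  simulate_organism <- function(org) {
    org_ids <- genes$transcript[genes$organism == org]
    n_g <- length(org_ids)
    mu0 <- base_means(n_g)
    planted <- pick_planted(org_ids, mu0)
    slope <- numeric(n_g)
    slope[match(planted$pos, org_ids)] <- cfg$planted_effect
    slope[match(planted$neg, org_ids)] <- -cfg$planted_effect
    # log-mean linear in standardized C per sample; control sits at base
    mu <- outer(mu0, rep(1, n_samples)) * exp(outer(slope, z_by_sample))
    mu <- sweep(mu, 2, sf, `*`)
    cts <- draw_counts(mu)
    if (org == "fungus") cts[, cond_of == "control"] <- 0L
    rownames(cts) <- org_ids
    list(counts = cts, planted = planted)
  }

  plant <- simulate_organism("plant")
  fungus <- simulate_organism("fungus")
  counts <- rbind(plant$counts, fungus$counts)
  colnames(counts) <- meta$sample
  storage.mode(counts) <- "integer"

  structure(
    list(
      counts = counts,
      meta = meta,
      genes = genes,
      truth = list(
        true_c = true_c,
        planted_pos_ids = c(plant$planted$pos, fungus$planted$pos),
        planted_neg_ids = c(plant$planted$neg, fungus$planted$neg),
        true_size_factors = sf
      )
    ),
    class = "counts_sim"
  )
}

#' Simulate free-text functional annotations for transcripts
#'
#' Assigns each transcript a short annotation string drawn from the default
#' functional-category keyword lexicon (see [carbon_category_lexicon()]) or
#' an uninformative filler, so that category tallies on synthetic screens
#' have a known composition.
#'
#' @param transcripts Character vector of transcript IDs.
#' @param prop_categorized Fraction of transcripts given an annotation
#'   containing a category keyword.
#' @param seed RNG seed.
#' @return Tibble: `transcript`, `annotation`.
#' @export
sim_annotations <- function(transcripts, prop_categorized = 0.5, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(stream_seed(seed, "annotations"))
  on.exit(.restore_seed(old), add = TRUE)
  lex <- carbon_category_lexicon()
  keywords <- unlist(lex, use.names = FALSE)
  fillers <- c(
    "hypothetical protein", "protein of unknown function",
    "ribosomal protein L7", "ATP synthase subunit", "tubulin alpha chain"
  )
  n <- length(transcripts)
  use_kw <- stats::runif(n) < prop_categorized
  ann <- ifelse(
    use_kw,
    paste("putative", sample(keywords, n, replace = TRUE), "protein"),
    sample(fillers, n, replace = TRUE)
  )
  tibble::tibble(transcript = transcripts, annotation = ann)
}
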