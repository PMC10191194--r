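#' Filter transcripts expressed under at least one condition
#'
#' Keeps a transcript iff its mean raw count within at least one condition
#' reaches the organism's threshold: 10 reads for plant transcripts and 5
#' for fungal transcripts by default. Transcripts below the threshold in
#' every condition are "not expressed under any condition" and removed
#' before normalization.
#'
#' @param counts Integer matrix, transcripts x samples (rownames =
#'   transcript IDs, colnames = sample IDs).
#' @param meta Tibble with columns `sample`, `condition` covering every
#'   column of `counts`.
#' @param genes Tibble with columns `transcript`, `organism` ("plant" or
#'   "fungus") covering every row of `counts`.
#' @param plant_min,fungal_min Mean-count thresholds per organism.
#' @return List: `counts` (the filtered matrix) and `report` (tibble of
#'   per-organism kept/removed totals).
#' @examples
#' cs <- sim_counts(sim_config(n_plant_transcripts = 200, n_fungal_transcripts = 100))
#' filt <- filter_expressed(cs$counts, cs$meta, cs$genes)
#' filt$report
#' @export
filter_expressed <- function(counts, meta, genes, plant_min = 10, fungal_min = 5) {
  stopifnot(plant_min > 0, fungal_min > 0)
  check_counts_meta(counts, meta)
  untagged <- setdiff(rownames(counts), genes$transcript)
  if (length(untagged)) {
    rlang::abort(paste0(
      "transcript(s) without an organism tag, e.g.: ",
      paste(utils::head(untagged, 3), collapse = ", ")
    ))
  }
  organism <- genes$organism[match(rownames(counts), genes$transcript)]
  if (!all(organism %in% c("plant", "fungus"))) {
    rlang::abort('organism must be "plant" or "fungus"')
  }

  cond <- meta$condition[match(colnames(counts), meta$sample)]
  cond_means <- condition_means(counts, cond)
  max_mean <- apply(cond_means, 1, max)
  threshold <- ifelse(organism == "plant", plant_min, fungal_min)
  keep <- max_mean >= threshold

  report <- tibble::tibble(organism = organism, keep = keep) |>
    dplyr::count(.data$organism, .data$keep) |>
    tidyr::pivot_wider(
      names_from = "keep", values_from = "n", values_fill = 0L,
      names_prefix = "k"
    ) |>
    dplyr::rename_with(~ c(kTRUE = "kept", kFALSE = "removed")[.x], dplyr::any_of(c("kTRUE", "kFALSE")))
  for (col in c("kept", "removed")) if (!col %in% names(report)) report[[col]] <- 0L

  list(counts = counts[keep, , drop = FALSE], report = report[c("organism", "kept", "removed")])
}

condition_means <- function(counts, cond) {
  conds <- unique(cond)
  out <- vapply(
    conds,
    function(cc) rowMeans(counts[, cond == cc, drop = FALSE]),
    numeric(nrow(counts))
  )
  if (nrow(counts) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(counts), conds))
  out
}

check_counts_meta <- function(counts, meta) {
  if (!is.matrix(counts)) rlang::abort("counts must be a matrix")
  if (any(counts < 0)) rlang::abort("counts must be non-negative")
  if (anyDuplicated(rownames(counts))) rlang::abort("duplicate transcript IDs")
  missing_meta <- setdiff(colnames(counts), meta$sample)
  if (length(missing_meta)) {
    rlang::abort(paste0("sample(s) absent from metadata: ", paste(missing_meta, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Median-of-ratios size factors
#'
#' The library-size normalization estimator: per transcript, the geometric
#' mean of its counts across samples (over transcripts with all counts
#' positive, the reference set); per sample, the median over that
#' reference set of the count / geometric-mean ratios. Dividing each
#' sample's counts by its factor equalizes library depth without letting a
#' few highly expressed transcripts dominate, the property that
#' distinguishes this estimator from total-count scaling.
#'
#' @param counts Non-negative matrix, transcripts x samples.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' m <- cbind(s1 = c(2, 4, 6), s2 = c(4, 8, 12))
#' size_factors(m) # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) rlang::abort("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    rlang::abort(paste0(
      "no transcript has positive counts in every sample; ",
      "the reference set is empty (is the expression filter too weak?)"
    ))
  }
  logc <- log(counts[ref, , drop = FALSE])
  log_geomean <- rowMeans(logc)
  factors <- apply(logc, 2, function(col) exp(stats::median(col - log_geomean)))
  stats::setNames(factors, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts Matrix of raw counts.
#' @param factors Per-sample size factors from [size_factors()]; computed
#'   from `counts` when omitted.
#' @return Matrix of normalized counts (`counts` divided column-wise).
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  stopifnot(ncol(counts) == length(factors), all(factors > 0))
  sweep(counts, 2, factors, `/`)
}

#' Log2 fold-change matrix relative to the cross-isolate baseline
#'
#' For each transcript: the mean normalized count per condition divided by
#' the baseline (the average of the isolate-condition means, excluding the
#' uninoculated control), log2-transformed. The control column, if present,
#' is reported against the same baseline. When a transcript has a zero
#' condition mean, a pseudocount is added to both numerator and denominator
#' for that transcript only, leaving typical transcripts untouched.
#'
#' @param norm_counts Normalized count matrix, transcripts x samples.
#' @param meta Tibble with `sample`, `condition`.
#' @param transcripts Transcript IDs to include (default: all rows).
#' @param control Condition label excluded from the baseline (set `NULL` if
#'   there is none).
#' @param pseudocount Value added to means of zero-containing rows; 0
#'   disables the rescue, in which case a zero baseline is an error.
#' @return Numeric matrix, transcripts x conditions (control last), of
#'   log2 fold changes.
#' @examples
#' cs <- sim_counts(sim_config(n_plant_transcripts = 200, n_fungal_transcripts = 100))
#' fc <- foldchange_matrix(normalize_counts(cs$counts), cs$meta)
#' fc[1:3, ]
#' @export
foldchange_matrix <- function(norm_counts, meta, transcripts = NULL,
                              control = "control", pseudocount = 1) {
  check_counts_meta(norm_counts, meta)
  if (is.null(transcripts)) transcripts <- rownames(norm_counts)
  missing_tx <- setdiff(transcripts, rownames(norm_counts))
  if (length(missing_tx)) {
    rlang::abort(paste0("transcript(s) not in matrix: ", paste(utils::head(missing_tx, 3), collapse = ", ")))
  }
  m <- norm_counts[transcripts, , drop = FALSE]
  cond <- meta$condition[match(colnames(m), meta$sample)]
  cm <- condition_means(m, cond)
  iso_conds <- setdiff(colnames(cm), control)
  if (length(iso_conds) < 2) rlang::abort("need at least 2 isolate conditions")
  cm <- cm[, c(iso_conds, intersect(control, colnames(cm))), drop = FALSE]

  baseline <- rowMeans(cm[, iso_conds, drop = FALSE])
  has_zero <- apply(cm == 0, 1, any) | baseline == 0
  if (pseudocount <= 0 && any(baseline == 0)) {
    rlang::abort("zero baseline with no pseudocount; set pseudocount > 0")
  }
  eps <- ifelse(has_zero, pseudocount, 0)
  log2((cm + eps) / (baseline + eps))
}

#' Dendrogram leaf order from hierarchical clustering
#'
#' Agglomerative clustering of matrix rows (or columns) on Euclidean
#' distance with average linkage by default; ties are broken by input
#' order, so the permutation is deterministic.
#'
#' @param mat Numeric matrix with no non-finite entries.
#' @param axis Cluster `"rows"` or `"cols"`.
#' @param linkage Agglomeration method, `"average"` (default) or
#'   `"complete"`.
#' @return Integer permutation of row (or column) indices: the dendrogram
#'   leaf order.
#' @examples
#' cluster_order(rbind(a = c(0, 0), b = c(10, 10), c = c(0.1, 0)))
#' @export
cluster_order <- function(mat, axis = c("rows", "cols"), linkage = c("average", "complete")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  if (axis == "cols") mat <- t(mat)
  if (nrow(mat) < 2) rlang::abort("need at least 2 rows to cluster")
  if (any(!is.finite(mat))) rlang::abort("matrix contains non-finite values")
  stats::hclust(stats::dist(mat, method = "euclidean"), method = linkage)$order
}

#' Select the top and bottom percentiles of correlation values
#'
#' Selection by count: the top set holds the `m = ceiling(0.01 * n)`
#' largest values (equivalently `n - floor(0.99 * n)`), the bottom set the
#' `m` smallest; for 24,615 values that is 247 per tail and for 12,959 it
#' is 130. The reported thresholds are the smallest selected top value
#' (q0.99) and the largest selected bottom value (q0.01). Ties are broken
#' by position (transcript ID order).
#'
#' @param r_values Named (or unnamed) numeric vector of n >= 100
#'   correlation values.
#' @return List: `top`, `bottom` (integer indices, also named if
#'   `r_values` is), `q99`, `q01`, `m`.
#' @examples
#' sel <- select_percentiles(stats::setNames(seq(-1, 1, length.out = 200), paste0("t", 1:200)))
#' sel$m
#' @export
select_percentiles <- function(r_values) {
  n <- length(r_values)
  if (n < 100) rlang::abort("need at least 100 values for a 1% tail")
  if (any(!is.finite(r_values))) rlang::abort("non-finite correlation values")
  m <- ceiling(0.01 * n)
  ord_desc <- order(r_values, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  ord_asc <- order(r_values, seq_len(n), method = "radix")
  top <- sort(ord_desc[seq_len(m)])
  bottom <- sort(ord_asc[seq_len(m)])
  if (!is.null(names(r_values))) {
    top <- stats::setNames(top, names(r_values)[top])
    bottom <- stats::setNames(bottom, names(r_values)[bottom])
  }
  list(
    top = top, bottom = bottom,
    q99 = min(r_values[top]), q01 = max(r_values[bottom]), m = m
  )
}

#' Two-tailed critical value of Pearson's r
#'
#' Inverts the t statistic of the correlation test: with `t*` the
#' `1 - alpha/2` quantile of Student's t on `n - 2` degrees of freedom,
#' `r_crit = t* / sqrt(t*^2 + n - 2)`. An observed correlation is
#' significant at level `alpha` iff `|r| >= r_crit`, reproducing the
#' standard table of critical values.
#'
#' @param n Sample size (>= 3); vectorized.
#' @param alpha Two-tailed significance level.
#' @return Critical |r|.
#' @examples
#' pearson_critical_value(9) # about 0.666
#' @export
pearson_critical_value <- function(n, alpha = 0.05) {
  if (any(n < 3)) rlang::abort("need n >= 3")
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Pearson percentile screen of transcripts against carbon acquisition
#'
#' For every transcript, computes Pearson's r between its normalized counts
#' and the per-isolate mean carbon acquisition, then selects the top and
#' bottom percentiles and flags significance against the critical value at
#' the effective sample size. The uninoculated control condition is
#' excluded (it has no C value).
#'
#' In `"replicate"` mode each sample is paired with its isolate's mean C
#' value (n = isolates x replicates, using all count data); in
#' `"averaged"` mode condition-mean counts are paired with the C means
#' (n = isolates).
#'
#' @param norm_counts Normalized count matrix, transcripts x samples.
#' @param meta Tibble with `sample`, `condition`.
#' @param c_table Tibble with `isolate`, `mean_c_symbiosis_mg` (e.g.
#'   `glance()` of a [carbon_flux()] fit), or a named numeric vector of
#'   per-isolate C values.
#' @param mode `"replicate"` (default) or `"averaged"`.
#' @param alpha Significance level for the critical-value flag.
#' @param control Condition label to exclude.
#' @return Object of class `correlation_screen`: list with `result`
#'   (tibble: `transcript`, `pearson_r`, `selected` in
#'   \{"top","bottom","none"\}, `significant`, `zero_variance`), `q99`,
#'   `q01`, `m`, `n_eff`, `r_crit`, `mode`. `tidy()` returns the result
#'   tibble.
#' @examples
#' cs <- sim_counts(sim_config(n_plant_transcripts = 300, n_fungal_transcripts = 150))
#' scr <- correlation_screen(normalize_counts(cs$counts), cs$meta, cs$truth$true_c)
#' scr$q99
#' @export
correlation_screen <- function(norm_counts, meta, c_table,
                               mode = c("replicate", "averaged"),
                               alpha = 0.05, control = "control") {
  mode <- match.arg(mode)
  check_counts_meta(norm_counts, meta)
  if (is.data.frame(c_table)) {
    c_col <- intersect(c("mean_c_symbiosis_mg", "c_symbiosis_mg", "c_value"), names(c_table))
    if (!length(c_col) || !"isolate" %in% names(c_table)) {
      rlang::abort("c_table needs columns isolate and mean_c_symbiosis_mg")
    }
    c_values <- stats::setNames(c_table[[c_col[1]]], c_table$isolate)
  } else {
    c_values <- c_table
  }

  cond <- meta$condition[match(colnames(norm_counts), meta$sample)]
  keep <- cond != control
  m <- norm_counts[, keep, drop = FALSE]
  cond <- cond[keep]
  missing_c <- setdiff(unique(cond), names(c_values))
  if (length(missing_c)) {
    rlang::abort(paste0("no C value for condition(s): ", paste(missing_c, collapse = ", ")))
  }

  if (mode == "averaged") {
    m <- condition_means(m, cond)
    y <- c_values[colnames(m)]
  } else {
    y <- c_values[cond]
  }
  n_eff <- ncol(m)
  if (n_eff < 3) rlang::abort("need at least 3 screening samples")

  row_sd <- apply(m, 1, stats::sd)
  zero_var <- row_sd == 0
  r <- rep(0, nrow(m))
  if (any(!zero_var)) {
    r[!zero_var] <- as.numeric(stats::cor(t(m[!zero_var, , drop = FALSE]), y))
  }
  names(r) <- rownames(m)

  r_crit <- pearson_critical_value(n_eff, alpha)
  # zero-variance transcripts stay in the ranking vector at r = 0 but are
  # never eligible for selection
  r_rank <- r
  r_rank[zero_var] <- 0
  sel <- select_percentiles_excluding(r_rank, exclude = zero_var)

  selected <- rep("none", length(r))
  selected[sel$top] <- "top"
  selected[sel$bottom] <- "bottom"

  result <- tibble::tibble(
    transcript = rownames(m),
    pearson_r = unname(r),
    selected = selected,
    significant = abs(r) >= r_crit & !zero_var,
    zero_variance = zero_var
  )
  structure(
    list(
      result = result, q99 = sel$q99, q01 = sel$q01, m = sel$m,
      n_eff = n_eff, r_crit = r_crit, mode = mode, alpha = alpha
    ),
    class = "correlation_screen"
  )
}

select_percentiles_excluding <- function(r_values, exclude) {
  if (!any(exclude)) return(select_percentiles(r_values))
  n <- length(r_values)
  if (n < 100) rlang::abort("need at least 100 values for a 1% tail")
  m <- ceiling(0.01 * n)
  idx <- which(!exclude)
  sub <- r_values[idx]
  if (length(sub) < m) rlang::abort("fewer eligible transcripts than the tail size")
  ord_desc <- order(sub, seq_along(sub), decreasing = c(TRUE, FALSE), method = "radix")
  ord_asc <- order(sub, seq_along(sub), method = "radix")
  top <- sort(idx[ord_desc[seq_len(m)]])
  bottom <- sort(idx[ord_asc[seq_len(m)]])
  list(
    top = top, bottom = bottom,
    q99 = min(r_values[top]), q01 = max(r_values[bottom]), m = m
  )
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf(
    "<correlation_screen> %d transcripts, %s mode (n = %d)\n  %d per tail; q0.99 = %.3f, q0.01 = %.3f; |r| critical = %.3f\n",
    nrow(x$result), x$mode, x$n_eff, x$m, x$q99, x$q01, x$r_crit
  ))
  invisible(x)
}

#' @rdname correlation_screen
#' @param x A `correlation_screen` object.
#' @param ... Unused.
#' @method tidy correlation_screen
#' @export
tidy.correlation_screen <- function(x, ...) x$result

#' @rdname correlation_screen
#' @method glance correlation_screen
#' @export
glance.correlation_screen <- function(x, ...) {
  tibble::tibble(
    n_transcripts = nrow(x$result), m_per_tail = x$m, q99 = x$q99,
    q01 = x$q01, n_eff = x$n_eff, r_crit = x$r_crit, mode = x$mode
  )
}

#' Default functional-category keyword lexicon
#'
#' Case-insensitive keyword lists mapping free-text functional annotations
#' to the carbon-related categories tallied for screened transcript sets:
#' carbohydrate biosynthesis, defence/disease resistance, growth/cell
#' cycle regulation, host-fungus interaction, sugar/carbohydrate
#' catabolism, signal transduction, stress response, transcription
#' regulation, and transporters. The keyword choices are this package's
#' own; edit or replace the list to change the vocabulary.
#'
#' @return Named list of character keyword vectors.
#' @export
carbon_category_lexicon <- function() {
  list(
    "Carbohydrate biosynthesis" = c(
      "galactinol synthase", "glycogen synthase", "trehalose-6-phosphate synthase",
      "sucrose synthase", "starch synthase", "cellulose synthase", "sugar biosynthesis"
    ),
    "Defence/disease resistance" = c(
      "disease resistance", "nb-arc", "lrr", "laccase", "u-box", "defensin",
      "pathogenesis-related", "resistance protein"
    ),
    "Growth/cell cycle regulation" = c(
      "cell cycle", "cyclin", "cell division", "f-box", "growth regulat"
    ),
    "Host-fungus interaction" = c(
      "effector", "symbiosis", "mycorrhiza", "host interaction"
    ),
    "Sugar/carbohydrate catabolism" = c(
      "fructokinase", "hexokinase", "glucosidase", "trehalase", "invertase",
      "glycoside hydrolase", "phosphoglucose isomerase", "glycolysis", "amylase"
    ),
    "Signal transduction" = c(
      "kinase", "phosphatase", "signal transduction", "g-protein", "calmodulin",
      "receptor-like"
    ),
    "Stress response" = c(
      "stress", "heat shock", "hsp", "peroxidase", "dehydrin",
      "late embryogenesis"
    ),
    "Transcription regulation" = c(
      "transcription factor", "zinc finger", "myb", "bzip", "wrky", "homeobox",
      "methyltransferase", "pentatricopeptide", "tetratricopeptide", "ubiquitin"
    ),
    "Transporter" = c(
      "transporter", "permease", "major facilitator", "abc transporter",
      "sweet", "aquaporin", "channel"
    )
  )
}

#' Tally functional categories among selected transcripts
#'
#' For each selected set (top / bottom percentile) and each category of the
#' keyword lexicon, the percentage of transcripts whose annotation matches
#' at least one keyword (case-insensitive substring). A transcript may
#' match several categories; transcripts without an annotation are counted
#' as uncategorized with a warning.
#'
#' @param screen A `correlation_screen` object or its tidied result tibble.
#' @param annotations Tibble with `transcript`, `annotation`.
#' @param lexicon Named list of keyword vectors; see
#'   [carbon_category_lexicon()].
#' @param digits Rounding applied to the reported percentages (0 for
#'   report-style integers).
#' @return Tibble: `category`, `pct_top`, `pct_bottom`, `pct_all` (the
#'   percentage over both sets combined).
#' @export
category_tally <- function(screen, annotations,
                           lexicon = carbon_category_lexicon(), digits = 0) {
  result <- if (inherits(screen, "correlation_screen")) screen$result else screen
  stopifnot(all(c("transcript", "selected") %in% names(result)))
  sel <- dplyr::filter(result, .data$selected != "none")
  if (nrow(sel) == 0) {
    rlang::warn("no selected transcripts; all category percentages are 0")
    return(tibble::tibble(
      category = names(lexicon), pct_top = 0, pct_bottom = 0, pct_all = 0
    ))
  }
  ann <- annotations$annotation[match(sel$transcript, annotations$transcript)]
  n_missing <- sum(is.na(ann))
  if (n_missing > 0) {
    rlang::warn(sprintf("%d selected transcript(s) lack annotations; counted as uncategorized", n_missing))
    ann[is.na(ann)] <- ""
  }
  ann <- tolower(ann)

  match_category <- function(keywords) {
    hits <- rep(FALSE, length(ann))
    for (kw in tolower(keywords)) hits <- hits | grepl(kw, ann, fixed = TRUE)
    hits
  }
  pct <- function(hits, set) {
    n <- sum(set)
    if (n == 0) return(0)
    round(100 * sum(hits & set) / n, digits)
  }
  is_top <- sel$selected == "top"
  purrr::map_dfr(names(lexicon), function(cat) {
    hits <- match_category(lexicon[[cat]])
    tibble::tibble(
      category = cat,
      pct_top = pct(hits, is_top),
      pct_bottom = pct(hits, !is_top),
      pct_all = pct(hits, rep(TRUE, length(hits)))
    )
  })
}

#' Flag transcripts whose expression is extreme in one condition
#'
#' Marks transcripts for which a chosen condition attains the row maximum
#' or row minimum across isolate conditions of a fold-change (or
#' expression) matrix -- the "genes of interest" rule for a condition known
#' to receive the most host carbon.
#'
#' @param mat Numeric matrix, transcripts x conditions.
#' @param condition Column name of the condition of interest.
#' @param exclude Column names ignored when ranking (e.g. the uninoculated
#'   control).
#' @return Tibble: `transcript`, `direction` ("highest"/"lowest"/"none").
#' @export
flag_extreme_condition <- function(mat, condition, exclude = "control") {
  conds <- setdiff(colnames(mat), exclude)
  if (!condition %in% conds) rlang::abort(paste0("condition not in matrix: ", condition))
  sub <- mat[, conds, drop = FALSE]
  hi <- sub[, condition] == apply(sub, 1, max)
  lo <- sub[, condition] == apply(sub, 1, min)
  tibble::tibble(
    transcript = rownames(mat),
    direction = dplyr::case_when(hi ~ "highest", lo ~ "lowest", TRUE ~ "none")
  )
}
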