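make_meta <- function(counts) {
  tibble::tibble(
    sample = colnames(counts),
    condition = sub("_r\\d+$", "", colnames(counts)),
    replicate = sub("^.*_(r\\d+)$", "\\1", colnames(counts))
  )
}

test_that("expression filter keeps transcripts reaching a threshold in one condition", {
  # 2 conditions x 2 reps; hand-evaluated means
  counts <- rbind(
    p_hi = c(10, 10, 0, 0), #  means 10, 0  -> kept (boundary)
    p_lo = c(9, 10, 9, 10), #  means 9.5    -> removed
    p_one = c(0, 0, 12, 10), # means 0, 11  -> kept
    f_hi = c(5, 5, 0, 0), #    means 5, 0   -> kept (fungal threshold 5)
    f_lo = c(4, 5, 4, 4), #    means 4.5, 4 -> removed
    f_mid = c(9, 9, 1, 1) #    means 9, 1   -> kept
  )
  colnames(counts) <- c("c1_r1", "c1_r2", "c2_r1", "c2_r2")
  meta <- make_meta(counts)
  genes <- tibble::tibble(
    transcript = rownames(counts),
    organism = c("plant", "plant", "plant", "fungus", "fungus", "fungus")
  )
  filt <- filter_expressed(counts, meta, genes)
  expect_setequal(rownames(filt$counts), c("p_hi", "p_one", "f_hi", "f_mid"))
  expect_equal(sum(filt$report$removed), 2L)
  # missing organism tag errors
  expect_error(filter_expressed(counts, meta, genes[-1, ]), "organism tag")
})

test_that("median-of-ratios size factors match the hand example and are equivariant", {
  m <- cbind(s1 = c(2, 4, 6), s2 = c(4, 8, 12))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  norm <- normalize_counts(m, sf)
  expect_equal(norm[, "s1"], norm[, "s2"]) # equalized across samples

  # identical samples -> all factors 1
  m2 <- cbind(a = c(3, 7, 1), b = c(3, 7, 1), c = c(3, 7, 1))
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))

  # scale equivariance: scaling one sample by c scales its factor by c,
  # relative to the other samples (factors are identified up to a constant)
  m3 <- matrix(rpois(300, 50) + 1, ncol = 3)
  colnames(m3) <- c("x", "y", "z")
  sf3 <- size_factors(m3)
  m3b <- m3
  m3b[, "y"] <- m3[, "y"] * 5
  sfb <- size_factors(m3b)
  expect_equal(sfb[["y"]] / sfb[["x"]], 5 * sf3[["y"]] / sf3[["x"]], tolerance = 1e-12)
  expect_equal(sfb[["z"]] / sfb[["x"]], sf3[["z"]] / sf3[["x"]], tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "reference set")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  m <- matrix(stats::rnbinom(200 * 6, mu = 80, size = 10), ncol = 6) + 1L
  colnames(m) <- paste0("s", 1:6)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("fold-change matrix uses the cross-isolate baseline", {
  # 3 isolate conditions, 1 rep each, plus control
  counts <- rbind(
    uniform = c(8, 8, 8, 8),
    up_in_a = c(4, 2, 2, 1), # baseline over isolates = mean(4,2,2) = 8/3
    zero_in_a = c(0, 6, 6, 3)
  )
  colnames(counts) <- c("a_r1", "b_r1", "c_r1", "control_r1")
  meta <- make_meta(counts)
  fc <- foldchange_matrix(counts, meta, control = "control")
  expect_equal(unname(fc["uniform", c("a", "b", "c")]), c(0, 0, 0))
  # hand arithmetic: baseline = (4+2+2)/3 = 8/3
  expect_equal(unname(fc["up_in_a", "a"]), log2(4 / (8 / 3)))
  expect_equal(unname(fc["uniform", "control"]), 0)
  # pseudocount applies only to rows with a zero condition mean
  base <- mean(c(0, 6, 6))
  expect_equal(unname(fc["zero_in_a", "a"]), log2((0 + 1) / (base + 1)))
  expect_equal(unname(fc["up_in_a", "b"]), log2(2 / (8 / 3))) # untouched row
  # a doubling fixture: one condition at 2x the overall mean
  counts2 <- rbind(g = c(4, 1, 1))
  colnames(counts2) <- c("a_r1", "b_r1", "c_r1")
  fc2 <- foldchange_matrix(counts2, make_meta(counts2), control = NULL)
  expect_equal(unname(fc2["g", "a"]), 1) # 4 / mean(4,1,1)=2 -> log2 = 1
  # zero baseline without pseudocount errors
  counts3 <- rbind(g = c(0, 0, 0, 5))
  colnames(counts3) <- c("a_r1", "b_r1", "c_r1", "control_r1")
  expect_error(foldchange_matrix(counts3, make_meta(counts3), pseudocount = 0), "pseudocount")
})

test_that("cluster order puts similar rows together and is a bijection", {
  m <- rbind(a = c(0, 0, 0), b = c(10, 10, 10), c = c(0.2, 0, 0), d = c(9.8, 10, 10))
  ord <- cluster_order(m)
  expect_setequal(ord, 1:4)
  pos <- match(1:4, ord)
  expect_equal(abs(pos[1] - pos[3]), 1) # a next to c
  expect_equal(abs(pos[2] - pos[4]), 1) # b next to d
  # 3-row fixture: distant row is outside the tight pair
  m2 <- rbind(x = c(0, 0), y = c(0.1, 0), z = c(50, 50))
  ord2 <- cluster_order(m2)
  expect_true(match(3, ord2) %in% c(1, 3))
  expect_error(cluster_order(rbind(c(1, NA), c(2, 3))), "non-finite")
  expect_error(cluster_order(m[1, , drop = FALSE]), "at least 2")
})

test_that("percentile selection count follows the ceiling rule", {
  # the two study set sizes
  set.seed(3)
  r1 <- stats::rnorm(24615)
  expect_equal(select_percentiles(r1)$m, 247)
  expect_equal(select_percentiles(stats::rnorm(12959))$m, 130)
  expect_equal(select_percentiles(stats::rnorm(100))$m, 1)
  expect_error(select_percentiles(stats::rnorm(99)), "at least 100")

  # brute-force sort oracle across a range of n
  for (n in c(100, 101, 199, 1000, 2501, 12959, 24615)) {
    r <- stats::rnorm(n)
    sel <- select_percentiles(r)
    oracle <- brute_top_bottom(r)
    expect_equal(sel$m, oracle$m)
    expect_equal(unname(sel$top), oracle$top)
    expect_equal(unname(sel$bottom), oracle$bottom)
    expect_equal(sel$q99, min(r[oracle$top]))
    expect_equal(sel$q01, max(r[oracle$bottom]))
  }
})

test_that("percentile selection breaks ties by position", {
  r <- c(rep(1, 5), seq(0, 0.9, length.out = 195))
  names(r) <- sprintf("t%03d", seq_along(r))
  sel <- select_percentiles(r) # m = 2; five tied maxima
  expect_equal(names(sel$top), c("t001", "t002"))
})

test_that("critical value inverts the t quantile and decreases with n", {
  expect_equal(pearson_critical_value(9), 0.666, tolerance = 1e-3) # published table value
  # consistency with cor.test: r at the critical value has p = alpha
  r <- pearson_critical_value(20, 0.05)
  tstat <- r * sqrt(18) / sqrt(1 - r^2)
  expect_equal(2 * stats::pt(-tstat, 18), 0.05, tolerance = 1e-10)
  expect_lt(pearson_critical_value(9, 0.9999), 1e-3) # alpha -> 1 limit
  rc <- pearson_critical_value(3:50)
  expect_true(all(diff(rc) < 0))
  expect_error(pearson_critical_value(2), "n >= 3")
})

test_that("screen ranks an affine transcript first and flags zero variance", {
  c_values <- stats::setNames(seq(0.1, 0.9, length.out = 9), sprintf("iso%02d", 1:9))
  meta <- tibble::tibble(
    sample = sprintf("s%02d", 1:27),
    condition = rep(names(c_values), each = 3),
    replicate = rep(paste0("r", 1:3), 9)
  )
  set.seed(6)
  m <- matrix(stats::runif(120 * 27, 1, 100), nrow = 120)
  rownames(m) <- sprintf("g%03d", 1:120)
  colnames(m) <- meta$sample
  m["g001", ] <- 5 + 10 * c_values[meta$condition] # affine in C
  m["g002", ] <- 7 # zero variance
  scr <- correlation_screen(m, meta, c_values)
  res <- scr$result
  expect_equal(res$pearson_r[res$transcript == "g001"], 1, tolerance = 1e-12)
  expect_equal(res$selected[res$transcript == "g001"], "top")
  expect_equal(res$pearson_r[res$transcript == "g002"], 0)
  expect_true(res$zero_variance[res$transcript == "g002"])
  expect_equal(res$selected[res$transcript == "g002"], "none")
  expect_false(res$significant[res$transcript == "g002"])
  expect_equal(scr$n_eff, 27)
  expect_equal(sum(res$selected == "top"), scr$m)
  expect_equal(sum(res$selected == "bottom"), scr$m)

  # averaged mode collapses to condition means: n_eff = 9
  scr_avg <- correlation_screen(m, meta, c_values, mode = "averaged")
  expect_equal(scr_avg$n_eff, 9)
  expect_equal(
    scr_avg$result$pearson_r[scr_avg$result$transcript == "g001"], 1,
    tolerance = 1e-12
  )

  # missing C value for a condition errors
  expect_error(correlation_screen(m, meta, c_values[-1]), "iso01")
})

test_that("screen excludes the control condition from the correlation", {
  c_values <- stats::setNames(c(1, 2, 3), c("a", "b", "c"))
  counts <- matrix(stats::rpois(120 * 8, 50), nrow = 120)
  rownames(counts) <- sprintf("g%03d", 1:120)
  colnames(counts) <- sprintf("s%d", 1:8)
  meta <- tibble::tibble(
    sample = colnames(counts),
    condition = c("a", "a", "b", "b", "c", "c", "control", "control"),
    replicate = rep(c("r1", "r2"), 4)
  )
  # make g001 perfectly correlated on isolate samples but wild in control
  counts[1, ] <- c(1, 1, 2, 2, 3, 3, 1000, 0)
  scr <- correlation_screen(counts, meta, c_values)
  expect_equal(scr$n_eff, 6)
  expect_equal(scr$result$pearson_r[1], 1, tolerance = 1e-12)
})

test_that("category tally matches a hand count and warns on gaps", {
  result <- tibble::tibble(
    transcript = sprintf("t%02d", 1:10),
    pearson_r = c(seq(0.9, 0.5, length.out = 5), seq(-0.5, -0.9, length.out = 5)),
    selected = rep(c("top", "bottom"), each = 5),
    significant = TRUE, zero_variance = FALSE
  )
  ann <- tibble::tibble(
    transcript = sprintf("t%02d", 1:9), # t10 unannotated
    annotation = c(
      "sugar transporter", "zinc finger protein", "MFS transporter permease",
      "unknown", "heat shock protein HSP70",
      "receptor-like kinase", "transcription factor MYB4", "cyclin B",
      "hypothetical protein"
    )
  )
  expect_warning(tally <- category_tally(result, ann), "lack annotations")
  get <- function(cat, col) tally[[col]][tally$category == cat]
  # top set: transporters t01, t03 -> 2/5 = 40%
  expect_equal(get("Transporter", "pct_top"), 40)
  # transcription regulation: top t02 (zinc finger) 20%; bottom t07 (TF MYB) 20%
  expect_equal(get("Transcription regulation", "pct_top"), 20)
  expect_equal(get("Transcription regulation", "pct_bottom"), 20)
  expect_equal(get("Stress response", "pct_top"), 20) # t05
  expect_equal(get("Signal transduction", "pct_bottom"), 20) # t06 kinase
  expect_equal(get("Growth/cell cycle regulation", "pct_bottom"), 20) # t08 cyclin
  expect_equal(get("Carbohydrate biosynthesis", "pct_all"), 0)

  # empty selection: all zero with a warning
  none <- dplyr::mutate(result, selected = "none")
  expect_warning(t0 <- category_tally(none, ann), "no selected")
  expect_true(all(t0$pct_top == 0))
})

test_that("extreme-condition flag marks row maxima and minima of one condition", {
  fc <- rbind(
    g1 = c(a = 3, b = 1, c = 2, control = 9), # a is max among isolates
    g2 = c(a = -2, b = 0, c = 1, control = -9), # a is min
    g3 = c(a = 1, b = 0, c = 2, control = 1)
  )
  flags <- flag_extreme_condition(fc, "a", exclude = "control")
  expect_equal(flags$direction, c("highest", "lowest", "none"))
  expect_error(flag_extreme_condition(fc, "zz"), "zz")
})

test_that("filter -> normalize -> screen is deterministic for fixed input", {
  cs <- sim_counts(tiny_cfg(seed = 14))
  run_once <- function() {
    filt <- filter_expressed(cs$counts, cs$meta, cs$genes)
    norm <- normalize_counts(filt$counts)
    correlation_screen(norm, cs$meta, cs$truth$true_c)$result
  }
  expect_identical(run_once(), run_once())
})
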