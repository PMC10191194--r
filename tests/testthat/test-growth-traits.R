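test_that("elementary trait formulas match hand arithmetic", {
  expect_equal(colonization_pct(0, 10), 0)
  expect_equal(colonization_pct(10, 10), 100)
  expect_equal(colonization_pct(7, 20), 35)
  expect_error(colonization_pct(1, 0), ">= 1")
  expect_error(colonization_pct(11, 10), "exceed")

  expect_equal(hyphal_density(1.0, 20), 0.05)
  expect_equal(hyphal_density(0, 5), 0)
  expect_equal(hyphal_density(2.0, 2.0), 1)
  expect_error(hyphal_density(1, 0), "positive")

  expect_equal(radial_growth_rate(10, 10, 14), 0)
  expect_equal(radial_growth_rate(10, 38, 14), 20)
  expect_equal(radial_growth_rate(5, 10, 14), 100 / 14)
  expect_error(radial_growth_rate(0, 10, 14), "positive")
  # alternative baseline: relative to the agar inoculation block
  expect_equal(
    radial_growth_rate(10, 38, 14, baseline = "agar_block", agar_block_area = 0.25),
    100 * 28 / 0.25 / 14
  )
})

test_that("derived trait table respects plate types and flags bad areas", {
  gs <- sim_growth(sim_config(growth_noise_cv = 0.1, seed = 21))
  traits <- derive_growth_traits(gs$raw)
  sym <- dplyr::filter(traits, plate_type == "symbiosis")
  fo <- dplyr::filter(traits, plate_type == "fungus_only")
  expect_true(all(!is.na(sym$colonization_pct)))
  expect_true(all(is.na(sym$hyphal_density)))
  expect_true(all(!is.na(fo$hyphal_density)))
  expect_true(all(fo$hyphal_density >= 0))
  expect_true(all(sym$colonization_pct >= 0 & sym$colonization_pct <= 100))

  bad <- gs$raw
  bad$colony_area_wk4[1] <- 0.1 # smaller than the 0.25 cm2 agar block
  expect_error(derive_growth_traits(bad), "agar block")
})

test_that("Tukey letters: identical groups share one letter, separated groups do not", {
  df <- data.frame(
    g = rep(c("a", "b", "c"), each = 5),
    y = c(rep(1, 5) + 0.01 * (1:5), rep(1, 5) + 0.01 * (1:5), rep(10, 5) + 0.01 * (1:5))
  )
  fit <- anova_tukey(df, y, g)
  lt <- fit$letters
  sm <- sharing_matrix(lt$letters, lt$group)
  rownames(sm) <- colnames(sm) <- lt$group
  expect_true(sm["a", "b"]) # indistinguishable pair shares a letter
  expect_false(sm["a", "c"]) # far group shares no letter
  expect_false(sm["b", "c"])

  # all groups identical -> single letter for everyone
  df2 <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = rep(c(1, 2, 3, 4), 3))
  fit2 <- anova_tukey(df2, y, g)
  expect_true(all(fit2$letters$letters == fit2$letters$letters[1]))
  expect_equal(nchar(fit2$letters$letters[1]), 1)
})

test_that("two well-separated groups get distinct letters (reference oracle draw)", {
  set.seed(101)
  df <- data.frame(
    g = rep(c("lo", "hi"), each = 5),
    y = c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  )
  fit <- anova_tukey(df, y, g)
  expect_equal(sort(fit$letters$letters), c("a", "b"))
  # group with the larger mean carries "a"
  expect_equal(fit$letters$group[fit$letters$letters == "a"], "hi")
})

test_that("letter display is partition-consistent with the pairwise p-matrix", {
  set.seed(55)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    means <- sample(c(0, 0, 4, 8, 12), k)
    df <- data.frame(
      g = rep(letters[1:k], each = 5),
      y = stats::rnorm(5 * k, rep(means, each = 5), 1)
    )
    fit <- anova_tukey(df, y, g)
    sm <- sharing_matrix(fit$letters$letters, fit$letters$group)
    rownames(sm) <- colnames(sm) <- fit$letters$group
    for (i in seq_len(nrow(fit$tukey))) {
      pair <- strsplit(fit$tukey$contrast[i], "-", fixed = TRUE)[[1]]
      if (fit$tukey$adj.p.value[i] < fit$alpha) {
        expect_false(sm[pair[1], pair[2]])
      } else {
        expect_true(sm[pair[1], pair[2]])
      }
    }
  }
})

test_that("groups with a single replicate are rejected", {
  df <- data.frame(g = c("a", "a", "b"), y = c(1, 2, 3))
  expect_error(anova_tukey(df, y, g), "fewer than 2")
})

test_that("PCA: collinear variables load on one component", {
  d <- tibble::tibble(
    isolate = sprintf("i%d", 1:6),
    v1 = c(1, 2, 3, 4, 5, 6),
    v2 = 2 * c(1, 2, 3, 4, 5, 6)
  )
  pca <- pca_traits(d, log_transform = FALSE, scale = FALSE)
  expect_equal(pca$var_explained[1], 1)
  expect_equal(sum(pca$var_explained), 1)
})

test_that("PCA variance fractions match an independent eigen decomposition", {
  set.seed(42)
  x <- matrix(stats::rlnorm(9 * 7, 1, 0.6), nrow = 9)
  colnames(x) <- paste0("v", 1:7)
  d <- tibble::as_tibble(x)
  # covariance route
  pca <- pca_traits(d, log_transform = FALSE, scale = FALSE)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(pca$var_explained, ev / sum(ev), tolerance = 1e-10)
  # correlation route
  pca_s <- pca_traits(d, log_transform = FALSE, scale = TRUE)
  ev_s <- eigen(stats::cor(x), symmetric = TRUE)$values
  expect_equal(pca_s$var_explained, ev_s / sum(ev_s), tolerance = 1e-10)
  # log route: eigenvalues of the covariance of the logged data
  pca_l <- pca_traits(d, log_transform = TRUE, scale = FALSE)
  xl <- apply(x, 2, function(col) log(col + min(col[col > 0]) * 1e-3))
  ev_l <- eigen(stats::cov(xl), symmetric = TRUE)$values
  expect_equal(pca_l$var_explained, ev_l / sum(ev_l), tolerance = 1e-10)
})

test_that("PCA scores reconstruct the centered data and signs are deterministic", {
  set.seed(9)
  x <- matrix(stats::runif(9 * 5, 1, 10), nrow = 9)
  colnames(x) <- paste0("v", 1:5)
  pca <- pca_traits(tibble::as_tibble(x), log_transform = FALSE, scale = FALSE)
  scores <- as.matrix(pca$scores[grep("^PC", names(pca$scores))])
  load <- as.matrix(pca$loadings[grep("^PC", names(pca$loadings))])
  recon <- scores %*% t(load) + matrix(colMeans(x), 9, 5, byrow = TRUE)
  expect_equal(unname(recon), unname(x), tolerance = 1e-10)
  # largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(load))) {
    expect_gt(load[which.max(abs(load[, j])), j], 0)
  }
})

test_that("PCA handles zero trait values via the epsilon offset", {
  d <- tibble::tibble(
    v1 = c(0, 0.5, 1, 2, 4), # zero biomass occurs in weak isolates
    v2 = c(3, 2, 5, 1, 4)
  )
  expect_silent(pca <- pca_traits(d))
  expect_equal(sum(pca$var_explained), 1)
})

test_that("trait-carbon correlation matches the closed-form Pearson r", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  expect_equal(trait_c_correlation(x, x * 3 + 1)$estimate, 1)
  expect_equal(trait_c_correlation(x, -x)$estimate, -1)
  set.seed(31)
  y <- stats::rnorm(9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- trait_c_correlation(x, y, paired = TRUE)
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  expect_true(res$paired)
  expect_equal(res$n, 9)
  expect_error(trait_c_correlation(x, rep(1, 9)), "zero variance")
  expect_error(trait_c_correlation(1:2, 1:3), "lengths")
})
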