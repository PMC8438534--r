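# ANOVA partition, heritability, descriptive variability, correlations,
# PCA, genotype selection and Ward clustering.

test_that("two-way ANOVA matches explicit textbook sums of squares", {
  # 2 genotypes x 2 treatments x 2 reps, hand-checkable values
  tab <- demo_table(c(10, 12, 6, 8, 20, 22, 10, 12))
  fit <- two_way_anova(tab, "y")
  ss <- hand_anova_ss(tab, "y")
  expect_equal(fit$ss, unname(ss[c("genotype", "concentration",
                                   "interaction", "error")]),
               tolerance = 1e-10)
  expect_equal(sum(fit$ss), unname(ss["total"]), tolerance = 1e-10)
  expect_equal(fit$df, c(1, 1, 1, 4))
  expect_equal(sum(fit$ss_pct), 100, tolerance = 1e-6)
})

test_that("ANOVA SS% partition sums to 100 on random balanced tables", {
  for (seed in 1:5) {
    m <- sim_model(n_genotypes = 8, n_reps = 3, sigma2_g = 2, sigma2_gc = 1,
                   conc_effect = -3, sigma2_e = 1, seed = seed)
    tab <- simulate_trait_table(m, "y")$table
    fit <- two_way_anova(tab, "y")
    expect_equal(sum(fit$ss_pct), 100, tolerance = 1e-6)
    expect_equal(sum(fit$df), nrow(tab) - 1L)
  }
})

test_that("a concentration-only response concentrates SS in the C term", {
  m <- sim_model(n_genotypes = 10, n_reps = 3, mu = 50, sigma2_g = 0,
                 sigma2_gc = 0, conc_effect = -10, sigma2_e = 1e-6, seed = 2)
  tab <- simulate_trait_table(m, "y")$table
  fit <- two_way_anova(tab, "y")
  expect_gt(fit$ss_pct[fit$term == "concentration"], 99.9)
  expect_lt(fit$ss_pct[fit$term == "genotype"], 0.1)
})

test_that("permuting genotype labels within treatments preserves the C term", {
  m <- sim_model(n_genotypes = 6, n_reps = 3, seed = 4)
  tab <- simulate_trait_table(m, "y")$table
  base_ss <- two_way_anova(tab, "y")$ss[2L]
  set.seed(1)
  shuffled <- tab |>
    dplyr::group_by(treatment) |>
    dplyr::mutate(genotype = sample(genotype)) |>
    dplyr::ungroup() |>
    dplyr::group_by(genotype, treatment) |>
    dplyr::mutate(rep = dplyr::row_number()) |>
    dplyr::ungroup()
  expect_equal(two_way_anova(shuffled, "y")$ss[2L], base_ss)
})

test_that("unbalanced designs are rejected with guidance", {
  m <- sim_model(n_genotypes = 4, n_reps = 3, seed = 5)
  tab <- simulate_trait_table(m, "y")$table
  expect_error(two_way_anova(tab[-1L, ], "y"), "unbalanced")
})

test_that("heritability hits its exact degenerate limits", {
  # no within-genotype variance: H2 = 100
  tab <- tibble::tibble(genotype = rep(c("A", "B", "C"), each = 2L),
                        treatment = "control", rep = rep(1:2, 3L),
                        y = rep(c(5, 9, 13), each = 2L))
  expect_equal(heritability(tab, "y", "control")$H2_pct, 100)
  # MS_G <= MS_E: sigma2_g truncated to 0, H2 = 0
  tab2 <- tibble::tibble(genotype = rep(c("A", "B"), each = 4L),
                         treatment = "control", rep = rep(1:4, 2L),
                         y = c(1, 9, 5, 5, 1, 9, 5, 5))
  h2 <- heritability(tab2, "y", "control")
  expect_equal(h2$sigma2_g, 0)
  expect_equal(h2$H2_pct, 0)
  expect_equal(h2$sigma2_p, h2$sigma2_g + h2$sigma2_e / h2$r)
})

test_that("heritability recovers the simulated variance ratio", {
  m <- sim_model(n_genotypes = 300, n_reps = 5, mu = 50, sigma2_g = 4,
                 sigma2_gc = 0, conc_effect = -5, sigma2_e = 1, seed = 11)
  tab <- simulate_trait_table(m, "y")$table
  h2 <- heritability(tab, "y", "control")$H2_pct
  expect_lt(abs(h2 - 100 * 4 / (4 + 1 / 5)), 3)
})

test_that("descriptive statistics match closed forms", {
  tab <- tibble::tibble(genotype = c("A", "B", "C"), treatment = "control",
                        rep = 1L, y = c(1, 2, 3))
  d <- suppressWarnings(descriptive_stats(tab, "y", "control"))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$cv_pct, 50)
  const <- tab
  const$y <- 7
  d2 <- suppressWarnings(descriptive_stats(const, "y", "control"))
  expect_equal(d2$sd, 0)
  expect_equal(d2$cv_pct, 0)
  expect_true(is.na(d2$skewness))
})

test_that("GCV tracks the simulated genotypic variation", {
  m <- sim_model(n_genotypes = 300, n_reps = 4, mu = 40, sigma2_g = 16,
                 sigma2_gc = 0, conc_effect = 0, sigma2_e = 1, seed = 12)
  tab <- simulate_trait_table(m, "y")$table
  d <- descriptive_stats(tab, "y", "control")
  expect_lt(abs(d$gcv_pct - 100 * 4 / 40) / (100 * 4 / 40), 0.1)
})

test_that("correlation matrix recovers engineered relationships", {
  set.seed(3)
  n <- 1000L
  x <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  x$dup <- x$a
  x$neg <- -x$b
  cm <- correlation_matrix(x)
  expect_equal(cm$r["a", "dup"], 1)
  expect_equal(cm$r["b", "neg"], -1)
  expect_lt(abs(cm$r["a", "b"]), 0.1) # independent columns
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 4L))
  expect_warning(cm2 <- correlation_matrix(dplyr::mutate(x, k = 1)),
                 "constant")
  expect_true(all(is.na(cm2$r["k", ])))
  long <- tidy(cm)
  expect_equal(nrow(long), choose(4L, 2L))
})

test_that("PCA explains variance correctly and reconstructs the data", {
  # rank-1 data: PC1 carries everything
  v <- matrix(rnorm(8), 4L, 2L)
  rank1 <- outer(c(1, 2, 3, 4, 5), c(2, -1, 0.5))
  rownames(rank1) <- paste0("g", 1:5)
  fit1 <- pca_screen(rank1, standardize = FALSE)
  expect_equal(fit1$explained_pct[1L], 100, tolerance = 1e-9)
  set.seed(5)
  x <- matrix(rnorm(24), 6L, 4L, dimnames = list(paste0("g", 1:6),
                                                 paste0("t", 1:4)))
  fit <- pca_screen(x, standardize = FALSE)
  expect_equal(sum(fit$explained_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(fit$explained_pct) <= 1e-12))
  # orthonormal loadings, diagonal score covariance
  expect_equal(crossprod(fit$loadings), diag(4L), tolerance = 1e-8,
               ignore_attr = TRUE)
  sc_cov <- crossprod(fit$scores) / (nrow(x) - 1L)
  expect_equal(sc_cov[upper.tri(sc_cov)], rep(0, 6L), tolerance = 1e-8)
  # full-rank reconstruction of the centered matrix
  rec <- fit$scores %*% t(fit$loadings)
  expect_equal(rec, scale(x, scale = FALSE), tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign convention
  for (j in seq_len(ncol(fit$loadings))) {
    v <- fit$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_screen(cbind(x, k = 1)), "constant")
  xna <- x; xna[1L] <- NA
  expect_error(pca_screen(xna), "missing")
})

test_that("mean-threshold selection covers quadrants and flags superiority", {
  set.seed(6)
  centers <- rbind(c(5, 5), c(5, -5), c(-5, 5), c(-5, -5))
  x <- centers[rep(1:4, each = 5L), ] + matrix(rnorm(40, sd = 0.3), 20L, 2L)
  x <- cbind(x, x[, 1L] + rnorm(20, sd = 0.2))
  dimnames(x) <- list(sprintf("g%02d", 1:20), c("ta", "tb", "tc"))
  fit <- pca_screen(x)
  sel <- select_genotypes(fit, x, c("ta", "tb"))
  expect_equal(sort(unique(sel$quadrant)),
               sort(c("+PC1+PC2", "+PC1-PC2", "-PC1+PC2", "-PC1-PC2")))
  picked <- sel[sel$selected, ]
  expect_equal(length(unique(picked$quadrant)), 4L)
  # a genotype above every panel mean is flagged superior on all traits
  top <- which(x[, "ta"] > mean(x[, "ta"]) & x[, "tb"] > mean(x[, "tb"]))[1L]
  expect_equal(unname(sel$n_superior[match(rownames(x)[top], sel$genotype)]), 2)
  expect_error(select_genotypes(fit, x, character(0)), "non-empty")
  flat <- matrix(1, 4L, 2L, dimnames = list(letters[1:4], c("ta", "tb")))
  fit_flat <- pca_screen(flat, standardize = FALSE)
  expect_error(select_genotypes(fit_flat, flat, c("ta", "tb")), "no contrast")
})

test_that("Ward clustering separates planted groups and scales rows", {
  set.seed(7)
  g1 <- matrix(rnorm(50, 0, 1), 10L, 5L)
  g2 <- matrix(rnorm(50, 100, 1), 10L, 5L) # 100 sd apart
  x <- rbind(g1, g2) + rnorm(100, 0, 0.01) # break exact row constancy risk
  rownames(x) <- sprintf("i%02d", 1:20)
  colnames(x) <- sprintf("f%d", 1:5)
  cl <- ward_cluster(x, scale_rows = FALSE, k = 2L)
  expect_equal(length(unique(cl$labels[1:10])), 1L)
  expect_equal(length(unique(cl$labels[11:20])), 1L)
  expect_false(cl$labels[1L] == cl$labels[20L])
  expect_true(all(diff(cl$item_hclust$height) >= -1e-9))
  scl <- ward_cluster(x, scale_rows = TRUE, k = 2L)
  expect_equal(unname(rowMeans(scl$scaled)), rep(0, 20L), tolerance = 1e-12)
  expect_equal(unname(apply(scl$scaled, 1L, sd)), rep(1, 20L), tolerance = 1e-12)
  # item-order invariance up to relabelling
  perm <- sample(nrow(x))
  cl2 <- ward_cluster(x[perm, ], scale_rows = FALSE, k = 2L)
  lab1 <- cl$labels[rownames(x)[perm]]
  agree <- table(lab1, cl2$labels)
  expect_equal(sum(apply(agree, 1L, max)), nrow(x))
  bad <- x
  bad[3L, ] <- 42
  expect_error(ward_cluster(bad, scale_rows = TRUE), "i03")
})
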