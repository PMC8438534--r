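# Tolerance/susceptibility indices, selection patterns, and their exact
# algebraic identities.

random_pairs <- function(n, seed) {
  set.seed(seed)
  p <- tibble::tibble(genotype = sprintf("G%04d", seq_len(n)),
                      y_ns = stats::runif(n, 5, 50),
                      y_s = stats::runif(n, 1, 45))
  attr(p, "grand_mean_ns") <- mean(p$y_ns)
  attr(p, "grand_mean_s") <- mean(p$y_s)
  p
}

test_that("stress intensity follows the Fischer-Maurer convention", {
  expect_equal(stress_intensity(6, 10), 0.4)
  expect_equal(stress_intensity(10, 10), 0)
  expect_error(stress_intensity(6, 0), "zero")
})

test_that("the worked single-genotype substitution reproduces all seven indices", {
  p <- tibble::tibble(genotype = "A", y_ns = 10, y_s = 6)
  attr(p, "grand_mean_ns") <- 10
  attr(p, "grand_mean_s") <- 6
  idx <- compute_indices(p)
  expect_equal(idx$MPI, 8)
  expect_equal(idx$TOL, 4)
  expect_equal(idx$STI, 0.6)
  expect_equal(idx$MRP, 2.0)
  expect_equal(idx$REI, 1.0)
  expect_equal(idx$DTE_pct, 60)
  expect_equal(idx$SSI, 1.0)
  expect_equal(attr(idx, "si"), 0.4)
})

test_that("index identities hold exactly on random panels", {
  pairs <- random_pairs(200, seed = 7)
  idx <- compute_indices(pairs)
  si <- attr(idx, "si")
  expect_equal(idx$y_ns, idx$MPI + idx$TOL / 2, tolerance = 1e-12)
  expect_equal(idx$y_s, idx$MPI - idx$TOL / 2, tolerance = 1e-12)
  expect_gt(si, 0)
  expect_equal(idx$DTE_pct, 100 * (1 - idx$SSI * si), tolerance = 1e-12)
  a <- idx$y_s / attr(idx, "grand_mean_s")
  b <- idx$y_ns / attr(idx, "grand_mean_ns")
  expect_equal(idx$MRP, a + b, tolerance = 1e-12)
  expect_equal(idx$REI, a * b, tolerance = 1e-12)
})

test_that("relative indices are unit-free; MPI and TOL carry the trait unit", {
  pairs <- random_pairs(40, seed = 8)
  k <- 7.3
  scaled <- pairs
  scaled$y_ns <- pairs$y_ns * k
  scaled$y_s <- pairs$y_s * k
  attr(scaled, "grand_mean_ns") <- attr(pairs, "grand_mean_ns") * k
  attr(scaled, "grand_mean_s") <- attr(pairs, "grand_mean_s") * k
  i1 <- compute_indices(pairs)
  i2 <- compute_indices(scaled)
  for (nm in c("MRP", "REI", "SSI", "DTE_pct", "STI")) {
    expect_equal(i2[[nm]], i1[[nm]], tolerance = 1e-12)
  }
  expect_equal(i2$MPI, k * i1$MPI, tolerance = 1e-12)
  expect_equal(i2$TOL, k * i1$TOL, tolerance = 1e-12)
})

test_that("STI and REI rank genotypes identically", {
  pairs <- random_pairs(60, seed = 9)
  idx <- compute_indices(pairs)
  expect_equal(rank(idx$STI), rank(idx$REI))
})

test_that("no-stress limit: TOL 0, DTE 100, SSI undefined", {
  p <- tibble::tibble(genotype = c("A", "B"), y_ns = c(10, 20), y_s = c(10, 20))
  attr(p, "grand_mean_ns") <- 15
  attr(p, "grand_mean_s") <- 15
  expect_warning(idx <- compute_indices(p), "stress intensity is zero")
  expect_equal(idx$TOL, c(0, 0))
  expect_equal(idx$DTE_pct, c(100, 100))
  expect_true(all(is.na(idx$SSI)))
  expect_equal(attr(idx, "si"), 0)
})

test_that("a zero control mean disables only that genotype's SSI and DTE", {
  p <- tibble::tibble(genotype = c("A", "B", "C"),
                      y_ns = c(10, 0, 20), y_s = c(6, 1, 12))
  expect_warning(idx <- compute_indices(p), "zero or missing control")
  expect_true(is.na(idx$SSI[2L]) && is.na(idx$DTE_pct[2L]))
  expect_false(anyNA(idx$SSI[-2L]))
  expect_false(anyNA(idx$MPI)) # additive indices survive
})

test_that("classification honours each index's selection pattern", {
  p <- tibble::tibble(genotype = c("A", "B"), y_ns = c(10, 8), y_s = c(6, 7))
  idx <- compute_indices(p)
  expect_equal(classify_genotypes(idx, "MPI")$genotype[1L], "A") # maximum value
  expect_equal(classify_genotypes(idx, "SSI")$genotype[1L], "B") # minimum value
  expect_equal(classify_genotypes(idx, "TOL")$genotype[1L], "B") # minimum value
  tied <- tibble::tibble(genotype = c("A", "B"), y_ns = c(10, 10), y_s = c(6, 6))
  expect_equal(classify_genotypes(compute_indices(tied), "MPI")$rank, c(1.5, 1.5))
  allna <- idx
  allna$SSI <- NA_real_
  expect_error(classify_genotypes(allna, "SSI"), "missing")
})

test_that("index-trait correlations recover engineered relationships", {
  pairs <- random_pairs(50, seed = 10)
  idx <- compute_indices(pairs)
  res <- index_trait_correlation(idx, idx$DTE_pct)
  expect_equal(res$r[res$index == "DTE_pct"], 1)
  res2 <- index_trait_correlation(idx, -idx$MPI)
  expect_equal(res2$r[res2$index == "MPI"], -1)
  # SSI is an affine function of DTE, so |r| = 1 with opposite sign
  expect_equal(res$r[res$index == "SSI"], -1, tolerance = 1e-9)
})

test_that("a concentration-only response makes DTE uninformative", {
  # no genotype x concentration interaction: y_s/y_ns nearly constant
  m <- sim_model(n_genotypes = 200, n_reps = 4, mu = 100, sigma2_g = 9,
                 sigma2_gc = 0, conc_effect = -20, sigma2_e = 0.01, seed = 13)
  tab <- simulate_trait_table(m, "y")$table
  idx <- compute_indices(tab, trait = "y")
  means_s <- trait_matrix(tab, "y", treatment = "deficient")[idx$genotype, 1L]
  res <- index_trait_correlation(idx, means_s)
  # DTE is near-constant (sub-1% spread around its mean) while MPI tracks
  # the deficient means tightly
  expect_gt(res$r[res$index == "MPI"], 0.95)
  expect_lt(100 * stats::sd(idx$DTE_pct) / mean(idx$DTE_pct), 1)
})

test_that("stress pairs exclude incomplete genotypes from the grand means", {
  tab <- tibble::tibble(
    genotype = c("A", "A", "B", "B", "C"),
    treatment = c("control", "deficient", "control", "deficient", "control"),
    rep = 1L, y = c(10, 6, 20, 12, 99))
  expect_warning(p <- stress_pairs(tab, "y"), "without both treatments")
  expect_equal(attr(p, "grand_mean_ns"), 15) # C's 99 excluded
  expect_equal(attr(p, "grand_mean_s"), 9)
})
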