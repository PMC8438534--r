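# Simulator for genotype x P-concentration trait tables.
#
# Generative model (the inverse of the fitted two-way ANOVA):
#   Y_ijk = mu + g_i + c_j + gc_ij + e_ijk
# with genotype effects g_i ~ N(0, sigma2_g), interaction gc_ij ~
# N(0, sigma2_gc), errors e_ijk ~ N(0, sigma2_e), and the concentration
# effect c_j equal to 0 under control and `conc_effect` under deficiency.

#' Simulation model for a genotype x treatment trial
#'
#' @param n_genotypes Number of genotypes, >= 2.
#' @param n_reps Replicates per genotype x treatment cell, >= 2 (fewer makes
#'   per-treatment heritability undefined).
#' @param mu Overall trait mean.
#' @param sigma2_g Genotypic variance, >= 0.
#' @param sigma2_gc Genotype x concentration interaction variance, >= 0.
#' @param conc_effect Additive shift applied under the deficient treatment
#'   (negative for traits depressed by low phosphorus).
#' @param sigma2_e Error (residual) variance, >= 0.
#' @param seed Integer seed.
#' @return An object of class `sim_model`.
#' @export
sim_model <- function(n_genotypes = 18L, n_reps = 3L, mu = 100,
                      sigma2_g = 4, sigma2_gc = 0, conc_effect = -10,
                      sigma2_e = 1, seed = 1L) {
  stopifnot(n_genotypes >= 2L, sigma2_g >= 0, sigma2_gc >= 0, sigma2_e >= 0,
            is.finite(mu), is.finite(conc_effect))
  if (n_reps < 2L) {
    stop("n_reps must be >= 2: per-treatment heritability is undefined ",
         "without replication", call. = FALSE)
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_reps = as.integer(n_reps), mu = mu,
                 sigma2_g = sigma2_g, sigma2_gc = sigma2_gc,
                 conc_effect = conc_effect, sigma2_e = sigma2_e,
                 seed = as.integer(seed)),
            class = "sim_model")
}

#' Simulate a balanced genotype x treatment trait table
#'
#' Draws one independent realisation of the two-way model per trait and
#' returns a tidy, balanced table (`n_genotypes` x 2 treatments x `n_reps`
#' rows) together with the realised effects, so downstream estimators can
#' be checked against the values actually drawn.
#'
#' @param model A [sim_model()].
#' @param traits Character vector of trait names.
#' @return List with `table` (tibble: `genotype`, `treatment`, `rep`, one
#'   column per trait) and `truth` (tibble of realised per-genotype effects:
#'   `trait`, `genotype`, `g_effect`, `gc_control`, `gc_deficient`).
#' @export
simulate_trait_table <- function(model, traits = "trait1") {
  stopifnot(inherits(model, "sim_model"), length(traits) >= 1L)
  genos <- sprintf("G%02d", seq_len(model$n_genotypes))
  grid <- tidyr::expand_grid(genotype = genos,
                             treatment = c("control", "deficient"),
                             rep = seq_len(model$n_reps))
  with_local_seed(model$seed, {
    truth <- list()
    for (tr in traits) {
      g <- stats::rnorm(model$n_genotypes, 0, sqrt(model$sigma2_g))
      gc <- matrix(stats::rnorm(2L * model$n_genotypes, 0, sqrt(model$sigma2_gc)),
                   ncol = 2L, dimnames = list(genos, c("control", "deficient")))
      e <- stats::rnorm(nrow(grid), 0, sqrt(model$sigma2_e))
      gi <- match(grid$genotype, genos)
      cj <- ifelse(grid$treatment == "deficient", model$conc_effect, 0)
      tj <- match(grid$treatment, c("control", "deficient"))
      grid[[tr]] <- model$mu + g[gi] + cj + gc[cbind(gi, tj)] + e
      truth[[tr]] <- tibble::tibble(trait = tr, genotype = genos, g_effect = g,
                                    gc_control = gc[, "control"],
                                    gc_deficient = gc[, "deficient"])
    }
    list(table = grid, truth = dplyr::bind_rows(truth))
  })
}
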