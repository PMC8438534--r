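# Replicate-level screening statistics: two-way ANOVA with sum-of-squares
# partition, broad-sense heritability from variance components, and
# descriptive variability measures.

check_balanced <- function(table, trait, two_way = TRUE) {
  stopifnot(trait %in% names(table))
  if (any(!is.finite(table[[trait]]))) {
    stop("trait '", trait, "' contains non-finite values", call. = FALSE)
  }
  counts <- dplyr::count(table, .data$genotype, .data$treatment)
  if (two_way) {
    n_t <- length(unique(table$treatment))
    if (n_t != 2L) stop("need exactly 2 treatments, found ", n_t, call. = FALSE)
    full <- length(unique(table$genotype)) * 2L
    if (nrow(counts) != full || length(unique(counts$n)) != 1L) {
      stop("unbalanced design for trait '", trait, "': every genotype x ",
           "treatment cell needs the same replicate count; impute cell ",
           "means or subset to a balanced panel first", call. = FALSE)
    }
  } else if (length(unique(counts$n)) != 1L) {
    stop("unbalanced replication for trait '", trait, "'", call. = FALSE)
  }
  counts$n[1L]
}

#' Balanced two-way analysis of variance with SS% partition
#'
#' Fits the fixed-effects model Y = mu + genotype + concentration +
#' genotype:concentration + error to a balanced genotype x treatment table
#' and reports, per term, the degrees of freedom, sum of squares, mean
#' square, F statistic against the error mean square, p-value, and the
#' term's percentage share of the total sum of squares (which sums to 100
#' over genotype, concentration, interaction and error).
#'
#' @param table Tidy trait table (`genotype`, `treatment`, `rep`, traits).
#' @param trait Trait column to analyse.
#' @return Tibble of class `anova_partition` with columns `term`, `df`,
#'   `ss`, `ms`, `f`, `p_value`, `ss_pct`; the trait name is attached as
#'   attribute `trait`.
#' @export
two_way_anova <- function(table, trait) {
  r <- check_balanced(table, trait, two_way = TRUE)
  if (r < 2L) stop("need at least 2 replicates per cell", call. = FALSE)
  if (length(unique(table$genotype)) < 2L) {
    stop("need at least 2 genotypes", call. = FALSE)
  }
  d <- data.frame(y = table[[trait]],
                  genotype = factor(table$genotype),
                  treatment = factor(table$treatment))
  fit <- stats::aov(y ~ genotype * treatment, data = d)
  tab <- summary(fit)[[1L]]
  terms <- c("genotype", "concentration", "interaction", "error")
  out <- tibble::tibble(
    term = terms,
    df = tab[["Df"]],
    ss = tab[["Sum Sq"]],
    ms = tab[["Mean Sq"]],
    f = tab[["F value"]],
    p_value = tab[["Pr(>F)"]]
  )
  out$ss_pct <- 100 * out$ss / sum(out$ss)
  structure(out, trait = trait, n = nrow(d),
            class = c("anova_partition", class(out)))
}

#' Broad-sense heritability within one treatment
#'
#' One-way ANOVA on genotypes within a single treatment gives the genotype
#' and error mean squares, from which the variance components are
#' sigma2_g = max(0, (MS_G - MS_E) / r) and sigma2_e = MS_E. Heritability
#' is H2 = sigma2_g / sigma2_p x 100 with phenotypic variance
#' sigma2_p = sigma2_g + sigma2_e / r (r = replicates per genotype).
#' Negative genotypic-variance estimates are truncated at zero, keeping H2
#' in \[0, 100\].
#'
#' @param table Tidy trait table.
#' @param trait Trait column.
#' @param treatment `"control"` or `"deficient"`.
#' @return One-row tibble of class `variance_components`: `trait`,
#'   `treatment`, `r`, `ms_g`, `ms_e`, `sigma2_g`, `sigma2_e`, `sigma2_p`,
#'   `H2_pct`.
#' @export
heritability <- function(table, trait, treatment = c("control", "deficient")) {
  treatment <- match.arg(treatment)
  sub <- table[table$treatment == treatment, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for treatment '", treatment, "'", call. = FALSE)
  r <- check_balanced(sub, trait, two_way = FALSE)
  if (r < 2L) {
    stop("need at least 2 replicates per genotype to separate genotypic ",
         "from error variance", call. = FALSE)
  }
  d <- data.frame(y = sub[[trait]], genotype = factor(sub$genotype))
  tab <- summary(stats::aov(y ~ genotype, data = d))[[1L]]
  ms_g <- tab[["Mean Sq"]][1L]
  ms_e <- tab[["Mean Sq"]][2L]
  sigma2_g <- max(0, (ms_g - ms_e) / r)
  sigma2_e <- ms_e
  sigma2_p <- sigma2_g + sigma2_e / r
  h2 <- if (sigma2_p > 0) 100 * sigma2_g / sigma2_p else {
    warning("zero phenotypic variance: heritability undefined", call. = FALSE)
    NA_real_
  }
  structure(
    tibble::tibble(trait = trait, treatment = treatment, r = r,
                   ms_g = ms_g, ms_e = ms_e, sigma2_g = sigma2_g,
                   sigma2_e = sigma2_e, sigma2_p = sigma2_p, H2_pct = h2),
    class = c("variance_components", class(tibble::tibble())))
}

#' Descriptive variability of one trait within a treatment
#'
#' Mean, standard deviation, coefficient of variation (100 sd / mean),
#' genotypic coefficient of variation (100 sqrt(sigma2_g) / mean, with
#' sigma2_g from [heritability()]), and adjusted Fisher-Pearson skewness.
#'
#' @param table Tidy trait table.
#' @param trait Trait column.
#' @param treatment `"control"` or `"deficient"`.
#' @return One-row tibble: `trait`, `treatment`, `n`, `mean`, `sd`,
#'   `cv_pct`, `gcv_pct`, `skewness`. CV and GCV are NA (with a warning)
#'   when the mean is zero; skewness is NA for constant data.
#' @export
descriptive_stats <- function(table, trait, treatment = c("control", "deficient")) {
  treatment <- match.arg(treatment)
  x <- table[[trait]][table$treatment == treatment]
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (m == 0) {
    warning("zero mean: CV and GCV undefined", call. = FALSE)
    cv <- gcv <- NA_real_
  } else {
    cv <- 100 * s / m
    gcv <- tryCatch({
      vc <- suppressWarnings(heritability(table, trait, treatment))
      100 * sqrt(vc$sigma2_g) / m
    }, error = function(e) {
      warning("GCV unavailable: ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  sk <- if (s == 0) NA_real_ else e1071::skewness(x, type = 2)
  tibble::tibble(trait = trait, treatment = treatment, n = length(x),
                 mean = m, sd = s, cv_pct = cv, gcv_pct = gcv, skewness = sk)
}
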