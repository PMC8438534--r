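# broom-style tidy()/glance() methods for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method
tidy.anova_partition <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method
glance.anova_partition <- function(x, ...) {
  tibble::tibble(
    trait = attr(x, "trait"),
    n = attr(x, "n"),
    ss_pct_genotype = x$ss_pct[x$term == "genotype"],
    ss_pct_concentration = x$ss_pct[x$term == "concentration"],
    ss_pct_interaction = x$ss_pct[x$term == "interaction"],
    ss_pct_error = x$ss_pct[x$term == "error"]
  )
}

#' @exportS3Method
tidy.tolerance_indices <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(INDEX_NAMES),
                        names_to = "index", values_to = "value") |>
    dplyr::select("genotype", "index", "value")
}

#' @exportS3Method
glance.tolerance_indices <- function(x, ...) {
  tibble::tibble(
    n_genotypes = nrow(x),
    stress_intensity = attr(x, "si"),
    grand_mean_ns = attr(x, "grand_mean_ns"),
    grand_mean_s = attr(x, "grand_mean_s")
  )
}

#' @exportS3Method
tidy.trait_correlations <- function(x, ...) {
  traits <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    trait1 = traits[idx[, 1L]],
    trait2 = traits[idx[, 2L]],
    r = x$r[idx],
    p_value = x$p[idx]
  )
}

#' @exportS3Method
tidy.pca_screen <- function(x, ...) {
  loadings <- x$loadings
  tibble::tibble(
    trait = rep(rownames(loadings), ncol(loadings)),
    component = rep(colnames(loadings), each = nrow(loadings)),
    loading = as.vector(loadings),
    contrib_pct = as.vector(x$contrib_pct)
  )
}

#' @exportS3Method
glance.pca_screen <- function(x, ...) {
  ex <- x$explained_pct
  tibble::tibble(
    n_components = length(ex),
    pc1_pct = ex[1L],
    pc2_pct = if (length(ex) >= 2L) ex[2L] else NA_real_,
    cumulative2_pct = sum(ex[seq_len(min(2L, length(ex)))])
  )
}

#' @exportS3Method
tidy.ward_cluster <- function(x, ...) {
  tibble::tibble(item = names(x$labels), cluster = unname(x$labels))
}
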