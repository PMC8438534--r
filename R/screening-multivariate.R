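# Multivariate screening: genotype-mean trait matrices, Pearson
# correlations, principal components with mean-threshold genotype
# selection, and Ward-D2 clustering with row Z-score scaling.

#' Genotype-mean trait matrix
#'
#' Collapses a tidy trait table to a genotype x trait matrix of means for
#' one treatment (or across both), the input format of the multivariate
#' stages.
#'
#' @param table Tidy trait table.
#' @param traits Trait columns to keep (default: all numeric columns except
#'   `rep`).
#' @param treatment `"control"`, `"deficient"`, or `NULL` for both pooled.
#' @return Numeric matrix, genotypes in rows (rownames), traits in columns.
#' @export
trait_matrix <- function(table, traits = NULL, treatment = NULL) {
  if (!is.null(treatment)) {
    table <- table[table$treatment %in% treatment, , drop = FALSE]
  }
  if (is.null(traits)) {
    traits <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], "rep")
  }
  means <- table |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits), mean), .groups = "drop")
  m <- as.matrix(means[traits])
  rownames(m) <- means$genotype
  m
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    id <- which(!vapply(x, is.numeric, logical(1)))
    if (length(id) > 0L) {
      rn <- x[[id[1L]]]
      x <- x[vapply(x, is.numeric, logical(1))]
      m <- as.matrix(x)
      rownames(m) <- rn
      return(m)
    }
    return(as.matrix(x))
  }
  as.matrix(x)
}

#' Pearson correlation matrix with significance tests
#'
#' Pairwise Pearson correlations between trait columns of a genotype-mean
#' matrix, with unadjusted two-sided t-test p-values (optionally Bonferroni
#' corrected). Constant traits produce NA rows/columns with a warning.
#'
#' @param x Genotype x trait matrix (e.g. from [trait_matrix()]).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Object of class `trait_correlations`: list with symmetric
#'   matrices `r` and `p` (unit diagonal, NA p on the diagonal) and the
#'   genotype count `n`. Use [generics::tidy()] for a long tibble.
#' @export
correlation_matrix <- function(x, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  x <- as_feature_matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 genotypes", call. = FALSE)
  constant <- apply(x, 2L, stats::sd) == 0
  if (any(constant)) {
    warning("constant trait(s) ", paste(colnames(x)[constant], collapse = ", "),
            ": correlations set to NA", call. = FALSE)
  }
  p <- ncol(x)
  r_mat <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  p_mat <- r_mat
  diag(r_mat) <- ifelse(constant, NA_real_, 1)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      if (constant[i] || constant[j]) next
      ct <- stats::cor.test(x[, i], x[, j], method = "pearson")
      r_mat[i, j] <- r_mat[j, i] <- unname(ct$estimate)
      p_mat[i, j] <- p_mat[j, i] <- ct$p.value
    }
  }
  if (adjust == "bonferroni") {
    m <- p * (p - 1L) / 2
    p_mat <- pmin(p_mat * m, 1)
  }
  structure(list(r = r_mat, p = p_mat, n = nrow(x)),
            class = "trait_correlations")
}

#' Principal component analysis of a trait matrix
#'
#' Column-centred (and, by default, unit-scaled) singular value
#' decomposition of a genotype x trait matrix. The percentage of variance
#' explained comes from the squared singular values and sums to 100 over
#' all components. Signs are fixed deterministically: each loading
#' vector's largest-magnitude element is made positive.
#'
#' @param x Genotype x trait matrix, no missing values.
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @return Object of class `pca_screen`: `loadings` (trait x component),
#'   `scores` (genotype x component), `explained_pct`, `contrib_pct`
#'   (percentage contribution of each trait to each component), `center`,
#'   `scale`.
#' @export
pca_screen <- function(x, standardize = TRUE) {
  x <- as_feature_matrix(x)
  if (anyNA(x)) stop("missing values in trait matrix", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 genotypes and 2 traits", call. = FALSE)
  }
  if (standardize && any(apply(x, 2L, stats::sd) == 0)) {
    stop("constant trait column(s) cannot be standardized: ",
         paste(colnames(x)[apply(x, 2L, stats::sd) == 0], collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(fit$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(fit$rotation, 2L, flip, `*`)
  scores <- sweep(fit$x, 2L, flip, `*`)
  ev <- fit$sdev ^ 2
  structure(list(
    loadings = loadings,
    scores = scores,
    explained_pct = 100 * ev / sum(ev),
    contrib_pct = 100 * loadings ^ 2,
    center = fit$center,
    scale = if (standardize) fit$scale else NULL
  ), class = "pca_screen")
}

#' @export
print.pca_screen <- function(x, ...) {
  cat("Principal components of", nrow(x$scores), "genotypes x",
      nrow(x$loadings), "traits\n")
  ex <- x$explained_pct
  cat(sprintf("  PC%d: %.1f%%", seq_along(ex), ex)[seq_len(min(4L, length(ex)))],
      "\n")
  invisible(x)
}

#' Mean-threshold genotype selection from a PCA
#'
#' Reproduces the panel-screening step: genotypes are labelled by the sign
#' quadrant of their first two principal-component scores, each genotype is
#' flagged superior on a selection trait when its mean exceeds the panel
#' mean of that trait (the mean acts as the selection threshold), and a
#' representative set is chosen covering every occupied quadrant with, where
#' available, both a superior and an inferior genotype per quadrant.
#'
#' @param scores A [pca_screen()] result.
#' @param trait_means Tibble or matrix of per-genotype means of the
#'   selection traits (rows aligned by genotype name).
#' @param selection_traits Character vector of trait columns to threshold
#'   on; must be non-empty.
#' @return Tibble: `genotype`, `PC1`, `PC2`, `quadrant`,
#'   `superior_<trait>` flags, `n_superior`, `selected`.
#' @export
select_genotypes <- function(scores, trait_means, selection_traits) {
  stopifnot(inherits(scores, "pca_screen"))
  if (length(selection_traits) == 0L) {
    stop("selection_traits must be non-empty", call. = FALSE)
  }
  tm <- as_feature_matrix(trait_means)
  stopifnot(all(selection_traits %in% colnames(tm)))
  genos <- rownames(scores$scores)
  tm <- tm[genos, selection_traits, drop = FALSE]
  pc1 <- scores$scores[, 1L]
  pc2 <- if (ncol(scores$scores) >= 2L) scores$scores[, 2L] else rep(0, length(pc1))
  if (all(abs(pc1) < 1e-12 & abs(pc2) < 1e-12) ||
      all(apply(tm, 2L, stats::sd) == 0)) {
    stop("no contrast among genotypes: scores and selection traits are all ",
         "at the threshold", call. = FALSE)
  }
  quadrant <- paste0(ifelse(pc1 >= 0, "+", "-"), "PC1",
                     ifelse(pc2 >= 0, "+", "-"), "PC2")
  superior <- sweep(tm, 2L, colMeans(tm), `>`)
  colnames(superior) <- paste0("superior_", selection_traits)
  out <- tibble::tibble(genotype = genos, PC1 = pc1, PC2 = pc2,
                        quadrant = quadrant) |>
    dplyr::bind_cols(tibble::as_tibble(superior)) |>
    dplyr::mutate(n_superior = rowSums(superior))
  picks <- out |>
    dplyr::group_by(.data$quadrant) |>
    dplyr::reframe(genotype = unique(c(
      .data$genotype[which.max(.data$n_superior)],
      .data$genotype[which.min(.data$n_superior)])))
  out$selected <- out$genotype %in% picks$genotype
  out
}

#' Ward-D2 clustering with row Z-score scaling
#'
#' Heat-map style double clustering: each row of the item x feature matrix
#' is optionally standardised to mean 0 and unit standard deviation
#' (Z = (x - mu) / sigma), then items and features are clustered
#' agglomeratively with Ward's D2 criterion on Euclidean distances, and
#' flat item labels are obtained by cutting the item dendrogram at `k`
#' clusters.
#'
#' @param x Item x feature numeric matrix (rownames = item ids).
#' @param scale_rows Apply row Z-score scaling (default `TRUE`).
#' @param k Number of flat clusters to cut (default 2).
#' @return Object of class `ward_cluster`: `item_hclust`, `feature_hclust`,
#'   `scaled` (the matrix actually clustered), `labels` (named integer
#'   vector), `k`.
#' @export
ward_cluster <- function(x, scale_rows = TRUE, k = 2L) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 items", call. = FALSE)
  if (scale_rows) {
    rs <- apply(x, 1L, stats::sd)
    if (any(rs == 0)) {
      stop("constant row(s) cannot be Z-scaled: ",
           paste(rownames(x)[rs == 0], collapse = ", "), call. = FALSE)
    }
    x <- (x - rowMeans(x)) / rs
  }
  item_hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  feature_hc <- if (ncol(x) >= 2L) {
    stats::hclust(stats::dist(t(x)), method = "ward.D2")
  } else NULL
  k <- min(k, nrow(x))
  labels <- stats::cutree(item_hc, k = k)
  structure(list(item_hclust = item_hc, feature_hclust = feature_hc,
                 scaled = x, labels = labels, k = k),
            class = "ward_cluster")
}

#' @export
print.ward_cluster <- function(x, ...) {
  cat("Ward-D2 clustering of", nrow(x$scaled), "items x", ncol(x$scaled),
      "features;", x$k, "flat clusters\n")
  print(table(x$labels))
  invisible(x)
}
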