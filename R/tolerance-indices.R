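# Stress tolerance and susceptibility indices for genotype screening.
#
# Notation: y_ns and y_s are a genotype's mean for one trait under control
# (non-stress) and deficient (stress) conditions; ybar_ns and ybar_s are
# the unweighted grand means of those genotype means over the panel.
#
#   MPI = (y_ns + y_s) / 2            tolerant = maximum
#   MRP = y_s/ybar_s + y_ns/ybar_ns   tolerant = maximum
#   REI = (y_s/ybar_s) * (y_ns/ybar_ns)  tolerant = maximum
#   TOL = y_ns - y_s                  tolerant = minimum
#   STI = (y_ns * y_s) / ybar_ns^2    tolerant = maximum
#   SSI = (1 - y_s/y_ns) / SI         tolerant = minimum
#   DTE = 100 * y_s / y_ns            tolerant = maximum
#
# SI is the Fischer-Maurer stress intensity 1 - ybar_s/ybar_ns, a panel-
# level property of the trait. MRP and REI are the sum and product of the
# same two relative-performance ratios, and MPI/TOL are the mean and the
# difference of the same pair, which gives the exact identities
# y_ns = MPI + TOL/2, y_s = MPI - TOL/2 and DTE = 100 (1 - SSI * SI).

INDEX_NAMES <- c("MPI", "MRP", "REI", "TOL", "STI", "SSI", "DTE_pct")

# selection pattern: does a larger value mean more tolerant?
INDEX_MAXIMISE <- c(MPI = TRUE, MRP = TRUE, REI = TRUE, TOL = FALSE,
                    STI = TRUE, SSI = FALSE, DTE_pct = TRUE)

#' Stress intensity of a treatment contrast
#'
#' SI = 1 - (stress grand mean) / (control grand mean): 0 when the stress
#' treatment leaves the panel mean unchanged, approaching 1 as the stress
#' suppresses the trait completely.
#'
#' @param grand_mean_s Panel grand mean under stress.
#' @param grand_mean_ns Panel grand mean under control, non-zero.
#' @return SI (unitless).
#' @export
stress_intensity <- function(grand_mean_s, grand_mean_ns) {
  if (any(grand_mean_ns == 0)) {
    stop("control grand mean is zero: stress intensity undefined", call. = FALSE)
  }
  1 - grand_mean_s / grand_mean_ns
}

#' Per-genotype control/stress means for one trait
#'
#' Collapses a tidy trait table to one row per genotype with its control
#' and deficient means, the inputs of [compute_indices()]. Grand means are
#' attached as attributes (unweighted means over genotype means; for a
#' balanced design these equal the raw treatment means).
#'
#' @param table Tidy trait table with `genotype`, `treatment` and the trait
#'   column.
#' @param trait Trait column name.
#' @return Tibble `genotype`, `y_ns`, `y_s` with attributes `grand_mean_ns`,
#'   `grand_mean_s`.
#' @export
stress_pairs <- function(table, trait) {
  stopifnot(trait %in% names(table))
  wide <- table |>
    dplyr::group_by(.data$genotype, .data$treatment) |>
    dplyr::summarise(m = mean(.data[[trait]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "m") |>
    dplyr::transmute(genotype = .data$genotype,
                     y_ns = .data$control, y_s = .data$deficient)
  keep <- stats::complete.cases(wide[c("y_ns", "y_s")])
  if (!all(keep)) {
    warning("genotypes without both treatments excluded from grand means: ",
            paste(wide$genotype[!keep], collapse = ", "), call. = FALSE)
  }
  attr(wide, "grand_mean_ns") <- mean(wide$y_ns[keep])
  attr(wide, "grand_mean_s") <- mean(wide$y_s[keep])
  wide
}

#' Tolerance and susceptibility indices per genotype
#'
#' Computes the seven indices (MPI, MRP, REI, TOL, STI, SSI, DTE) for every
#' genotype of one trait. SSI is undefined (NA, with a warning) when the
#' stress intensity is zero; a genotype with a zero control mean has its
#' SSI and DTE set to NA with a warning while the other genotypes remain
#' computable.
#'
#' @param pairs A [stress_pairs()] tibble, or a tidy trait table if `trait`
#'   is given.
#' @param trait Trait column name (when `pairs` is a raw trait table).
#' @return Tibble of class `tolerance_indices`: `genotype`, `y_ns`, `y_s`,
#'   and the seven index columns; the trait's stress intensity and grand
#'   means are attached as attributes (`si`, `grand_mean_ns`,
#'   `grand_mean_s`).
#' @export
compute_indices <- function(pairs, trait = NULL) {
  if (!is.null(trait)) pairs <- stress_pairs(pairs, trait)
  stopifnot(all(c("genotype", "y_ns", "y_s") %in% names(pairs)))
  ybar_ns <- attr(pairs, "grand_mean_ns") %||% mean(pairs$y_ns, na.rm = TRUE)
  ybar_s <- attr(pairs, "grand_mean_s") %||% mean(pairs$y_s, na.rm = TRUE)
  if (ybar_ns == 0 || ybar_s == 0) {
    stop("a grand mean is zero: relative indices undefined", call. = FALSE)
  }
  si <- stress_intensity(ybar_s, ybar_ns)
  y_ns <- pairs$y_ns; y_s <- pairs$y_s
  ratio <- rep(NA_real_, length(y_ns))
  ok <- !is.na(y_ns) & y_ns != 0
  if (any(!ok)) {
    warning("zero or missing control mean for genotype(s) ",
            paste(pairs$genotype[!ok], collapse = ", "),
            ": SSI and DTE set to NA", call. = FALSE)
  }
  ratio[ok] <- y_s[ok] / y_ns[ok]
  out <- tibble::tibble(
    genotype = pairs$genotype,
    y_ns = y_ns, y_s = y_s,
    MPI = (y_ns + y_s) / 2,
    MRP = y_s / ybar_s + y_ns / ybar_ns,
    REI = (y_s / ybar_s) * (y_ns / ybar_ns),
    TOL = y_ns - y_s,
    STI = (y_ns * y_s) / ybar_ns ^ 2,
    SSI = NA_real_,
    DTE_pct = 100 * ratio
  )
  if (si == 0) {
    warning("stress intensity is zero: SSI undefined for every genotype",
            call. = FALSE)
  } else {
    out$SSI <- (1 - ratio) / si
  }
  structure(out, si = si, grand_mean_ns = ybar_ns, grand_mean_s = ybar_s,
            class = c("tolerance_indices", class(out)))
}

#' Rank genotypes by a tolerance index
#'
#' Applies the index's selection pattern (maximum value = tolerant for MPI,
#' MRP, REI, STI and DTE; minimum value = tolerant for TOL and SSI): rank 1
#' is the most tolerant genotype, ties share the mean rank, and each
#' genotype is labelled `"tolerant"` or `"susceptible"` by whether it ranks
#' in the better half of the panel.
#'
#' @param indices A [compute_indices()] result.
#' @param index_name One of `"MPI"`, `"MRP"`, `"REI"`, `"TOL"`, `"STI"`,
#'   `"SSI"`, `"DTE_pct"` (`"DTE"` accepted).
#' @return The input with `rank` and `label` columns, sorted by rank.
#' @export
classify_genotypes <- function(indices, index_name) {
  if (identical(index_name, "DTE")) index_name <- "DTE_pct"
  index_name <- match.arg(index_name, INDEX_NAMES)
  x <- indices[[index_name]]
  if (all(is.na(x))) {
    stop("all values of ", index_name, " are missing; cannot rank", call. = FALSE)
  }
  if (sum(!is.na(x)) < 2L) {
    stop("need at least two genotypes with defined ", index_name, call. = FALSE)
  }
  direction <- if (INDEX_MAXIMISE[[index_name]]) -1 else 1
  rk <- rank(direction * x, ties.method = "average", na.last = "keep")
  out <- indices |>
    dplyr::mutate(rank = rk,
                  label = dplyr::if_else(rk <= sum(!is.na(rk)) / 2,
                                         "tolerant", "susceptible")) |>
    dplyr::arrange(.data$rank)
  out
}

#' Correlation between tolerance indices and stress-condition trait means
#'
#' Pearson correlation of each index vector with the genotype means of a
#' trait measured under the deficient condition -- the screen used to judge
#' which indices track performance under stress.
#'
#' @param indices A [compute_indices()] result.
#' @param trait_means Numeric vector of deficient-condition genotype means,
#'   aligned with `indices$genotype`, or a named vector matched by name.
#' @return Tibble `index`, `r`, `p_value`; constant vectors yield NA with a
#'   warning.
#' @export
index_trait_correlation <- function(indices, trait_means) {
  if (!is.null(names(trait_means))) {
    trait_means <- trait_means[indices$genotype]
  }
  stopifnot(length(trait_means) == nrow(indices))
  if (nrow(indices) < 3L) stop("need at least 3 genotypes", call. = FALSE)
  purrr::map_dfr(INDEX_NAMES, function(nm) {
    x <- indices[[nm]]
    ok <- stats::complete.cases(x, trait_means)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(trait_means[ok]) == 0) {
      warning("constant or insufficient values for ", nm,
              ": correlation undefined", call. = FALSE)
      return(tibble::tibble(index = nm, r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(x[ok], trait_means[ok], method = "pearson")
    tibble::tibble(index = nm, r = unname(ct$estimate), p_value = ct$p.value)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
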