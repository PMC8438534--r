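# Derived physiological quantities: phosphorus utilisation efficiency,
# dry-matter contribution percentages, and treatment-relative differences.

#' Phosphorus utilisation efficiency
#'
#' PUE = (tissue P content under control - tissue P content under
#' deficiency) / phosphorus applied. Computed separately for shoot and root
#' tissue in practice. The result may be negative when a genotype
#' accumulates more P under deficiency. The denominator's units (per plant
#' or per unit medium) are whatever the experimenter supplied; the ratio is
#' reported on that basis.
#'
#' @param p_content_control P content under control, mg/g dry weight.
#' @param p_content_deficient P content under deficiency, mg/g dry weight.
#' @param p_applied Amount of phosphorus applied, > 0.
#' @return PUE (vectorised over the first two arguments).
#' @export
pue <- function(p_content_control, p_content_deficient, p_applied) {
  if (length(p_applied) != 1L || !is.finite(p_applied) || p_applied <= 0) {
    stop("p_applied must be a single positive number", call. = FALSE)
  }
  (p_content_control - p_content_deficient) / p_applied
}

#' Contribution percentage of a plant part
#'
#' The generic kernel behind the five contribution formulas: 100 x part /
#' denominator, where the denominator selects the reference pool (total
#' leaf weight, total dry weight, shoot dry weight, or root dry weight).
#'
#' @param part_weight Weight of the part, >= 0 (g).
#' @param denominator_weight Reference weight, > 0 (g).
#' @return Percentage (vectorised).
#' @export
contribution_percent <- function(part_weight, denominator_weight) {
  if (any(!is.finite(denominator_weight)) || any(denominator_weight <= 0)) {
    stop("denominator_weight must be positive", call. = FALSE)
  }
  if (any(part_weight < 0)) stop("part_weight must be >= 0", call. = FALSE)
  100 * part_weight / denominator_weight
}

#' Relative difference between treatments
#'
#' 100 x (deficient - control) / control; positive values mean the trait
#' increased under phosphorus deficiency (e.g. average root diameter),
#' negative values a decrease (e.g. root tip number).
#'
#' @param control_value Trait value under control, non-zero.
#' @param deficient_value Trait value under deficiency.
#' @return Percent change (vectorised).
#' @export
relative_difference <- function(control_value, deficient_value) {
  if (any(control_value == 0)) {
    stop("control_value must be non-zero", call. = FALSE)
  }
  100 * (deficient_value - control_value) / control_value
}

#' Per-leaf and per-part contribution table
#'
#' For every replicate, computes the five contribution quantities from the
#' part dry weights, then averages over replicates within genotype x
#' treatment (contributions are formed per replicate, not from averaged
#' weights, so within-genotype variation propagates correctly):
#'
#' * `own_pct`: individual leaf / total leaf weight x 100
#' * `total_pct`: individual leaf / total dry weight x 100
#' * `partition_pct`: each part (leaves, stem, root) / total dry weight x 100
#' * `to_shoot_pct`: individual leaf / shoot dry weight x 100
#' * `to_root_pct`: individual leaf / root dry weight x 100 (can exceed 100)
#'
#' Total dry weight is the sum of all leaf, stem and root columns; shoot dry
#' weight the sum of leaves and stem.
#'
#' @param table Tidy trait table (see [read_trait_table()]) whose columns
#'   include the per-position leaf weights plus stem and root weights.
#' @param leaf_cols Names of the individual leaf dry-weight columns, in
#'   positional order from the base.
#' @param stem_col,root_col Names of the stem and root dry-weight columns.
#' @return Tibble with one row per genotype x treatment x part:
#'   `part` (leaf position label, `"stem"` or `"root"`), `own_pct`
#'   (leaves only), `total_pct` (leaves only), `partition_pct`,
#'   `to_shoot_pct`, `to_root_pct` (leaves only).
#' @export
contribution_table <- function(table, leaf_cols, stem_col = "stem_dw",
                               root_col = "root_dw") {
  stopifnot(all(c(leaf_cols, stem_col, root_col) %in% names(table)))
  parts <- c(leaf_cols, stem_col, root_col)
  long <- table |>
    dplyr::mutate(
      .total_leaf = rowSums(dplyr::pick(dplyr::all_of(leaf_cols))),
      .total = rowSums(dplyr::pick(dplyr::all_of(parts))),
      .shoot = .data$.total_leaf + .data[[stem_col]],
      .root = .data[[root_col]] # kept aside: the part columns get pivoted
    ) |>
    tidyr::pivot_longer(dplyr::all_of(parts), names_to = "part",
                        values_to = ".w") |>
    dplyr::mutate(
      is_leaf = .data$part %in% leaf_cols,
      own_pct = ifelse(.data$is_leaf,
                       contribution_percent(.data$.w, .data$.total_leaf), NA_real_),
      total_pct = ifelse(.data$is_leaf,
                         contribution_percent(.data$.w, .data$.total), NA_real_),
      partition_pct = contribution_percent(.data$.w, .data$.total),
      to_shoot_pct = ifelse(.data$is_leaf,
                            contribution_percent(.data$.w, .data$.shoot), NA_real_),
      to_root_pct = ifelse(.data$is_leaf,
                           contribution_percent(.data$.w, .data$.root),
                           NA_real_)
    )
  long |>
    dplyr::group_by(.data$genotype, .data$treatment, .data$part) |>
    dplyr::summarise(dplyr::across(dplyr::ends_with("_pct"),
                                   ~ mean(.x, na.rm = FALSE)),
                     .groups = "drop") |>
    dplyr::mutate(part = factor(.data$part, levels = parts)) |>
    dplyr::arrange(.data$genotype, .data$treatment, .data$part) |>
    dplyr::mutate(part = as.character(.data$part))
}
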