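# Pipeline driver: simulate -> extract -> indices -> screen, with a run
# manifest for reproducibility. All randomness flows from the single
# config seed.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic stage.
#' @param trait_table Optional path to an existing trait-table CSV; when
#'   `NULL` a table is simulated from `sim`.
#' @param sim A [sim_model()] used when `trait_table` is `NULL` (its own
#'   seed is overridden by `seed`).
#' @param traits Trait names to simulate / analyse.
#' @param images_dir Optional directory of plant PNGs; when `NULL`,
#'   `n_images` synthetic top views are rendered into `out_dir/images`.
#' @param n_images Number of synthetic images when `images_dir` is `NULL`.
#' @param thresholds [hsb_thresholds()] for segmentation.
#' @param selection_traits Traits thresholded in [select_genotypes()].
#' @param k Flat cluster count for [ward_cluster()].
#' @param standardize Standardize traits in [pca_screen()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            trait_table = NULL,
                            sim = sim_model(),
                            traits = c("shoot_length", "shoot_dw", "root_dw",
                                       "mec_diameter"),
                            images_dir = NULL,
                            n_images = 3L,
                            thresholds = hsb_thresholds(),
                            selection_traits = traits[1:2],
                            k = 2L,
                            standardize = TRUE) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L,
            inherits(sim, "sim_model"), inherits(thresholds, "hsb_thresholds"),
            length(traits) >= 2L, all(selection_traits %in% traits))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 trait_table = trait_table, sim = sim, traits = traits,
                 images_dir = images_dir, n_images = as.integer(n_images),
                 thresholds = thresholds, selection_traits = selection_traits,
                 k = as.integer(k), standardize = standardize),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [pipeline_config()] arguments; `sim` and
#' `thresholds` may be given as nested maps of their constructor arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$sim)) args$sim <- do.call(sim_model, y$sim)
  if (!is.null(y$thresholds)) {
    args$thresholds <- do.call(hsb_thresholds, y$thresholds)
  }
  do.call(pipeline_config, args)
}

#' Run the full screening pipeline
#'
#' Executes the stages in order -- `simulate` (trait table and images,
#' unless supplied), `extract` (image-derived geometric traits), `indices`
#' (tolerance indices per trait), `screen` (ANOVA, heritability,
#' correlations, PCA with genotype selection, Ward clustering) -- writing
#' every stage output as CSV under `config$out_dir` and finally a JSON
#' manifest with the config snapshot, seed, package version, per-file MD5
#' checksums and any warnings. A failing stage stops the run, leaving
#' prior outputs in place and the manifest marking which stage failed.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phosphoscreen")),
    seed = config$seed,
    config = config_snapshot(config),
    stages = list(), warnings = character(0), files = list()
  )
  log_warning <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(name, code) {
    result <- tryCatch(
      withCallingHandlers(code(), warning = log_warning),
      error = function(e) e)
    if (inherits(result, "error")) {
      manifest$stages[[name]] <<- "failed"
      write_manifest(manifest, out)
      stop("stage '", name, "' failed: ", conditionMessage(result),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- "ok"
    result
  }

  # -- simulate ------------------------------------------------------------
  sim_out <- run_stage("simulate", function() {
    if (is.null(config$trait_table)) {
      model <- config$sim
      model$seed <- config$seed
      tab <- simulate_trait_table(model, config$traits)$table
      write_trait_table(tab, file.path(out, "traits.csv"))
    } else {
      tab <- read_trait_table(config$trait_table)
    }
    img_dir <- config$images_dir
    if (is.null(img_dir)) {
      img_dir <- file.path(out, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (i in seq_len(config$n_images)) {
        spec <- random_plant_spec(config$seed + i)
        write_plant_image(render_plant(spec, "top", seed = config$seed + i),
                          file.path(img_dir, sprintf("plant%02d.png", i)))
      }
    }
    list(table = tab, img_dir = img_dir)
  })
  tab <- sim_out$table

  # -- extract -------------------------------------------------------------
  run_stage("extract", function() {
    paths <- sort(list.files(sim_out$img_dir, "\\.png$", full.names = TRUE))
    if (length(paths) == 0L) {
      stop("no PNG images in ", sim_out$img_dir, call. = FALSE)
    }
    geo <- extract_image_traits(paths, thresholds = config$thresholds)
    readr::write_csv(geo, file.path(out, "image_traits.csv"))
  })

  # -- indices -------------------------------------------------------------
  run_stage("indices", function() {
    si <- list()
    for (tr in config$traits) {
      idx <- compute_indices(tab, trait = tr)
      si[[tr]] <- attr(idx, "si")
      ranked <- Reduce(function(acc, nm) {
        r <- classify_genotypes(idx, nm)
        acc[[paste0("rank_", nm)]] <-
          r$rank[match(acc$genotype, r$genotype)]
        acc
      }, INDEX_NAMES[colSums(!is.na(idx[INDEX_NAMES])) >= 2L], init = idx)
      readr::write_csv(as.data.frame(ranked),
                       file.path(out, paste0("indices_", tr, ".csv")))
    }
    jsonlite::write_json(si, file.path(out, "stress_intensity.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  # -- screen --------------------------------------------------------------
  run_stage("screen", function() {
    anova_tab <- purrr::map_dfr(config$traits, function(tr) {
      dplyr::bind_cols(tibble::tibble(trait = tr), two_way_anova(tab, tr))
    })
    readr::write_csv(anova_tab, file.path(out, "anova.csv"))

    herit <- purrr::map_dfr(config$traits, function(tr) {
      dplyr::bind_rows(heritability(tab, tr, "control"),
                       heritability(tab, tr, "deficient"))
    })
    readr::write_csv(herit, file.path(out, "heritability.csv"))

    m <- trait_matrix(tab, config$traits, treatment = "deficient")
    cm <- correlation_matrix(m)
    readr::write_csv(as.data.frame(cm$r) |> tibble::rownames_to_column("trait"),
                     file.path(out, "corr.csv"))
    readr::write_csv(as.data.frame(cm$p) |> tibble::rownames_to_column("trait"),
                     file.path(out, "corr_p.csv"))

    pca <- pca_screen(m, standardize = config$standardize)
    readr::write_csv(as.data.frame(pca$loadings) |>
                       tibble::rownames_to_column("trait"),
                     file.path(out, "pca_loadings.csv"))
    readr::write_csv(as.data.frame(pca$scores) |>
                       tibble::rownames_to_column("genotype"),
                     file.path(out, "pca_scores.csv"))

    sel <- select_genotypes(pca, m, config$selection_traits)
    readr::write_csv(sel, file.path(out, "selection.csv"))

    cl <- ward_cluster(m, scale_rows = TRUE, k = config$k)
    readr::write_csv(tibble::tibble(genotype = names(cl$labels),
                                    cluster = unname(cl$labels)),
                     file.path(out, "clusters.csv"))
    readr::write_csv(as.data.frame(cl$scaled) |>
                       tibble::rownames_to_column("genotype"),
                     file.path(out, "scaled_matrix.csv"))
  })

  files <- sort(list.files(out, "\\.(csv|png|json)$", recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  manifest$files <- as.list(tools::md5sum(file.path(out, files)))
  names(manifest$files) <- files
  write_manifest(manifest, out)
  invisible(manifest)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$sim <- unclass(snap$sim)
  snap$thresholds <- unclass(snap$thresholds)
  snap
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}
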