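#' Full pipeline configuration
#'
#' Bundles the settings of every stage: synthetic generation, central crop,
#' GLCM quantization, sequential forward selection, and both classifiers.
#' A serialized copy is written into every run directory.
#'
#' @param generator A [generator_config()] list.
#' @param crop Central crop size in pixels.
#' @param glcm_levels,glcm_distance GLCM settings.
#' @param select_max_k,select_min_improvement,select_folds Selection settings.
#' @param ann_hidden Hidden-layer size, or `"scan"` to search 5-20 by
#'   validation accuracy.
#' @param ann_max_epochs,ann_patience ANN training settings.
#' @param svm_kernel `"radial"` or `"linear"`.
#' @param ann_split,svm_split Partition fractions for the two classifiers.
#' @param master_seed Single seed from which all randomness derives.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       crop = 192L, glcm_levels = 32L, glcm_distance = 1L,
                       select_max_k = 20L, select_min_improvement = 1e-3,
                       select_folds = 5L,
                       ann_hidden = 10L, ann_max_epochs = 150L, ann_patience = 8L,
                       svm_kernel = "radial",
                       ann_split = c(train = 0.6, validation = 0.2, test = 0.2),
                       svm_split = c(train = 0.8, validation = 0, test = 0.2),
                       master_seed = 42L) {
  generator$master_seed <- as.integer(master_seed)
  structure(
    list(
      generator = generator, crop = as.integer(crop),
      glcm_levels = as.integer(glcm_levels),
      glcm_distance = as.integer(glcm_distance),
      select_max_k = as.integer(select_max_k),
      select_min_improvement = select_min_improvement,
      select_folds = as.integer(select_folds),
      ann_hidden = ann_hidden, ann_max_epochs = as.integer(ann_max_epochs),
      ann_patience = as.integer(ann_patience), svm_kernel = svm_kernel,
      ann_split = ann_split, svm_split = svm_split,
      master_seed = as.integer(master_seed)
    ),
    class = "run_config"
  )
}

config_to_list <- function(config) {
  cfg <- unclass(config)
  cfg$generator$products <- lapply(cfg$generator$products, unclass)
  cfg$generator$adulterant <- unclass(cfg$generator$adulterant)
  # named vectors become YAML maps only as lists
  cfg$ann_split <- as.list(cfg$ann_split)
  cfg$svm_split <- as.list(cfg$svm_split)
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` invisibly returns `config`; `read_run_config`
#'   the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  d <- yaml::read_yaml(path)
  gen <- d$generator
  gen$products <- lapply(gen$products, function(p) {
    powder_spec(p$name, unlist(p$color_mean), unlist(p$color_sd),
                p$granule_scale, p$illumination_sd)
  })
  a <- gen$adulterant
  gen$adulterant <- powder_spec(a$name, unlist(a$color_mean), unlist(a$color_sd),
                                a$granule_scale, a$illumination_sd)
  gen$levels <- unlist(gen$levels)
  d$ann_split <- unlist(d$ann_split)
  d$svm_split <- unlist(d$svm_split)
  do.call(run_config, c(
    list(generator = do.call(generator_config, gen)),
    d[setdiff(names(d), c("generator", "master_seed"))],
    list(master_seed = d$master_seed)
  ))
}

# Train + evaluate both classifiers on one product's feature table.
classify_product <- function(tb, selection, config, seed) {
  feats <- selection$selected
  cls <- fraction_to_class(tb$fraction, config$generator$levels)

  # ANN: 60/20/20 stratified split
  tb_ann <- split_data(tb, config$ann_split, seed = derive_seed(seed, 1L))
  tr <- tb_ann$.split == "train"; va <- tb_ann$.split == "validation"
  x <- as.matrix(tb_ann[feats])
  ann <- if (identical(config$ann_hidden, "scan")) {
    scan_ann_hidden(x[tr, , drop = FALSE], cls[tr], x[va, , drop = FALSE],
                    cls[va], n_class = length(config$generator$levels),
                    seed = derive_seed(seed, 2L),
                    max_epochs = config$ann_max_epochs,
                    patience = config$ann_patience)
  } else {
    train_ann(x[tr, , drop = FALSE], cls[tr], x[va, , drop = FALSE], cls[va],
              n_hidden = config$ann_hidden,
              n_class = length(config$generator$levels),
              seed = derive_seed(seed, 2L),
              max_epochs = config$ann_max_epochs,
              patience = config$ann_patience)
  }
  ann_eval <- evaluate(ann, tb_ann, levels = config$generator$levels)

  # SVM: 80/20 stratified split
  tb_svm <- split_data(tb, config$svm_split, seed = derive_seed(seed, 3L))
  tr2 <- tb_svm$.split == "train"
  x2 <- as.matrix(tb_svm[feats])
  cls2 <- fraction_to_class(tb_svm$fraction, config$generator$levels)
  svm <- train_svm(x2[tr2, , drop = FALSE], cls2[tr2],
                   kernel = config$svm_kernel, seed = derive_seed(seed, 4L))
  svm_eval <- evaluate(svm, tb_svm, levels = config$generator$levels)

  list(ann = ann, ann_eval = ann_eval, svm = svm, svm_eval = svm_eval)
}

#' Run the complete pipeline
#'
#' Executes, per product: synthetic image generation, central cropping,
#' channel expansion, 266-feature extraction, sequential forward selection,
#' and training plus evaluation of the neural-network and one-against-one
#' SVM classifiers. All artefacts (images, manifest, feature tables,
#' selection JSON, report JSON, config copy) are written under `out_dir`.
#' Rerunning with the same configuration and seed reproduces them.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created if absent).
#' @param keep_images Keep the generated PNGs after extraction (default
#'   `TRUE`); set `FALSE` to reclaim disk space in throwaway runs.
#' @return A `run_report`: list with `per_product` (each holding the
#'   selection, models and `powder_eval`s), `summary` tibble, `config`,
#'   `seed`.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("powdersight_run_"),
                    keep_images = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  seed0 <- config$master_seed

  img_dir <- file.path(out_dir, "images")
  manifest <- generate_dataset(config$generator, img_dir)

  per_product <- list()
  summaries <- list()
  for (prod in unique(manifest$product)) {
    mani_p <- manifest[manifest$product == prod, ]
    tb <- extract_dataset(mani_p, crop = config$crop,
                          glcm_levels = config$glcm_levels,
                          glcm_distance = config$glcm_distance)
    write_feature_table(tb, file.path(out_dir, paste0("features_", prod, ".csv")))

    seed_p <- derive_seed(seed0, match(prod, unique(manifest$product)), 100L)
    sel <- sequential_forward_select(
      tb, max_k = config$select_max_k,
      min_improvement = config$select_min_improvement,
      folds = config$select_folds, seed = seed_p
    )
    write_selection(sel, file.path(out_dir, paste0("selection_", prod, ".json")))

    fit <- classify_product(tb, sel, config, seed_p)
    utils::write.csv(fit$ann_eval$confusion_all,
                     file.path(out_dir, paste0("confusion_ann_", prod, ".csv")))
    utils::write.csv(fit$svm_eval$confusion_all,
                     file.path(out_dir, paste0("confusion_svm_", prod, ".csv")))

    per_product[[prod]] <- c(list(features = tb, selection = sel), fit)
    summaries[[prod]] <- tibble::tibble(
      product = prod,
      n_images = nrow(tb),
      n_selected = length(sel$selected),
      ann_hidden = fit$ann$n_hidden,
      ann_rate_all = fit$ann_eval$rate_all,
      ann_rate_test = fit$ann_eval$rate_test,
      ann_r_all = fit$ann_eval$regression_r$r[
        fit$ann_eval$regression_r$partition == "all"],
      svm_rate_all = fit$svm_eval$rate_all,
      svm_rate_test = fit$svm_eval$rate_test
    )
  }
  summary <- dplyr::bind_rows(summaries)
  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       dataframe = "rows", digits = NA)
  if (!keep_images) unlink(img_dir, recursive = TRUE)

  structure(
    list(per_product = per_product, summary = summary, config = config,
         seed = seed0, out_dir = out_dir),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d products, master seed %d\n",
              nrow(x$summary), x$seed))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_all Per-product summary tibble of the run.
#' @param x A `run_report` object.
#' @param ... Unused.
#' @export
tidy.run_report <- function(x, ...) x$summary
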