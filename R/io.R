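# File formats: TSV manifests with a commented header (format version +
# class vocabulary), 2-page 16-bit grayscale TIFF images (page 1 = red,
# page 2 = green) with a paired-PNG alternative, and dataset read/write
# round trips.  Tabular outputs are TSV, UTF-8, '.' decimal; pixel
# coordinates are row-major with origin top-left.

MANIFEST_VERSION <- "1.0"
MANIFEST_COLUMNS <- c("cell_id", "image", "protein_id", "label", "fold",
                      "quality")
INTENSITY_MAX <- 65535

#' Write / read a 2-channel cell image
#'
#' The primary format is a single 2-page grayscale TIFF (16 bit; page 1 =
#' red, page 2 = green).  Paths ending in `.png` use paired files
#' (`<stem>_red.png`, `<stem>_green.png`, 8 bit).  Intensities are stored
#' on the 16-bit scale 0..65535 (clamped); `save_image` then `load_image`
#' reproduces rounded 16-bit TIFF values exactly.
#'
#' @param pixels 2 x H x W array (or `cell_image`).
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @return `load_image` returns the 2 x H x W numeric array.
#' @export
save_image <- function(pixels, path) {
  if (inherits(pixels, "cell_image")) pixels <- pixels$pixels
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[1] == 2)
  scaled <- pmin(pmax(pixels, 0), INTENSITY_MAX) / INTENSITY_MAX
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    stem <- sub("\\.png$", "", path, ignore.case = TRUE)
    png::writePNG(scaled[1, , ], paste0(stem, "_red.png"))
    png::writePNG(scaled[2, , ], paste0(stem, "_green.png"))
  } else {
    tiff::writeTIFF(list(scaled[1, , ], scaled[2, , ]), path,
                    bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname save_image
#' @export
load_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    stem <- sub("\\.png$", "", path, ignore.case = TRUE)
    pages <- lapply(paste0(stem, c("_red.png", "_green.png")), function(p) {
      if (!file.exists(p)) stop("missing paired PNG: ", p)
      m <- png::readPNG(p)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 2)
      stop("expected 2 channels (pages), found ", length(pages), " in ",
           path)
  }
  d1 <- dim(pages[[1]]); d2 <- dim(pages[[2]])
  if (!identical(d1, d2))
    stop("channel size mismatch: ", paste(d1, collapse = "x"), " vs ",
         paste(d2, collapse = "x"))
  px <- array(0, c(2L, d1[1], d1[2]))
  px[1, , ] <- round(pages[[1]] * INTENSITY_MAX)
  px[2, , ] <- round(pages[[2]] * INTENSITY_MAX)
  px
}

validate_manifest <- function(df, classes = NULL) {
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id: ", df$cell_id[duplicated(df$cell_id)][1])
  bad_fold <- setdiff(unique(df$fold), c("train", "val", "test", "none"))
  if (length(bad_fold))
    stop("invalid fold value(s): ", paste(bad_fold, collapse = ", "))
  # protein-disjoint folds (ignoring "none")
  sub <- df[df$fold != "none", ]
  nf <- tapply(sub$fold, sub$protein_id, function(x) length(unique(x)))
  if (any(nf > 1))
    stop("protein in multiple folds: ",
         paste(names(nf)[nf > 1], collapse = ", "))
  if (!is.null(classes)) {
    bad <- setdiff(unique(df$label), c(classes, "nonCell"))
    if (length(bad)) stop("labels outside vocabulary: ",
                          paste(bad, collapse = ", "))
  }
  invisible(df)
}

#' Write / read a dataset manifest
#'
#' TSV with `#`-prefixed header lines recording the format version and
#' class vocabulary, then columns cell_id, image, protein_id, label,
#' fold, quality.  Reading validates column presence, cell_id uniqueness,
#' fold values, and protein-disjointness of folds (hard error naming the
#' offending protein); with `check_images = TRUE` every referenced image
#' must exist (and parse to 2 x 64 x 64 when `parse_images = TRUE`).
#'
#' @param manifest data.frame with the manifest columns.
#' @param path TSV path.
#' @param classes Class vocabulary recorded in the header.
#' @return `read_manifest` returns the manifest data.frame with the
#'   vocabulary in attribute `"classes"`.
#' @export
write_manifest <- function(manifest, path, classes = core_classes()) {
  validate_manifest(manifest, classes)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# yeastloc manifest v", MANIFEST_VERSION),
               paste0("# classes: ", paste(classes, collapse = ","))), con)
  utils::write.table(manifest[, MANIFEST_COLUMNS], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_images Verify that referenced image files exist.
#' @param parse_images Additionally load each image and check its shape.
#' @export
read_manifest <- function(path, check_images = FALSE, parse_images = FALSE) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  classes <- NULL
  cl_line <- grep("^# classes:", hdr, value = TRUE)
  if (length(cl_line))
    classes <- strsplit(sub("^# classes:\\s*", "", cl_line[1]), ",")[[1]]
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  df$quality <- as.logical(df$quality)
  validate_manifest(df, classes)
  if (check_images || parse_images) {
    base <- dirname(path)
    for (img in df$image) {
      p <- file.path(base, img)
      if (!file.exists(p) &&
          !file.exists(file.path(base, sub("\\.png$", "_red.png", p))))
        stop("referenced image missing: ", img)
      if (parse_images) {
        px <- load_image(p)
        if (!identical(dim(px), c(2L, 64L, 64L)))
          stop("image ", img, " has shape ",
               paste(dim(px), collapse = "x"), ", expected 2x64x64")
      }
    }
  }
  attr(df, "classes") <- classes
  df
}

#' Write a full dataset (images + manifest) to a directory
#'
#' @param ds A `cell_dataset`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cid in names(ds$images))
    save_image(ds$images[[cid]],
               file.path(dir, ds$manifest$image[ds$manifest$cell_id == cid]))
  write_manifest(ds$manifest, file.path(dir, "manifest.tsv"),
                 classes = ds$classes)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.tsv` and image files.
#' @return A `cell_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.tsv"), check_images = TRUE)
  images <- lapply(file.path(dir, man$image), load_image)
  names(images) <- man$cell_id
  structure(list(manifest = man, images = images,
                 classes = attr(man, "classes")),
            class = "cell_dataset")
}

## ---- run configuration and pipeline ----

default_run_config <- function() {
  list(
    seed = 1L,
    simulate = list(classes = core_classes(), proteins_per_class = 6L,
                    cells_per_protein = 12L,
                    fold_fractions = c(0.72, 0.14, 0.14)),
    train = list(scale = "small", epochs = 12L, batch_size = 50L,
                 initial_lr = 0.1, lr_halving_interval = 150L,
                 dropout_rate = 0.15),
    baseline = list(grid = "small"),
    evaluate = list(n_boot = 2000L),
    aggregate = list(prior = 1, min_cells = 10L, top_k = 3L)
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Nested list with stages simulate / train / baseline / evaluate /
#' aggregate and a master seed; unknown keys at either level are rejected
#' to catch typos.  Values not supplied fall back to documented defaults.
#'
#' @param config Partial configuration list (possibly from a YAML file).
#' @return Completed configuration list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (stage in names(config)) {
    if (is.list(defaults[[stage]])) {
      bad <- setdiff(names(config[[stage]]), names(defaults[[stage]]))
      if (length(bad))
        stop("unknown key(s) in '", stage, "': ", paste(bad, collapse = ", "))
      defaults[[stage]] <- utils::modifyList(defaults[[stage]],
                                             config[[stage]])
    } else defaults[[stage]] <- config[[stage]]
  }
  defaults
}

#' Run the full pipeline on synthetic data
#'
#' Simulate -> extract features -> train the network and the baseline ->
#' predict -> evaluate both -> aggregate to protein calls.  Every stage
#' is seeded from the master seed, so identical configurations give
#' identical outputs.
#'
#' @param config A [run_config()] list (or partial list / YAML path).
#' @param out_dir Optional directory for TSV outputs.
#' @param verbose Log stage progress.
#' @return List with the dataset, feature table, trained models,
#'   evaluation reports, and protein-level calls.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, verbose = TRUE) {
  cfg <- run_config(config)
  log_ <- function(...) if (verbose) message("[pipeline] ", ...)
  seed <- cfg$seed
  log_("simulate: ", length(cfg$simulate$classes), " classes, seed ", seed)
  spec <- dataset_spec(classes = cfg$simulate$classes,
                       proteins_per_class = cfg$simulate$proteins_per_class,
                       cells_per_protein = cfg$simulate$cells_per_protein,
                       fold_fractions = cfg$simulate$fold_fractions,
                       seed = seed)
  ds <- generate_dataset(spec)
  man <- ds$manifest
  tr <- man$fold == "train"; va <- man$fold == "val"; te <- man$fold == "test"
  log_("features: ", nrow(man), " cells")
  ft <- extract_feature_table(ds)
  log_("baseline forest")
  grid <- if (identical(cfg$baseline$grid, "small")) rf_grid_small() else rf_grid()
  rf <- train_rf_baseline(ft[tr, ], man$label[tr], ft[va, ], man$label[va],
                          grid, seed = derive_seed(seed, 2L))
  log_("network: ", cfg$train$epochs, " epochs")
  ncfg <- if (identical(cfg$train$scale, "full"))
    network_config(fc_widths = c(512, 512, length(ds$classes)))
  else {
    nc <- small_network_config(length(ds$classes))
    nc$dropout_rate <- cfg$train$dropout_rate
    nc
  }
  net <- build_network(ncfg, seed = derive_seed(seed, 3L))
  tcfg <- train_config(epochs = cfg$train$epochs,
                       batch_size = cfg$train$batch_size,
                       initial_lr = cfg$train$initial_lr,
                       lr_halving_interval = cfg$train$lr_halving_interval,
                       warmup_iters = 20L, grad_clip = 5,
                       seed = derive_seed(seed, 4L), verbose = verbose)
  cnn <- train_network(net, ds, tcfg)
  log_("predict + evaluate")
  P <- predict_proba(cnn, ds$images[man$cell_id[te]])
  cnn_eval <- evaluate_predictions(man$label[te], predict_class(P),
                                   n_boot = cfg$evaluate$n_boot,
                                   seed = derive_seed(seed, 5L))
  rf_pred <- predict_rf_class(rf, ft[te, ])
  rf_eval <- evaluate_predictions(man$label[te], rf_pred,
                                  n_boot = cfg$evaluate$n_boot,
                                  seed = derive_seed(seed, 6L))
  log_("aggregate proteins")
  calls <- aggregate_proteins(P, man$protein_id[te],
                              prior_alpha = cfg$aggregate$prior,
                              top_k = cfg$aggregate$top_k)
  truth <- tapply(man$label[te], man$protein_id[te], `[`, 1)
  prot <- protein_level_report(calls, truth,
                               min_cells = cfg$aggregate$min_cells)
  res <- list(config = cfg, dataset = ds, features = ft, baseline = rf,
              network = cnn, cnn_eval = cnn_eval, rf_eval = rf_eval,
              protein_calls = calls, protein_report = prot)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    digest <- substr(unname(tools::md5sum(textConnection_write(
      as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE))))), 1, 12)
    write_tsv_prov <- function(df, name) {
      path <- file.path(out_dir, name)
      writeLines(c(sprintf("# yeastloc %s",
                           as.character(utils::packageVersion("yeastloc"))),
                   sprintf("# seed: %d  config: %s", seed, digest)), path)
      suppressWarnings(utils::write.table(df, path, sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          append = TRUE))
    }
    write_tsv_prov(calls, "protein_calls.tsv")
    write_tsv_prov(cnn_eval$per_class, "cnn_per_class.tsv")
    write_tsv_prov(as.data.frame(cnn_eval$confusion), "cnn_confusion.tsv")
  }
  res
}

# md5 of a character vector via a temp file (tools::md5sum is file-based)
textConnection_write <- function(lines) {
  tf <- tempfile()
  writeLines(lines, tf)
  tf
}
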