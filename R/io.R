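# 16-bit TIFF helpers: counts are stored as value/65535, so integer count
# images round-trip losslessly.

array_to_pages <- function(a) {
  if (is.matrix(a)) return(list(a / 65535))
  lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 65535)
}

pages_to_array <- function(pages) {
  if (is.matrix(pages)) pages <- list(pages)
  a <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) a[, , k] <- round(pages[[k]] * 65535)
  if (dim(a)[3] == 1L) a[, , 1] else a
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param a Numeric matrix or 3-D array of integer counts in
#'   `[0, 65535]`.
#' @param path Output path.
#' @export
write_stack_tiff <- function(a, path) {
  tiff::writeTIFF(array_to_pages(a), path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages_to_array(tiff::readTIFF(path, all = TRUE))
}

#' Persist a synthetic dataset to a directory
#'
#' Writes the wide-field movie pair (interleaved acquisition stored as one
#' multi-page TIFF per excitation channel), the transmission images, the
#' confocal Z-stacks (one file per channel), the ROI label image, the
#' ground-truth and negative-control CSVs, the landmark CSV, the true
#' transform JSON and the config YAML.
#'
#' @param ds A `furascope_dataset` with rendered images.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "furascope_dataset"))
  if (is.null(ds$widefield))
    stop("dataset was generated with render_images = FALSE; nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack_tiff(ds$widefield$ch340, file.path(dir, "widefield_340.tif"))
  write_stack_tiff(ds$widefield$ch385, file.path(dir, "widefield_385.tif"))
  write_stack_tiff(ds$widefield$transmission,
                   file.path(dir, "widefield_transmission.tif"))
  write_stack_tiff(ds$roi_labels, file.path(dir, "roi_labels.tif"))
  for (ch in c("TRPA1", "TRPV1", "DAPI"))
    write_stack_tiff(ds$confocal[[ch]],
                     file.path(dir, sprintf("confocal_%s.tif", tolower(ch))))
  write_stack_tiff(ds$confocal$transmission,
                   file.path(dir, "confocal_transmission.tif"))
  utils::write.csv(ds$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(intensity = ds$negative_controls),
                   file.path(dir, "negative_controls.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$landmarks, file.path(dir, "landmarks.csv"),
                   row.names = FALSE)
  write_transform(ds$transform, file.path(dir, "true_transform.json"))
  cfg <- ds$config
  cfg$schedule <- lapply(seq_len(nrow(cfg$schedule)),
                         function(i) as.list(cfg$schedule[i, ]))
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  sched <- do.call(rbind, lapply(cfg$schedule, as.data.frame))
  config <- synth_config(
    n_cells = cfg$n_cells, fraction_neurons = cfg$fraction_neurons,
    fraction_expressing = cfg$fraction_expressing,
    true_correlation = cfg$true_correlation, noise_sd = cfg$noise_sd,
    frame_rate = cfg$frame_rate, schedule = sched,
    transform = cfg$transform,
    rate_rnascope_only = cfg$rate_rnascope_only,
    rate_functional_only = cfg$rate_functional_only,
    seed = cfg$seed, expression_meanlog = cfg$expression_meanlog,
    expression_sdlog = cfg$expression_sdlog, auc_mean = cfg$auc_mean,
    auc_sd = cfg$auc_sd, n_controls = cfg$n_controls)
  labels <- read_stack_tiff(file.path(dir, "roi_labels.tif"))
  storage.mode(labels) <- "integer"
  structure(
    list(
      config = config,
      truth = utils::read.csv(file.path(dir, "ground_truth.csv")),
      traces = NULL,
      roi_labels = labels,
      negative_controls =
        utils::read.csv(file.path(dir, "negative_controls.csv"))$intensity,
      landmarks = utils::read.csv(file.path(dir, "landmarks.csv")),
      transform = read_transform(file.path(dir, "true_transform.json")),
      widefield = list(
        ch340 = read_stack_tiff(file.path(dir, "widefield_340.tif")),
        ch385 = read_stack_tiff(file.path(dir, "widefield_385.tif")),
        transmission =
          read_stack_tiff(file.path(dir, "widefield_transmission.tif"))),
      confocal = list(
        TRPA1 = read_stack_tiff(file.path(dir, "confocal_trpa1.tif")),
        TRPV1 = read_stack_tiff(file.path(dir, "confocal_trpv1.tif")),
        DAPI = read_stack_tiff(file.path(dir, "confocal_dapi.tif")),
        transmission =
          read_stack_tiff(file.path(dir, "confocal_transmission.tif"))),
      measurements = NULL),
    class = "furascope_dataset")
}
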