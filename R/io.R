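#' Write and read binary masks as PNG files
#'
#' Masks are stored as 8-bit grayscale PNGs with values 0/255, one file
#' per frame (`mask_000001.png`, ...).
#'
#' @param masks `[H,W,T]` array or list of binary matrices.
#' @param dir Output directory (created if needed).
#' @return `write_masks` returns the file paths invisibly; `read_masks`
#'   returns a `[H,W,T]` logical array.
#' @export
write_masks <- function(masks, dir) {
  if (is.array(masks) && length(dim(masks)) == 3)
    masks <- lapply(seq_len(dim(masks)[3]), function(k) masks[, , k])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("mask_%06d.png", seq_along(masks)))
  for (k in seq_along(masks))
    png::writePNG((masks[[k]] > 0.5) * 1, paths[k])
  invisible(paths)
}

#' @rdname write_masks
#' @export
read_masks <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop_param("no PNG masks in %s", dir)
  lst <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  })
  array(unlist(lst), c(dim(lst[[1]]), length(lst)))
}

#' Write and read clip frames as PNG files
#'
#' @param frames `[H,W,3,T]` array with values in `[0,1]`.
#' @param dir Frame directory.
#' @return `write_frames` returns paths invisibly; `read_frames` returns
#'   a `[H,W,3,T]` array.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(frames)[4]
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_len(n)))
  for (k in seq_len(n)) png::writePNG(frames[, , , k], paths[k])
  invisible(paths)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop_param("no PNG frames in %s", dir)
  lst <- lapply(files, png::readPNG)
  array(unlist(lst), c(dim(lst[[1]]), length(lst)))
}

#' Write a segmentation dataset to disk with a manifest
#'
#' Images and masks become PNGs; `manifest.csv` lists image path, mask
#' path and participant key per row.
#'
#' @param dataset A `seg_dataset`.
#' @param dir Output directory.
#' @return `write_manifest` returns the manifest path invisibly;
#'   `read_manifest` returns a `seg_dataset`.
#' @export
write_manifest <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  img <- sprintf("images/img_%05d.png", seq_len(n))
  msk <- sprintf("masks/msk_%05d.png", seq_len(n))
  for (k in seq_len(n)) {
    png::writePNG(dataset$images[[k]], file.path(dir, img[k]))
    png::writePNG((dataset$masks[[k]] > 0.5) * 1, file.path(dir, msk[k]))
  }
  manifest <- data.frame(image = img, mask = msk,
                         participant = dataset$participant)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  images <- lapply(file.path(dir, manifest$image), png::readPNG)
  masks <- lapply(file.path(dir, manifest$mask), function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    (m > 0.5) * 1
  })
  structure(list(images = images, masks = masks,
                 participant = manifest$participant,
                 size = dim(images[[1]])[1]),
            class = "seg_dataset")
}

#' Write a cross-validation metrics report as JSON
#'
#' @param cv A `seg_cv` result.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_seg_report <- function(cv, path) {
  stopifnot(inherits(cv, "seg_cv"))
  jsonlite::write_json(list(
    mean_dice = cv$mean_dice, sd_dice = cv$sd_dice,
    mean_iou = cv$mean_iou, sd_iou = cv$sd_iou,
    per_fold = cv$per_fold,
    n_images = nrow(cv$per_image),
    n_participants = nrow(cv$fold_assignment)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save and load generator / run configurations as YAML
#'
#' @param config A named list (e.g. a `clip_spec` or `run_config`).
#' @param path YAML file path.
#' @return `save_config_yaml` returns the path invisibly;
#'   `load_config_yaml` the named list.
#' @export
save_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config_yaml
#' @export
load_config_yaml <- function(path) {
  yaml::read_yaml(path)
}
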