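#' Read and write multi-channel TIFF stacks
#'
#' Stacks are stored as multi-page greyscale TIFFs, one page per (channel, z)
#' plane with each channel's planes contiguous (channel-major page order).
#' Because baseline TIFF writers cannot carry arbitrary physical-size tags,
#' the voxel geometry, channel count and page order are written to a JSON
#' sidecar (`<path>.json`); `read_stack()` consumes the sidecar, and an
#' explicit `voxel` / `n_channels` override always wins over file metadata.
#'
#' Integer intensities up to 65535 survive the round trip bit-exactly
#' (16-bit storage). Non-integer data are rounded on write: the pipeline's
#' acquisition model is integer counts (12-bit cameras / photon counting).
#'
#' @param path TIFF file path.
#' @param voxel Optional [voxel_size()] override. If neither a sidecar nor
#'   an override is available, reading fails naming the missing field.
#' @param n_channels Optional channel-count override (default from sidecar,
#'   else 1).
#' @param stack_id Optional stack label (default from sidecar, else the
#'   file name).
#' @return `read_stack()`: an [image_stack()]; `write_stack()`: `path`,
#'   invisibly.
#' @export
read_stack <- function(path, voxel = NULL, n_channels = NULL, stack_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read stack: file '%s' does not exist", path),
          class = "fociquant_io_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    abort(sprintf("inconsistent page dimensions in '%s'", path),
          class = "fociquant_io_error")
  }
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  nch <- n_channels %||% meta$n_channels %||% 1L
  nch <- as.integer(nch)
  if (length(pages) %% nch != 0L) {
    abort(sprintf("'%s' has %d pages, not divisible by %d channels",
                  path, length(pages), nch),
          class = "fociquant_io_error")
  }
  if (is.null(voxel)) {
    if (is.null(meta$voxel_nm)) {
      abort(paste0("no voxel size for '", path, "': supply `voxel` or provide ",
                   "a '", basename(sidecar), "' sidecar with field voxel_nm"),
            class = "fociquant_io_error")
    }
    voxel <- voxel_size(meta$voxel_nm[1], meta$voxel_nm[2], meta$voxel_nm[3])
  }
  nz <- length(pages) %/% nch
  d2 <- dim(pages[[1]])
  channels <- lapply(seq_len(nch), function(ci) {
    arr <- array(0, c(d2[1], d2[2], nz))
    for (k in seq_len(nz)) arr[, , k] <- pages[[(ci - 1L) * nz + k]]
    arr
  })
  image_stack(channels, voxel = voxel,
              stack_id = stack_id %||% meta$stack_id %||% basename(path))
}

#' @param stack An [image_stack()].
#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  if (!dir.exists(dirname(path))) {
    abort(sprintf("cannot write stack: directory '%s' does not exist", dirname(path)),
          class = "fociquant_io_error")
  }
  mx <- max(vapply(stack$channels, max, numeric(1)), 1)
  if (mx > 65535) {
    abort("intensities exceed 65535; 16-bit TIFF storage cannot hold them losslessly",
          class = "fociquant_io_error")
  }
  nz <- stack_dims(stack)[["nz"]]
  pages <- list()
  for (ch in stack$channels) {
    for (k in seq_len(nz)) {
      pages[[length(pages) + 1L]] <- round(ch[, , k]) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate",
                  reduce = FALSE)
  v <- stack$voxel
  jsonlite::write_json(
    list(stack_id = stack$stack_id,
         n_channels = n_channels(stack),
         voxel_nm = c(v$dx_nm, v$dy_nm, v$dz_nm),
         page_order = "channel_major",
         axes = "yx planes stacked in z"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a scene (stack + truth + seeds + provenance) to a directory
#'
#' @param scene A scene from [make_spot_scene()] or [make_bead_field()].
#' @param dir Output directory (created if missing).
#' @param name Base name for the files.
#' @return A named list of the paths written, invisibly.
#' @export
write_scene <- function(scene, dir, name = scene$stack$stack_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(stack = file.path(dir, paste0(name, ".tif")),
                truth = file.path(dir, paste0(name, "_truth.csv")),
                params = file.path(dir, paste0(name, "_params.json")))
  write_stack(scene$stack, paths$stack)
  utils::write.csv(scene$truth, paths$truth, row.names = FALSE)
  if (!is.null(scene$seeds)) {
    paths$seeds <- file.path(dir, paste0(name, "_seeds.csv"))
    write_seed_points(scene$seeds, paths$seeds)
  }
  jsonlite::write_json(scene$params, paths$params, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(paths)
}

#' Read a truth table CSV written by [write_scene()]
#'
#' @param path CSV path.
#' @return A truth tibble.
#' @export
read_truth <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
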