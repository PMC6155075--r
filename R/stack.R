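#' Multi-channel 3D image stacks
#'
#' An `image_stack` holds one or more co-registered 3D intensity grids plus
#' their physical voxel geometry. Each channel is stored as a base R array
#' with dim `(ny, nx, nz)` — plane matrices (rows = y, columns = x) stacked
#' along the third dimension — and addressed externally by 0-based
#' (x, y, z) voxel indices throughout the package.
#'
#' @param channels A 3D array or a list of 3D arrays of identical
#'   dimensions; intensities must be finite and non-negative.
#' @param voxel A [voxel_size()].
#' @param stack_id Text label carried into every measurement table.
#' @return An object of class `image_stack`.
#' @examples
#' a <- array(0, c(16, 16, 5))
#' s <- image_stack(list(a, a), stack_id = "demo")
#' stack_dims(s)
#' @export
image_stack <- function(channels, voxel = voxel_size(), stack_id = "stack") {
  if (is.array(channels) && length(dim(channels)) == 3L) channels <- list(channels)
  if (!is.list(channels) || length(channels) < 1L) {
    abort("`channels` must be a 3D array or a non-empty list of 3D arrays",
          class = "fociquant_value_error")
  }
  d <- dim(channels[[1]])
  for (i in seq_along(channels)) {
    ch <- channels[[i]]
    if (!is.array(ch) || length(dim(ch)) != 3L) {
      abort(sprintf("channel %d is not a 3D array", i),
            class = "fociquant_value_error")
    }
    if (!identical(dim(ch), d)) {
      abort(sprintf("channel %d has dimensions (%s); channel 1 has (%s)",
                    i, paste(dim(ch), collapse = ","), paste(d, collapse = ",")),
            class = "fociquant_value_error")
    }
    if (anyNA(ch) || any(ch < 0)) {
      abort(sprintf("channel %d contains negative or missing intensities", i),
            class = "fociquant_value_error")
    }
  }
  structure(list(channels = channels, voxel = as_voxel_size(voxel),
                 stack_id = as.character(stack_id)),
            class = "image_stack")
}

is_image_stack <- function(x) inherits(x, "image_stack")

#' @rdname image_stack
#' @param stack An `image_stack`.
#' @return `stack_dims()`: integer (nx, ny, nz); `n_channels()`: integer.
#' @export
stack_dims <- function(stack) {
  d <- dim(stack$channels[[1]])
  c(nx = d[2], ny = d[1], nz = d[3])
}

#' @rdname image_stack
#' @export
n_channels <- function(stack) length(stack$channels)

#' @export
print.image_stack <- function(x, ...) {
  d <- stack_dims(x)
  cat(sprintf("<image_stack> '%s': %d channel(s), %d x %d x %d voxels (x, y, z)\n",
              x$stack_id, n_channels(x), d[1], d[2], d[3]))
  print(x$voxel)
  invisible(x)
}

# resolve a single stack or a named list of stacks against a stack_id column
resolve_stack <- function(stacks, stack_id) {
  if (is_image_stack(stacks)) {
    if (!identical(stacks$stack_id, stack_id)) {
      abort(sprintf("seed table references stack '%s' but the supplied stack is '%s'",
                    stack_id, stacks$stack_id),
            class = "fociquant_value_error")
    }
    return(stacks)
  }
  nm <- vapply(stacks, function(s) s$stack_id, character(1))
  i <- match(stack_id, nm)
  if (is.na(i)) {
    abort(sprintf("no stack with stack_id '%s' among the supplied stacks", stack_id),
          class = "fociquant_value_error")
  }
  stacks[[i]]
}

#' Seed-point tables
#'
#' Seed points mark candidate foci: one row per (stack, locus, channel) with
#' 0-based voxel indices. They emulate the manual identification of signal
#' pairs in interactive analysis; the synthetic generator produces them from
#' ground truth with a configurable click jitter.
#'
#' @param stack_id,locus_id Text identifiers.
#' @param channel_index 1-based channel index into the stack.
#' @param x,y,z 0-based voxel indices (integers).
#' @param role Optional role label for triple geometries
#'   (`"vertex"`, `"arm1"`, `"arm2"`); `NA` for pairs.
#' @return A seed-point tibble.
#' @export
seed_points <- function(stack_id, locus_id, channel_index, x, y, z, role = NA_character_) {
  tibble(stack_id = as.character(stack_id), locus_id = as.character(locus_id),
         channel_index = as.integer(channel_index),
         x = as.integer(x), y = as.integer(y), z = as.integer(z),
         role = as.character(role))
}

#' Read or write a seed-point CSV
#'
#' @param path CSV path with columns `stack_id, locus_id, channel_index,
#'   x, y, z` (and optionally `role`).
#' @param seeds A seed-point tibble.
#' @return `read_seed_points()`: a seed tibble; `write_seed_points()`:
#'   `path`, invisibly.
#' @export
read_seed_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stack_id", "locus_id", "channel_index", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("seed-point file %s is missing column(s): %s",
                  path, paste(miss, collapse = ", ")),
          class = "fociquant_io_error")
  }
  if (is.null(df$role)) df$role <- NA_character_
  seed_points(df$stack_id, df$locus_id, df$channel_index, df$x, df$y, df$z, df$role)
}

#' @rdname read_seed_points
#' @export
write_seed_points <- function(seeds, path) {
  utils::write.csv(seeds, path, row.names = FALSE)
  invisible(path)
}
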