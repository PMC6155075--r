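#' Physical voxel geometry
#'
#' A voxel size records the physical edge lengths of one image element.
#' The default, 64.5 x 64.5 x 150 nm, is the widefield acquisition geometry
#' the rest of the package assumes unless told otherwise (100x/1.40 NA
#' objective, 150 nm z-step).
#'
#' @param dx_nm,dy_nm,dz_nm Physical length of one voxel along x, y and z,
#'   in nanometres. All must be strictly positive.
#' @return An object of class `voxel_size`: a named list with elements
#'   `dx_nm`, `dy_nm`, `dz_nm`.
#' @examples
#' voxel_size()
#' voxel_size(31.9, 31.9, 110)   # gated-STED geometry
#' @export
voxel_size <- function(dx_nm = 64.5, dy_nm = 64.5, dz_nm = 150) {
  v <- list(dx_nm = as.numeric(dx_nm), dy_nm = as.numeric(dy_nm),
            dz_nm = as.numeric(dz_nm))
  if (!all(vapply(v, function(x) is.finite(x) && length(x) == 1L && x > 0,
                  logical(1)))) {
    abort("all voxel edge lengths must be single, finite, strictly positive numbers",
          class = "fociquant_value_error")
  }
  structure(v, class = "voxel_size")
}

#' @export
print.voxel_size <- function(x, ...) {
  cat(sprintf("<voxel_size> %g x %g x %g nm (x, y, z)\n",
              x$dx_nm, x$dy_nm, x$dz_nm))
  invisible(x)
}

is_voxel_size <- function(x) inherits(x, "voxel_size")

as_voxel_size <- function(x) {
  if (is_voxel_size(x)) return(x)
  if (is.numeric(x) && length(x) == 3L) return(voxel_size(x[1], x[2], x[3]))
  abort("`voxel` must be a voxel_size object or a numeric (dx, dy, dz) triple",
        class = "fociquant_value_error")
}

#' Volume of one voxel
#'
#' At the default geometry one voxel is 64.5 * 64.5 * 150 = 624037.5 nm^3,
#' i.e. 6.240375e-4 um^3; this exact product is the bin width used for
#' cumulative volume distributions.
#'
#' @param voxel A [voxel_size()].
#' @return Volume of one voxel, in nm^3 (`voxel_volume_nm3`) or um^3
#'   (`voxel_volume_um3`).
#' @export
voxel_volume_nm3 <- function(voxel = voxel_size()) {
  voxel <- as_voxel_size(voxel)
  voxel$dx_nm * voxel$dy_nm * voxel$dz_nm
}

#' @rdname voxel_volume_nm3
#' @export
voxel_volume_um3 <- function(voxel = voxel_size()) {
  voxel_volume_nm3(voxel) / 1e9
}

#' Convert voxel indices to physical positions
#'
#' Voxel indices are 0-based and may be fractional; positions refer to voxel
#' centres, so index (0, 0, 0) maps to the origin and one unit step along an
#' axis advances by that axis' voxel edge length. The map is linear.
#'
#' @param index A numeric (x, y, z) triple, or an n x 3 matrix / data frame
#'   of such triples (columns x, y, z in voxel units).
#' @param voxel A [voxel_size()].
#' @return Positions in nm, same shape as the input (vector or n x 3 matrix
#'   with columns `x_nm`, `y_nm`, `z_nm`).
#' @examples
#' physical_position(c(10, 0, 0))          # 645 0 0
#' physical_position(c(1, 1, 1))           # 64.5 64.5 150
#' @export
physical_position <- function(index, voxel = voxel_size()) {
  voxel <- as_voxel_size(voxel)
  scale <- c(voxel$dx_nm, voxel$dy_nm, voxel$dz_nm)
  if (is.data.frame(index)) index <- as.matrix(index)
  if (is.matrix(index)) {
    if (ncol(index) != 3L) {
      abort("`index` matrix must have 3 columns (x, y, z)",
            class = "fociquant_value_error")
    }
    out <- sweep(index, 2L, scale, `*`)
    colnames(out) <- c("x_nm", "y_nm", "z_nm")
    return(out)
  }
  if (length(index) != 3L) {
    abort("`index` must be an (x, y, z) triple", class = "fociquant_value_error")
  }
  unname(as.numeric(index) * scale)
}

#' Genomic probe records and spans
#'
#' `probe_record()` builds a one-row tibble describing a FISH probe as a
#' genomic interval; printed probe coordinates are treated as 1-based
#' inclusive (genome-browser convention), so a probe's span is
#' `end - start + 1` bp. `genomic_span()` appends `span_bp` and `span_kb`
#' (rounded half-up to the nearest integer kb) to a probe table.
#'
#' @param name Probe label.
#' @param chrom Chromosome name.
#' @param start_bp,end_bp 1-based inclusive interval, `start_bp >= 1`,
#'   `start_bp <= end_bp`.
#' @return A tibble with columns `name`, `chrom`, `start_bp`, `end_bp`
#'   (and, for `genomic_span()`, `span_bp`, `span_kb`).
#' @examples
#' genomic_span(probe_record("pEx", "chr11", 32129812, 32136918))
#' @export
probe_record <- function(name, chrom, start_bp, end_bp) {
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  if (any(start_bp < 1) || any(start_bp > end_bp)) {
    abort("probe intervals need 1 <= start_bp <= end_bp",
          class = "fociquant_value_error")
  }
  tibble(name = as.character(name), chrom = as.character(chrom),
         start_bp = start_bp, end_bp = end_bp)
}

#' @param probes A probe tibble as built by [probe_record()] (or several
#'   rows bound together).
#' @rdname probe_record
#' @export
genomic_span <- function(probes) {
  stopifnot(all(c("start_bp", "end_bp") %in% names(probes)))
  if (any(probes$start_bp < 1) || any(probes$start_bp > probes$end_bp)) {
    abort("probe intervals need 1 <= start_bp <= end_bp",
          class = "fociquant_value_error")
  }
  dplyr::mutate(as_tibble(probes),
                span_bp = .data$end_bp - .data$start_bp + 1,
                span_kb = floor(.data$span_bp / 1000 + 0.5))
}

#' Mouse alpha-globin probe panel
#'
#' The plasmid and engineered-BAC probes with published mm9 coordinates used
#' to interrogate the mouse alpha-globin self-interacting domain: the five
#' plasmid probes tiling the locus (pEx, pE, pA, pC, pCx) and the engineered
#' COMP BAC insert that spans the domain itself (~64 kb).
#'
#' @return A probe tibble suitable for [genomic_span()].
#' @examples
#' genomic_span(alpha_globin_probes())
#' @export
alpha_globin_probes <- function() {
  dplyr::bind_rows(
    probe_record("pEx",  "chr11", 32129812, 32136918),
    probe_record("pE",   "chr11", 32146280, 32153457),
    probe_record("COMP", "chr11", 32137046, 32200781),
    probe_record("pA",   "chr11", 32201016, 32208529),
    probe_record("pC",   "chr11", 32251235, 32258747),
    probe_record("pCx",  "chr11", 32275986, 32282385)
  )
}

#' Export probes as BED intervals
#'
#' Writes a 4-column BED file (0-based half-open, per the BED convention)
#' from a 1-based inclusive probe table.
#'
#' @param probes A probe tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probes_bed <- function(probes, path) {
  bed <- data.frame(chrom = probes$chrom,
                    start = format(probes$start_bp - 1, scientific = FALSE, trim = TRUE),
                    end   = format(probes$end_bp, scientific = FALSE, trim = TRUE),
                    name  = probes$name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
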