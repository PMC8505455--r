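#' Construct a voxel-grid brain geometry with lobe labels
#'
#' Builds a rectangular 3-D voxel grid with physical voxel dimensions, a
#' per-voxel anatomical lobe label, and an index-to-millimetre mapping.
#' Voxels are enumerated in column-major order (first grid axis fastest).
#' The geometry stands in for an atlas-derived parcellation: every analysis
#' that is performed "per lobe" (stable-voxel selection, the individual-level
#' factor analyses) uses these labels.
#'
#' The default `"octant"` partition splits the grid at the midpoint of each
#' axis and assigns the eight octants cyclically to the four lobes
#' (`frontal`, `parietal`, `temporal-fusiform`, `occipital`), giving each
#' lobe two diagonally opposed blocks.
#'
#' @param grid_shape integer vector of length 3, voxel counts per axis.
#' @param voxel_size_mm positive reals of length 3, physical voxel edge
#'   lengths in millimetres. The default matches a 3.125 x 3.125 x 6 mm
#'   acquisition voxel.
#' @param lobe_partition either the string `"octant"` or a character vector
#'   with one lobe label per voxel.
#' @param origin millimetre coordinate of the corner of voxel (1,1,1); the
#'   affine maps zero-based index (0,0,0) to this origin.
#' @return An object of class `brain_geometry`: a list with elements
#'   `grid_shape`, `voxel_size_mm`, `origin`, `lobe` (character per voxel),
#'   `ijk` (1-based grid indices, voxels x 3), `n_voxels` and
#'   `voxel_volume_mm3`.
#' @examples
#' g <- make_geometry(c(4, 4, 4))
#' table(g$lobe)
#' g$voxel_volume_mm3    # 58.59375 at the default voxel size
#' @export
make_geometry <- function(grid_shape = c(12L, 12L, 8L),
                          voxel_size_mm = c(3.125, 3.125, 6),
                          lobe_partition = "octant",
                          origin = c(0, 0, 0)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop("grid_shape must be three positive integers")
  }
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be three positive numbers")
  }
  nv <- prod(grid_shape)
  ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3]),
                               KEEP.OUT.ATTRS = FALSE))
  if (identical(lobe_partition, "octant")) {
    mid <- grid_shape / 2
    hi <- sweep(ijk, 2, mid, ">")
    oct <- hi[, 1] + 2 * hi[, 2] + 4 * hi[, 3]
    lobe <- LOBE_NAMES[oct %% 4 + 1]
  } else {
    lobe <- as.character(lobe_partition)
    if (length(lobe) != nv) {
      stop("custom lobe_partition must supply one label per voxel")
    }
    bad <- setdiff(unique(lobe), LOBE_NAMES)
    if (length(bad)) stop("unknown lobe label(s): ", paste(bad, collapse = ", "))
  }
  missing_lobe <- setdiff(LOBE_NAMES, unique(lobe))
  if (length(missing_lobe)) {
    stop(sprintf("lobe partition leaves lobe '%s' empty", missing_lobe[1]))
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin = as.numeric(origin),
                 lobe = lobe,
                 ijk = ijk,
                 n_voxels = nv,
                 voxel_volume_mm3 = prod(voxel_size_mm)),
            class = "brain_geometry")
}

#' Millimetre coordinates of voxels
#'
#' @param geometry a [make_geometry()] object.
#' @param voxels optional voxel indices; defaults to all voxels.
#' @return numeric matrix (voxels x 3) of coordinates of voxel corners, i.e.
#'   zero-based grid index times voxel size plus the origin.
#' @export
voxel_mm <- function(geometry, voxels = NULL) {
  ijk <- geometry$ijk
  if (!is.null(voxels)) ijk <- ijk[voxels, , drop = FALSE]
  out <- sweep(sweep(ijk - 1, 2, geometry$voxel_size_mm, "*"),
               2, geometry$origin, "+")
  colnames(out) <- c("x", "y", "z")
  out
}

# Map mm coordinates back to the nearest 1-based grid index (clamped).
mm_to_ijk <- function(geometry, mm) {
  mm <- matrix(mm, ncol = 3)
  ijk <- round(sweep(sweep(mm, 2, geometry$origin, "-"),
                     2, geometry$voxel_size_mm, "/")) + 1
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), geometry$grid_shape[a])
  ijk
}

ijk_to_index <- function(geometry, ijk) {
  g <- geometry$grid_shape
  as.integer(ijk[, 1] + (ijk[, 2] - 1) * g[1] + (ijk[, 3] - 1) * g[1] * g[2])
}

#' @export
print.brain_geometry <- function(x, ...) {
  cat(sprintf("brain_geometry: %d x %d x %d grid (%d voxels), voxel %.4g x %.4g x %.4g mm\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3], x$n_voxels,
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  print(table(x$lobe))
  invisible(x)
}
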