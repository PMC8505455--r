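#' Extract spatial voxel clusters per factor
#'
#' Finds, for every factor, the connected components of the voxels assigned
#' to it, using face adjacency (6-connectivity) by default or full
#' 26-connectivity behind a flag. Components smaller than `min_size` are
#' dropped into the unassigned set. The cluster centroid is the mean of the
#' member voxels' millimetre coordinates.
#'
#' @param assignment integer vector of per-voxel factor indices (`NA` for
#'   unassigned), as returned by [assign_voxels_to_factors()].
#' @param geometry the `brain_geometry` the voxels live on.
#' @param min_size minimum cluster size (default 2 voxels).
#' @param connectivity 6 (face) or 26 (face, edge and corner) adjacency.
#' @return An object of class `cluster_map`: list with `clusters` (each a
#'   list with `factor`, `voxels` (sorted), `size`, `centroid` (mm),
#'   `lobe` of the majority of members), `unassigned` (voxels assigned to a
#'   factor but not in any retained cluster), `connectivity`, `geometry`.
#'   Clusters are ordered by factor then smallest member index, so the
#'   result is invariant to voxel enumeration order.
#' @export
extract_clusters <- function(assignment, geometry, min_size = 2,
                             connectivity = 6) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  assignment <- as.integer(assignment)
  clusters <- list()
  unassigned <- integer(0)
  for (f in sort(unique(assignment[!is.na(assignment)]))) {
    vox <- which(!is.na(assignment) & assignment == f)
    comps <- grid_components(vox, geometry, connectivity)
    for (comp in comps) {
      if (length(comp) >= min_size) {
        mm <- voxel_mm(geometry, comp)
        lb <- names(which.max(table(geometry$lobe[comp])))
        clusters[[length(clusters) + 1]] <-
          list(factor = f, voxels = sort(comp), size = length(comp),
               centroid = colMeans(mm), lobe = lb)
      } else {
        unassigned <- c(unassigned, comp)
      }
    }
  }
  ord <- order(vapply(clusters, function(cl) cl$factor, 1),
               vapply(clusters, function(cl) min(cl$voxels), 1))
  structure(list(clusters = clusters[ord],
                 unassigned = sort(unassigned),
                 connectivity = connectivity,
                 geometry = geometry),
            class = "cluster_map")
}

# Connected components of a voxel set on the grid.
grid_components <- function(voxels, geometry, connectivity = 6) {
  if (!length(voxels)) return(list())
  g <- geometry$grid_shape
  in_set <- new.env(hash = TRUE, size = length(voxels))
  for (v in voxels) assign(as.character(v), TRUE, envir = in_set)
  offsets <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o[rowSums(abs(o)) > 0, , drop = FALSE]
  }
  seen <- logical(length(voxels))
  names(seen) <- as.character(voxels)
  comps <- list()
  for (v in sort(voxels)) {
    if (seen[as.character(v)]) next
    comp <- integer(0)
    queue <- v
    seen[as.character(v)] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      ijk <- geometry$ijk[u, ]
      for (r in seq_len(nrow(offsets))) {
        p <- ijk + offsets[r, ]
        if (any(p < 1) || any(p > g)) next
        w <- ijk_to_index(geometry, matrix(p, ncol = 3))
        key <- as.character(w)
        if (!is.null(in_set[[key]]) && !seen[key]) {
          seen[key] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Combined physical volume of a cluster
#'
#' @param cluster_or_size a cluster entry from a `cluster_map`, or a voxel
#'   count.
#' @param geometry the `brain_geometry` supplying the voxel volume.
#' @return volume in cubic millimetres.
#' @examples
#' g <- make_geometry(c(4, 4, 4))
#' cluster_volume_mm3(2, g)   # 117.1875 at the default voxel size
#' @export
cluster_volume_mm3 <- function(cluster_or_size, geometry) {
  n <- if (is.list(cluster_or_size)) cluster_or_size$size else cluster_or_size
  n * geometry$voxel_volume_mm3
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("cluster_map: %d cluster(s), %d unassigned voxel(s), %d-connectivity\n",
              length(x$clusters), length(x$unassigned), x$connectivity))
  invisible(x)
}

#' Write a cluster map as TSV
#'
#' One row per cluster: factor, size, lobe, centroid x/y/z in mm, member
#' voxel indices (comma separated).
#' @param cluster_map a `cluster_map` or cluster set (list of clusters).
#' @param path output path.
#' @export
write_clusters_tsv <- function(cluster_map, path) {
  cl <- if (inherits(cluster_map, "cluster_map")) cluster_map$clusters else cluster_map
  df <- do.call(rbind, lapply(cl, function(c) {
    data.frame(factor = c$factor, size = c$size,
               lobe = c$lobe %||% NA_character_,
               x = c$centroid[1], y = c$centroid[2], z = c$centroid[3],
               voxels = paste(c$voxels, collapse = ","))
  }))
  if (is.null(df)) df <- data.frame(factor = integer(0), size = integer(0),
                                    lobe = character(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    voxels = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
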