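# Study bundle: a plain-text directory container for a full study
# (geometry, per-participant PSC tensors, concept table, ratings, optional
# ground truth). Numbers are written with 17 significant digits so the
# round trip is bit exact.

fmt_num <- function(x) sprintf("%.17g", x)

BUNDLE_VERSION <- 1L

#' Write a study bundle to disk
#'
#' Serializes a study (geometry, datasets, concept table, optional ratings
#' and ground truth) into a directory of TSV/JSON files. `read_bundle()`
#' restores it bit-exactly.
#'
#' @param bundle list with elements `geometry` (a `brain_geometry`),
#'   `datasets` (list of `activation_dataset`s), `concepts` (data.frame
#'   with at least a `label` column), and optionally `ratings` (a
#'   `ratings_matrix`) and `ground_truth`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  geom <- bundle$geometry
  ids <- vapply(bundle$datasets, function(d) d$participant_id, 1L)
  manifest <- list(format = "neurosem-bundle",
                   version = BUNDLE_VERSION,
                   n_participants = length(bundle$datasets),
                   participant_ids = as.integer(ids),
                   groups = vapply(bundle$datasets, function(d) d$group, ""),
                   n_concepts = nrow(bundle$concepts),
                   n_presentations = if (length(bundle$datasets))
                     dim(bundle$datasets[[1]]$psc)[2] else 0L,
                   has_ratings = !is.null(bundle$ratings),
                   has_ground_truth = !is.null(bundle$ground_truth))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(grid_shape = geom$grid_shape,
                            voxel_size_mm = geom$voxel_size_mm,
                            origin = geom$origin,
                            lobe = geom$lobe),
                       file.path(path, "geometry.json"), digits = NA)
  utils::write.table(bundle$concepts, file.path(path, "concepts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$ratings)) {
    write_ratings_tsv(bundle$ratings, file.path(path, "ratings.tsv"))
  }
  for (d in bundle$datasets) {
    psc <- d$psc
    C <- dim(psc)[1]; P <- dim(psc)[2]; V <- dim(psc)[3]
    flat <- matrix(aperm(psc, c(2, 1, 3)), nrow = C * P)  # rows: (c,p) pairs
    df <- data.frame(concept = rep(seq_len(C), each = P),
                     presentation = rep(seq_len(P), times = C))
    vals <- apply(flat, 2, fmt_num)
    out <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
    colnames(out) <- c("concept", "presentation", paste0("v", seq_len(V)))
    utils::write.table(out,
                       file.path(path, sprintf("psc_%03d.tsv", d$participant_id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$ground_truth)) {
    gtd <- file.path(path, "ground_truth")
    dir.create(gtd, showWarnings = FALSE)
    gt <- bundle$ground_truth
    sc <- gt$concept_scores
    scdf <- data.frame(concept = seq_len(nrow(sc)),
                       apply(sc, 2, fmt_num), check.names = FALSE)
    utils::write.table(scdf, file.path(gtd, "concept_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sparse_load <- function(L, cohort) {
      idx <- which(L != 0, arr.ind = TRUE)
      data.frame(voxel = idx[, 1],
                 dimension = colnames(L)[idx[, 2]],
                 value = fmt_num(L[idx]),
                 cohort = cohort)
    }
    ld <- rbind(sparse_load(gt$loading_map, "faculty"),
                sparse_load(gt$loading_map_student, "student"))
    utils::write.table(ld, file.path(gtd, "loading_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(dimension_names = gt$dimension_names,
                              noise_sd = gt$noise_sd,
                              participant_sd = gt$participant_sd,
                              group_effect = gt$group_effect,
                              seed = gt$seed,
                              cluster_spec = gt$cluster_spec,
                              cluster_spec_student = gt$cluster_spec_student),
                         file.path(gtd, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a study bundle from disk
#'
#' @param path bundle directory written by [write_bundle()].
#' @return a bundle list (see [write_bundle()]); `ground_truth` and
#'   `ratings` are `NULL` when absent.
#' @export
read_bundle <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("missing mandatory group 'manifest' in bundle: ", path)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(manifest$format, "neurosem-bundle")) {
    stop("not a neurosem bundle: ", path)
  }
  if (manifest$version != BUNDLE_VERSION) {
    stop(sprintf("bundle version mismatch: file has %s, reader supports %d",
                 manifest$version, BUNDLE_VERSION))
  }
  gpath <- file.path(path, "geometry.json")
  if (!file.exists(gpath)) stop("missing mandatory group 'geometry' in bundle: ", path)
  g <- jsonlite::read_json(gpath, simplifyVector = TRUE)
  geometry <- make_geometry(g$grid_shape, g$voxel_size_mm, g$lobe, g$origin)
  cpath <- file.path(path, "concepts.tsv")
  if (!file.exists(cpath)) stop("missing mandatory group 'concepts' in bundle: ", path)
  concepts <- utils::read.delim(cpath, stringsAsFactors = FALSE)
  ratings <- NULL
  if (isTRUE(manifest$has_ratings)) {
    ratings <- read_ratings_tsv(file.path(path, "ratings.tsv"))
  }
  datasets <- vector("list", manifest$n_participants)
  for (i in seq_len(manifest$n_participants)) {
    pid <- manifest$participant_ids[i]
    fpath <- file.path(path, sprintf("psc_%03d.tsv", pid))
    if (!file.exists(fpath)) stop("missing mandatory group 'psc' for participant ", pid)
    tab <- utils::read.delim(fpath, stringsAsFactors = FALSE,
                             colClasses = "character")
    C <- manifest$n_concepts; P <- manifest$n_presentations
    V <- ncol(tab) - 2
    if (nrow(tab) != C * P) stop("truncated psc table for participant ", pid)
    vals <- vapply(tab[, -(1:2), drop = FALSE], as.numeric, numeric(nrow(tab)))
    psc <- aperm(array(vals, dim = c(P, C, V)), c(2, 1, 3))
    dimnames(psc) <- list(concepts$label, NULL, NULL)
    datasets[[i]] <- structure(list(participant_id = as.integer(pid),
                                    group = manifest$groups[i],
                                    psc = psc,
                                    concept_labels = concepts$label,
                                    geometry = geometry),
                               class = "activation_dataset")
  }
  ground_truth <- NULL
  gtd <- file.path(path, "ground_truth")
  if (dir.exists(gtd)) {
    pj <- jsonlite::read_json(file.path(gtd, "params.json"), simplifyVector = TRUE)
    scdf <- utils::read.delim(file.path(gtd, "concept_scores.tsv"),
                              colClasses = "character")
    scores <- vapply(scdf[, -1, drop = FALSE], as.numeric, numeric(nrow(scdf)))
    rownames(scores) <- concepts$label
    ld <- utils::read.delim(file.path(gtd, "loading_map.tsv"),
                            stringsAsFactors = FALSE)
    mk_load <- function(cohort) {
      L <- matrix(0, geometry$n_voxels, length(pj$dimension_names),
                  dimnames = list(NULL, pj$dimension_names))
      sub <- ld[ld$cohort == cohort, ]
      L[cbind(sub$voxel, match(sub$dimension, pj$dimension_names))] <-
        as.numeric(sub$value)
      L
    }
    ground_truth <- structure(list(concept_scores = scores,
                                   dimension_names = pj$dimension_names,
                                   loading_map = mk_load("faculty"),
                                   loading_map_student = mk_load("student"),
                                   cluster_spec = pj$cluster_spec,
                                   cluster_spec_student = pj$cluster_spec_student,
                                   noise_sd = pj$noise_sd,
                                   participant_sd = pj$participant_sd,
                                   group_effect = pj$group_effect,
                                   geometry = geometry,
                                   concept_labels = concepts$label,
                                   concept_categories = concepts$category,
                                   seed = as.integer(pj$seed)),
                              class = "ground_truth")
  }
  list(geometry = geometry, datasets = datasets, concepts = concepts,
       ratings = ratings, ground_truth = ground_truth)
}

#' Read a ratings table from TSV
#'
#' Expects a header row (`concept` followed by dimension names) and one
#' concept per row; values must lie in [1, 7]. CRLF and LF line endings
#' parse identically.
#'
#' @param path TSV file path.
#' @return a `ratings_matrix` (concepts x dimensions) with concept row
#'   names.
#' @export
read_ratings_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("ratings table needs a concept column plus dimensions")
  labels <- as.character(tab[[1]])
  dup <- labels[duplicated(labels)]
  if (length(dup)) stop("duplicate concept(s) in ratings: ",
                        paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  bad <- which(!is.finite(vals) | vals < 1 | vals > 7, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("rating out of range [1, 7] at row %d ('%s'), column '%s'",
                 bad[1, 1], labels[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  rownames(vals) <- labels
  structure(vals, rater_count = NA_integer_,
            class = c("ratings_matrix", "matrix", "array"))
}

#' Write a ratings table as TSV
#' @param ratings a `ratings_matrix` (concepts x dimensions, row names =
#'   concept labels).
#' @param path output path.
#' @export
write_ratings_tsv <- function(ratings, path) {
  df <- data.frame(concept = rownames(ratings) %||% seq_len(nrow(ratings)),
                   apply(unclass(ratings), 2, fmt_num), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
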