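#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#' Defaults follow the analysis protocol: 120 stable voxels per lobe, 10
#' individual-level factors, a 0.4 absolute-loading threshold, minimum
#' cluster size 2, 5-voxel cluster means for the forward model, 6-voxel
#' cluster means for the group comparison, 45 concepts presented 6 times,
#' and a >= 4-participant cluster replication filter.
#'
#' @param seed master seed for every stochastic stage.
#' @param grid_shape,voxel_size_mm geometry of the simulated brain.
#' @param n_presentations stimulus presentations per concept.
#' @param n_faculty,n_students cohort sizes.
#' @param noise_sd,participant_sd,group_effect generator noise parameters
#'   (see [sample_ground_truth()]).
#' @param clusters_per_dimension,cluster_size_range planted cluster layout.
#' @param n_raters,rater_noise_sd ratings simulation parameters.
#' @param n_per_lobe stable voxels per lobe for the factor analyses.
#' @param n_factors_individual factors extracted per lobe and participant.
#' @param variance_threshold group-level factor retention threshold, in
#'   eigenvalue units (1 = Kaiser rule).
#' @param loading_threshold absolute loading for voxel-factor assignment.
#' @param min_cluster_size,connectivity spatial clustering parameters.
#' @param n_fa_participants participants (most accurately classified) whose
#'   data enter the two-level factor analysis.
#' @param n_decoding_features stable voxels used by the concept decoders.
#' @param forward_n_voxels,cuboid_radius forward-model cluster features.
#' @param group_n_voxels,min_cluster_participants,n_factors_group_compare
#'   group-comparison parameters.
#' @param stepwise_beam_width beam cap for the stepwise concept search.
#' @param n_permutations label permutations for the decoding p-value
#'   (0 skips the permutation test).
#' @param stages character vector of pipeline stages to run, from
#'   `c("simulate", "decoding", "factors", "forward_model",
#'   "group_compare")`.
#' @param output_dir optional directory for the JSON report and TSV
#'   artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       grid_shape = c(12L, 12L, 8L),
                       voxel_size_mm = c(3.125, 3.125, 6),
                       n_presentations = 6,
                       n_faculty = 10,
                       n_students = 9,
                       noise_sd = 0.1,
                       participant_sd = 0.1,
                       group_effect = 1,
                       clusters_per_dimension = 3,
                       cluster_size_range = c(3L, 9L),
                       n_raters = 6,
                       rater_noise_sd = 1.0,
                       n_per_lobe = 120,
                       n_factors_individual = 10,
                       variance_threshold = 1,
                       loading_threshold = 0.4,
                       min_cluster_size = 2,
                       connectivity = 6,
                       n_fa_participants = 3,
                       n_decoding_features = 120,
                       forward_n_voxels = 5,
                       cuboid_radius = 1,
                       group_n_voxels = 6,
                       min_cluster_participants = 4,
                       n_factors_group_compare = 4,
                       stepwise_beam_width = 10,
                       n_permutations = 99,
                       stages = c("simulate", "decoding", "factors",
                                  "forward_model", "group_compare"),
                       output_dir = NULL) {
  cfg <- as.list(environment())
  known <- c("simulate", "decoding", "factors", "forward_model", "group_compare")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unspecified keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file values.
#' @return a `run_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
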