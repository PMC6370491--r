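# Plain-text serialization: cohort TSV/JSON writers, report round-trip.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write a cohort to a directory of TSV files
#'
#' Writes the atlas (`node_id, x, y, z, subnetwork`), the covariate table,
#' per-subject contaminated signal matrices (nodes x frames), per-subject
#' nuisance channel matrices, and a JSON manifest recording the generation
#' parameters and master seed.
#'
#' @param cohort a `dfc_cohort`.
#' @param dir output directory (created if needed).
#' @param signals write per-subject signal TSVs (default `TRUE`).
#' @param nuisance write per-subject nuisance TSVs (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, signals = TRUE, nuisance = TRUE) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- cohort$atlas
  write_tsv(data.frame(
    node_id = atlas$node_id,
    x = atlas$coord_mm[, 1L], y = atlas$coord_mm[, 2L],
    z = atlas$coord_mm[, 3L],
    subnetwork = atlas$subnetwork_label
  ), file.path(dir, "atlas.tsv"))
  write_tsv(cohort_covariates(cohort), file.path(dir, "covariates.tsv"))

  if (signals || nuisance) {
    dir.create(file.path(dir, "subjects"), showWarnings = FALSE)
    for (s in cohort$subjects) {
      if (signals) {
        write_tsv(as.data.frame(s$contaminated_signals),
                  file.path(dir, "subjects",
                            paste0(s$subject_id, "_signals.tsv")))
      }
      if (nuisance) {
        nu <- cbind(global = s$nuisance$global,
                    s$nuisance$csf_like,
                    s$nuisance$wm$channels)
        colnames(nu) <- c("global",
                          paste0("csf", seq_len(ncol(s$nuisance$csf_like))),
                          paste0("wm", seq_len(ncol(s$nuisance$wm$channels))))
        write_tsv(as.data.frame(nu),
                  file.path(dir, "subjects",
                            paste0(s$subject_id, "_nuisance.tsv")))
      }
    }
  }
  manifest <- list(
    n_subjects = length(cohort$subjects),
    n_nodes = atlas$n_nodes,
    n_subnetworks = atlas$n_subnetworks,
    n_frames = cohort$n_frames,
    tr = cohort$tr,
    seed = cohort$seed,
    model = unclass(cohort$model)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Serialize a benchmark report losslessly
#'
#' Uses type-preserving JSON serialization so that
#' `read_report(write_report(x))` reproduces the report exactly.
#'
#' @param report a `dfc_benchmark_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "dfc_benchmark_report"))
  writeLines(jsonlite::serializeJSON(report, digits = I(17)), path)
  invisible(path)
}

#' Read back a serialized benchmark report
#' @param path file written by [write_report()].
#' @return the `dfc_benchmark_report`.
#' @export
read_report <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Run the full benchmarking study end to end
#'
#' Chains simulate, de-noise, network construction, dispersion,
#' modularity, reconfiguration and benchmarking with one master seed, and
#' writes every product (cohort TSVs and manifest, per-pipeline summary
#' table, full report) under `out_dir`. Identical seeds and parameters
#' produce byte-identical output trees.
#'
#' @param out_dir output directory.
#' @param n_subjects,n_nodes,n_subnetworks,n_epochs cohort dimensions.
#' @param n_frames,tr acquisition parameters.
#' @param beta_spike,lambda_d artifact parameters (other model parameters
#'   take their [artifact_model()] defaults).
#' @param pipelines registry pipeline names to benchmark.
#' @param do_modularity,n_iterations modularity switches.
#' @param seed master seed for the whole run.
#' @param write_subject_files write per-subject signal/nuisance TSVs
#'   (default `TRUE`).
#' @return the `dfc_benchmark_report`, invisibly.
#' @export
run_full_study <- function(out_dir, n_subjects = 30L, n_nodes = 60L,
                           n_subnetworks = 6L, n_epochs = 3L,
                           n_frames = 120L, tr = 3, beta_spike = 1,
                           lambda_d = 40,
                           pipelines = c("NONE", "6P", "36P"),
                           do_modularity = FALSE, n_iterations = 10L,
                           seed = 1L, write_subject_files = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- artifact_model(beta_spike = beta_spike, lambda_d = lambda_d)
  atlas <- generate_atlas(n_nodes, n_subnetworks, n_epochs,
                          seed = derive_seed(seed, 1L))
  cohort <- generate_cohort(n_subjects, atlas, model, n_frames, tr,
                            seed = derive_seed(seed, 2L))
  write_cohort(cohort, file.path(out_dir, "cohort"),
               signals = write_subject_files,
               nuisance = write_subject_files)
  report <- build_report(cohort, pipelines,
                         do_modularity = do_modularity,
                         n_iterations = n_iterations,
                         seed = derive_seed(seed, 3L))
  write_tsv(report_table(report), file.path(out_dir, "benchmark_summary.tsv"))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(report)
}
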