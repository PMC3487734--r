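#' Run configuration
#'
#' A flat key-value configuration for [run_pipeline()]. Replicate
#' trajectories are multiple coordinate files sharing one topology, as in a
#' study design with several independent runs from one starting structure.
#'
#' @param topology path to the topology/structure file (PDB or GRO).
#' @param trajectories character vector of per-replica trajectory files
#'   (DCD or multi-model PDB); may be empty when the topology is
#'   multi-frame.
#' @param stages analysis stages to run, any of `"helicity"`, `"angle"`,
#'   `"jcoupling"`, `"dihedral_fluctuation"`.
#' @param frames frame range specification (see [resolve_frames()]),
#'   e.g. `"last-half"`.
#' @param output_dir directory for TSV outputs and the manifest.
#' @param bin_width interhelical-angle bin width (degrees).
#' @param boundary family boundary (degrees).
#' @param seed seed recorded in the manifest (the analyses themselves are
#'   deterministic).
#' @return config list of class `mh_config`.
#' @export
run_config <- function(topology, trajectories = character(0),
                       stages = c("helicity", "angle", "jcoupling"),
                       frames = "all", output_dir = tempfile("memhelix_run_"),
                       bin_width = 10, boundary = 60, seed = 1L) {
  stopifnot(bin_width > 0, boundary > 0)
  structure(list(topology = topology, trajectories = trajectories,
                 stages = stages, frames = frames, output_dir = output_dir,
                 bin_width = bin_width, boundary = boundary, seed = seed),
            class = "mh_config")
}

#' Load a run configuration from a YAML file
#'
#' Flat key-value document; every key of [run_config()] is recognised.
#'
#' @param path YAML file.
#' @return an `mh_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' Aggregate an observable across replicate trajectories
#'
#' Unweighted mean and sample standard deviation (n - 1 denominator) across
#' replicas; the sd is `NA` for a single replica.
#'
#' @param values numeric vector (one value per replica) or a matrix with
#'   one column per replica.
#' @return for a vector: list with `mean`, `sd`, `n_replicas`; for a
#'   matrix: data.frame with per-row `mean`, `sd`, `n_replicas`.
#' @export
aggregate_replicas <- function(values) {
  if (is.matrix(values)) {
    return(data.frame(mean = rowMeans(values),
                      sd = if (ncol(values) >= 2L)
                        apply(values, 1L, stats::sd) else NA_real_,
                      n_replicas = ncol(values)))
  }
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       n_replicas = length(values))
}

#' Run the peptide analysis pipeline over replicate trajectories
#'
#' Loads the topology, attaches each replica, runs the requested stages on
#' the configured frame range, aggregates per-residue observables across
#' replicas, and writes TSV reports plus a YAML run manifest. A stage
#' failure is recorded in the manifest and the remaining stages proceed.
#'
#' @param config an `mh_config` from [run_config()].
#' @return invisible list with the per-stage results, the manifest, and
#'   `ok` (logical: all stages succeeded).
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  topo <- read_structure(config$topology)
  replicas <- if (length(config$trajectories) == 0L) list(topo) else
    lapply(config$trajectories, function(p)
      attach_trajectory(set_frames(topo, list()), p))
  errors <- list(); results <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) results[[name]] <<- res
  }
  par_block <- list(frames = config$frames,
                    n_replicas = length(replicas), seed = config$seed)
  if ("helicity" %in% config$stages) run_stage("helicity", function() {
    ss <- lapply(replicas, assign_secondary_structure)
    ss <- lapply(ss, function(s)
      s[, resolve_frames(ncol(s), config$frames), drop = FALSE])
    prof <- helicity(ss)
    write_tsv_report(prof, file.path(config$output_dir, "helicity.tsv"),
                     par_block)
    prof
  })
  if ("angle" %in% config$stages) run_stage("angle", function() {
    series <- lapply(replicas, function(r) {
      a <- interhelical_angle(r)
      a[resolve_frames(length(a), config$frames)]
    })
    pooled <- unlist(series)
    dist <- angle_distribution(pooled, config$bin_width)
    fam <- classify_families(pooled, config$boundary)
    write_tsv_report(dist, file.path(config$output_dir, "angle_hist.tsv"),
                     c(par_block, bin_width = config$bin_width,
                       boundary = config$boundary))
    write_tsv_report(
      data.frame(family = names(fam$fractions), fraction = fam$fractions),
      file.path(config$output_dir, "families.tsv"),
      c(par_block, boundary = config$boundary))
    list(distribution = dist, families = fam)
  })
  if ("jcoupling" %in% config$stages) run_stage("jcoupling", function() {
    per <- lapply(replicas, function(r)
      j_profile(backbone_dihedrals(r), frames = config$frames))
    shared <- Reduce(intersect, lapply(per, function(p) p$resseq))
    M <- vapply(per, function(p) p$mean_j[match(shared, p$resseq)],
                numeric(length(shared)))
    agg <- aggregate_replicas(as.matrix(M))
    out <- cbind(data.frame(resseq = shared), agg)
    write_tsv_report(out, file.path(config$output_dir, "jcoupling.tsv"),
                     par_block)
    out
  })
  if ("dihedral_fluctuation" %in% config$stages)
    run_stage("dihedral_fluctuation", function() {
      fl <- lapply(replicas, function(r) {
        dh <- backbone_dihedrals(r)
        dihedral_fluctuation(dh, residues = intersect(c(18L, 19L, 20L),
                                                      dh$resseq))
      })
      write_tsv_report(fl[[1L]],
                       file.path(config$output_dir,
                                 "dihedral_fluctuation.tsv"), par_block)
      fl
    })
  manifest <- list(
    package = "memhelix",
    version = as.character(utils::packageVersion("memhelix")),
    config = unclass(config),
    stages_run = names(results),
    stage_errors = if (length(errors) > 0) errors else NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yml"))
  invisible(list(results = results, manifest = manifest,
                 ok = length(errors) == 0L))
}
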