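# Pipeline driver: runs the figure-level analyses end to end from a single
# run configuration, writing TSV results with a JSON metadata sidecar. The
# configuration is the single source of every numeric convention (5 A
# cutoff, strict > 5 complexation threshold, 50 ns species bins, 325 K,
# t0 = 1 ns); stage code takes them from here.

#' Pipeline run configuration
#'
#' @param structure path to a PDB structure file (or NULL when a
#'   \code{trajectory} object is passed to \code{\link{run_pipeline}})
#' @param traj_file path to a trajectory in the plain-text fallback format
#' @param roles named character vector: chain id to role
#' @param cutoff contact cutoff, Angstrom
#' @param threshold strict complexation/oligomer contact threshold
#' @param bin_ns species bin width, ns
#' @param temperature K
#' @param t0 survival escape tolerance, ns
#' @param max_lag_ns maximum survival lag, ns (NULL: half the run)
#' @param selection_atom atom name for the structural metrics (default CA)
#' @param outdir output directory
#' @param seed integer seed recorded in the metadata
#' @return an object of class \code{run_config}
#' @export
run_config <- function(structure = NULL, traj_file = NULL, roles = NULL,
                       cutoff = 5.0, threshold = 5L, bin_ns = 50,
                       temperature = 325, t0 = 1.0, max_lag_ns = NULL,
                       selection_atom = "CA", outdir = "oligotraj-out",
                       seed = 1L) {
  stopifnot(cutoff > 0, threshold > 0, bin_ns > 0, temperature > 0,
            t0 >= 0)
  structure(list(structure = structure, traj_file = traj_file,
                 roles = roles, cutoff = cutoff,
                 threshold = as.integer(threshold), bin_ns = bin_ns,
                 temperature = temperature, t0 = t0,
                 max_lag_ns = max_lag_ns, selection_atom = selection_atom,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / deserialize a run configuration (lossless round trip)
#' @param config a \code{run_config}
#' @param path JSON file path
#' @return \code{write_run_config}: the path, invisibly;
#'   \code{read_run_config}: a \code{run_config}
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$roles)) x$roles <- as.list(x$roles)  # keep chain names
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$roles)) x$roles <- unlist(x$roles)
  do.call(run_config, x)
}

config_hash <- function(config) {
  # polynomial rolling hash (mod a 31-bit prime) of the canonical JSON
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         null = "null")
  h <- 17
  for (b in utf8ToInt(as.character(js))) h <- (h * 31 + b) %% 536870909
  sprintf("%08x", h)
}

write_result_tsv <- function(df, path, config, extra = list()) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c(list(config_hash = config_hash(config),
                 cutoff = config$cutoff, threshold = config$threshold,
                 version = as.character(
                   utils::packageVersion("oligotraj"))),
            extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

map_to_long <- function(map) {
  g <- expand.grid(row = seq_along(map$row_labels),
                   col = seq_along(map$col_labels))
  data.frame(row_label = map$row_labels[g$row],
             col_label = map$col_labels[g$col],
             probability = as.vector(map$P),
             n = map$n_obs)
}

PIPELINE_STAGES <- c("contacts", "species", "pmf", "survival", "maps",
                     "rmsd", "rmsf")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on a trajectory (either
#' passed directly or loaded from the configured files) and writes one TSV
#' per stage plus JSON metadata sidecars carrying the configuration hash.
#' Re-running with the same inputs, configuration and seed reproduces the
#' outputs byte for byte.
#'
#' @param config a \code{run_config}
#' @param stages character vector of stages (subset of \code{"contacts"},
#'   \code{"species"}, \code{"pmf"}, \code{"survival"}, \code{"maps"},
#'   \code{"rmsd"}, \code{"rmsf"}), or \code{"all"}
#' @param traj optional \code{trajectory} (overrides the configured files)
#' @return named list of in-memory stage results, invisibly
#' @export
run_pipeline <- function(config, stages = "all", traj = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  if (is.null(traj)) {
    if (is.null(config$structure) || is.null(config$traj_file))
      stop("stage input missing: no trajectory given and no ",
           "structure/trajectory files configured")
    model <- load_system(config$structure, config$roles)
    traj <- read_trajectory(config$traj_file, model)
  }
  model <- traj$model
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ccfg <- contact_config(cutoff = config$cutoff)
  kcfg <- kinetics_config(threshold = config$threshold, t0 = config$t0,
                          max_lag = config$max_lag_ns)
  lcfg <- landscape_config(temperature = config$temperature)
  has_inh <- length(chains_by_role(model, "inhibitor")) > 0
  needs_inh <- intersect(stages, c("pmf", "survival", "maps"))
  if (length(needs_inh) > 0 && !has_inh)
    stop("stage '", needs_inh[1], "' requires an inhibitor in the model")

  results <- list()
  need_ensemble <- "maps" %in% stages
  ens <- if (need_ensemble) contact_ensemble(traj, ccfg) else NULL
  counts <- if (!is.null(ens)) ens$chain_counts
            else if (length(intersect(stages,
                     c("contacts", "species", "pmf", "survival"))) > 0)
              trajectory_chain_counts(traj, ccfg)
            else NULL
  out <- function(name) file.path(config$outdir, name)
  t_start <- proc.time()[["elapsed"]]
  log_stage <- function(stage, n) {
    message(sprintf("[oligotraj] stage %-8s done (%d rows, %.1f s)",
                    stage, n, proc.time()[["elapsed"]] - t_start))
  }

  if ("contacts" %in% stages) {
    cid <- model$chain_ids
    nc <- length(cid)
    ut <- which(upper.tri(diag(nc)), arr.ind = TRUE)
    df <- do.call(rbind, lapply(seq_len(dim(counts)[3]), function(f)
      data.frame(time = traj$times[f], chain_a = cid[ut[, 1]],
                 chain_b = cid[ut[, 2]],
                 count = counts[, , f][ut])))
    df <- df[df$count > 0, , drop = FALSE]
    write_result_tsv(df, out("contacts.tsv"), config)
    results$contacts <- df
    log_stage("contacts", nrow(df))
  }
  if ("species" %in% stages) {
    sp <- species_counts(counts, model = model, times = traj$times,
                         threshold = config$threshold,
                         bin_ns = config$bin_ns)
    write_result_tsv(as.data.frame(sp), out("species.tsv"), config,
                     list(bin_ns = config$bin_ns,
                          partial_last_bin = attr(sp, "partial_last_bin")))
    results$species <- sp
    log_stage("species", nrow(sp))
  }
  if ("pmf" %in% stages) {
    obs <- observable_series(structure(list(
      chain_counts = counts, model = model, times = traj$times),
      class = "contact_ensemble"))
    grid <- pmf2d(obs, lcfg)
    g <- expand.grid(x = grid$x_centers, y = grid$y_centers)
    df <- data.frame(x = g$x, y = g$y, P = as.vector(grid$P),
                     W = as.vector(grid$W),
                     masked = as.vector(grid$mask))
    write_result_tsv(df, out("pmf.tsv"), config,
                     list(temperature = lcfg$temperature,
                          kBT = lcfg$kBT))
    results$pmf <- grid
    log_stage("pmf", nrow(df))
  }
  if ("survival" %in% stages) {
    bs <- bound_series(structure(list(
      chain_counts = counts, model = model, times = traj$times),
      class = "contact_ensemble"), kcfg = kcfg)
    sv <- survival_correlation(bs, kcfg)
    write_result_tsv(as.data.frame(sv), out("survival.tsv"), config,
                     list(t0 = config$t0, N = attr(sv, "N")))
    results$survival <- sv
    log_stage("survival", nrow(sv))
  }
  if ("maps" %in% stages) {
    maps <- list(
      inhibitor = inhibitor_peptide_map(ens, threshold = config$threshold),
      tertiary_complexed = tertiary_map(ens, population = "complexed",
                                        threshold = config$threshold),
      quaternary_complexed = quaternary_map(ens, population = "complexed",
                                            threshold = config$threshold))
    for (nm in names(maps)) {
      if (is.null(maps[[nm]])) next
      write_result_tsv(map_to_long(maps[[nm]]),
                       out(paste0("map_", nm, ".tsv")), config,
                       list(conditioning = maps[[nm]]$conditioning))
    }
    results$maps <- maps
    log_stage("maps", sum(!vapply(maps, is.null, logical(1))))
  }
  if ("rmsd" %in% stages || "rmsf" %in% stages) {
    sel_role <- if (has_inh) "inhibitor" else "peptide"
    sel <- select_atoms(model, role = sel_role,
                        atom_names = config$selection_atom)
    if ("rmsd" %in% stages) {
      df <- rmsd_series(traj, reference = 1L, selection = sel)
      write_result_tsv(df, out("rmsd.tsv"), config,
                       list(selection = config$selection_atom,
                            role = sel_role))
      results$rmsd <- df
      log_stage("rmsd", nrow(df))
    }
    if ("rmsf" %in% stages) {
      df <- rmsf_per_residue(traj, sel)
      write_result_tsv(df, out("rmsf.tsv"), config,
                       list(selection = config$selection_atom,
                            role = sel_role))
      results$rmsf <- df
      log_stage("rmsf", nrow(df))
    }
  }
  invisible(results)
}
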