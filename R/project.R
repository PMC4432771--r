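# Project configurations: a declarative YAML description of one descriptor
# run (inputs, selected indices/weightings/groups/aggregators, parameters,
# output prefix), serializable and reloadable losslessly, plus the batch
# runner.

#' Build a project configuration
#'
#' @param inputs character vector of input file paths (PDB or FASTA).
#' @param indices per-residue index names.
#' @param weightings weighting tags (`"NONE"`, `"AC2"`, `"KH1"`, `"ES"`,
#'   `"IB"`, `"GR3"`, ...).
#' @param groups residue group names (see [resolve_groups()]).
#' @param aggregators aggregation operator names (see `AGGREGATORS`).
#' @param d,t contact-map cutoffs (Angstrom / sequence separation).
#' @param contact_weight contact weighting scheme.
#' @param sasa_cutoff INT/SUP relative-accessibility cutoff.
#' @param probe_radius SASA probe radius (Angstrom).
#' @param ic_precision rounding precision of the information-content
#'   equivalence classes.
#' @param format input format (`"auto"`, `"pdb"`, `"fasta"`).
#' @param chain optional PDB chain id.
#' @param output_prefix path prefix of the two output files.
#' @param sentinel missing-value token in output files.
#' @param strict error (instead of sentinel-fill) on incompatible
#'   selections.
#' @param zero_on_degenerate zeros instead of error for contact maps
#'   without contacts.
#' @param seed integer seed recorded in the config (used by fixture
#'   generation steps, if any; the pipeline itself is deterministic).
#' @return An object of class `ProjectConfig`.
#' @export
project_config <- function(inputs = character(0),
                           indices = c("HP"),
                           weightings = c("NONE"),
                           groups = c("PRT"),
                           aggregators = c("AM"),
                           d = 8, t = 4,
                           contact_weight = "none",
                           sasa_cutoff = 0.25,
                           probe_radius = 1.4,
                           ic_precision = 6,
                           format = "auto",
                           chain = NULL,
                           output_prefix = "protdescr_out",
                           sentinel = "NA",
                           strict = FALSE,
                           zero_on_degenerate = FALSE,
                           seed = 1L) {
  cfg <- structure(
    list(schema = 1L, inputs = inputs, indices = indices,
         weightings = weightings, groups = groups,
         aggregators = aggregators, d = d, t = t,
         contact_weight = contact_weight, sasa_cutoff = sasa_cutoff,
         probe_radius = probe_radius, ic_precision = ic_precision,
         format = format, chain = chain, output_prefix = output_prefix,
         sentinel = sentinel, strict = strict,
         zero_on_degenerate = zero_on_degenerate, seed = as.integer(seed)),
    class = "ProjectConfig"
  )
  validate_config(cfg)
}

#' Validate a project configuration
#'
#' Checks every referenced index, weighting, group and aggregator name
#' against the registries and the parameter ranges; errors name the
#' offending field.
#'
#' @param cfg a `ProjectConfig` (or a plain list with the same fields).
#' @return The validated config, invisibly classed as `ProjectConfig`.
#' @export
validate_config <- function(cfg) {
  known_idx <- c(list_property_scales(), TOPOGRAPHIC_INDICES,
                 THERMODYNAMIC_INDICES)
  bad <- setdiff(cfg$indices, known_idx)
  if (length(bad))
    stop("config field 'indices': unknown index name(s): ",
         paste(bad, collapse = ", "))
  for (w in cfg$weightings)
    tryCatch(parse_weighting(w), error = function(e)
      stop("config field 'weightings': ", conditionMessage(e),
           call. = FALSE))
  known_grp <- c("PRT", "INT", "SUP", "HEX", "SHT", "TRN", "RCL",
                 unname(AA3), names(PROPERTY_CLASSES))
  bad <- setdiff(cfg$groups, known_grp)
  if (length(bad))
    stop("config field 'groups': unknown group name(s): ",
         paste(bad, collapse = ", "))
  bad <- setdiff(cfg$aggregators, AGGREGATORS)
  if (length(bad))
    stop("config field 'aggregators': unknown aggregator(s): ",
         paste(bad, collapse = ", "))
  if (!is.numeric(cfg$d) || cfg$d <= 0)
    stop("config field 'd': must be a positive distance in Angstrom")
  if (!is.numeric(cfg$t) || cfg$t < 0)
    stop("config field 't': must be a non-negative sequence separation")
  if (cfg$sasa_cutoff < 0 || cfg$sasa_cutoff > 1)
    stop("config field 'sasa_cutoff': must lie in [0, 1]")
  if (!length(cfg$indices) || !length(cfg$weightings) ||
      !length(cfg$groups) || !length(cfg$aggregators))
    stop("config: indices, weightings, groups and aggregators must all ",
         "be non-empty")
  class(cfg) <- "ProjectConfig"
  cfg
}

#' @export
print.ProjectConfig <- function(x, ...) {
  cat(sprintf(paste0("ProjectConfig: %d input(s), %d index(es) x %d ",
                     "weighting(s) x %d group(s) x %d aggregator(s)\n"),
              length(x$inputs), length(x$indices), length(x$weightings),
              length(x$groups), length(x$aggregators)))
  invisible(x)
}

#' Save / load a project configuration (YAML)
#'
#' @param cfg a [project_config()].
#' @param path file path.
#' @return `write_project_config` returns `path` invisibly;
#'   `read_project_config` returns the validated `ProjectConfig`.
#' @export
write_project_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ProjectConfig"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_project_config
#' @export
read_project_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- project_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("config file ", path, ": unknown field(s): ",
         paste(unknown, collapse = ", "))
  for (nm in names(raw)) cfg[nm] <- list(raw[[nm]])  # keeps NULLs (chain)
  validate_config(cfg)
}

#' Run one project end to end
#'
#' Loads the configuration (path or object), reads the inputs, generates
#' descriptors, writes the `_AA.txt` / `_Prot.txt` outputs and a run log.
#'
#' @param cfg a `ProjectConfig` or path to a YAML config file.
#' @return Named character vector with the `aa`, `prot` and `log` paths.
#' @export
run_project <- function(cfg) {
  if (is.character(cfg)) cfg <- read_project_config(cfg)
  cfg <- validate_config(cfg)
  if (!length(cfg$inputs)) stop("config field 'inputs': no input files")
  log_lines <- character(0)
  models <- withCallingHandlers(
    read_proteins(cfg$inputs, format = cfg$format, chain = cfg$chain),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("WARNING:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  res <- withCallingHandlers(
    generate_descriptors(models, cfg),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("WARNING:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      log_lines <<- c(log_lines, paste("NOTE:",
                                       trimws(conditionMessage(m))))
      invokeRestart("muffleMessage")
    })
  paths <- write_outputs(res$residue_tables, res$table,
                         cfg$output_prefix, sentinel = cfg$sentinel)
  log_path <- paste0(cfg$output_prefix, ".log")
  writeLines(c(
    sprintf("proteins: %d", length(models)),
    sprintf("descriptors per protein: %d", ncol(res$table)),
    log_lines), log_path)
  c(aa = paths[1], prot = paths[2], log = log_path)
}

#' Run several projects in batch mode
#'
#' Projects run sequentially; a failing project does not abort the batch.
#'
#' @param cfg_paths character vector of config file paths.
#' @return Named list, one entry per config: either the [run_project()]
#'   result or a `"failed"` entry carrying the error message.  A summary
#'   attribute `"n_failed"` counts failures.
#' @export
run_multi <- function(cfg_paths) {
  out <- vector("list", length(cfg_paths))
  names(out) <- cfg_paths
  failed <- 0L
  for (k in seq_along(cfg_paths)) {
    out[[k]] <- tryCatch(run_project(cfg_paths[[k]]),
                         error = function(e) {
                           failed <<- failed + 1L
                           list(failed = TRUE,
                                error = conditionMessage(e))
                         })
  }
  attr(out, "n_failed") <- failed
  out
}
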