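# Structured plain-text (YAML) run configuration: defaults, validation,
# round-tripping. The standard protocol settings live here as defaults:
# w_cnt = 1, tau = 48.9 fs, Q = 5 kcal/MTU^2/mol, friction factor 0.01,
# 8 A contact cutoff, 0.1 A flat half width, w_restraint = 0.006,
# box 220 A, the 36-temperature ladder.

.config_schema <- list(
  structure = c("source", "pdb_path", "kind", "n_residues", "placement",
                "seed", "jitter"),
  cnt = c("enabled", "radius", "weight", "sc_epsilon", "sc_sigma",
          "p_epsilon", "p_sigma"),
  box = c("edge"),
  restraints = c("enabled", "weight", "halfwidth", "cutoff", "min_sep"),
  dynamics = c("ensemble", "dt", "steps", "T_set", "tau", "Q",
               "friction_scale", "seed", "sample_every", "traj_every"),
  remd = c("ladder", "replicas_per_temperature", "n_cycles",
           "steps_per_cycle", "dt", "seed", "discard"),
  analysis = c("cutoff", "n_clusters", "temperature"),
  output = c("prefix")
)

#' Default run configuration
#'
#' Every physical quantity carries its documented unit: distances in A,
#' times in fs, temperatures in K, energies in kcal/mol.
#'
#' @return nested list (class `run_config`) covering the structure, tube,
#'   box, restraint, dynamics, replica-exchange, analysis and output blocks.
#' @export
default_run_config <- function() {
  structure(list(
    structure = list(source = "fixture", pdb_path = NULL,
                     kind = "trpcage_like", n_residues = 20L,
                     placement = 10, seed = 1L, jitter = 0),
    cnt = list(enabled = TRUE, radius = 6, weight = 1, sc_epsilon = 0.5,
               sc_sigma = 4.0, p_epsilon = 0.3, p_sigma = 3.5),
    box = list(edge = 220),
    restraints = list(enabled = FALSE, weight = 0.006, halfwidth = 0.1,
                      cutoff = 8, min_sep = 3L),
    dynamics = list(ensemble = "nve", dt = 0.489, steps = 200000L,
                    T_set = 300, tau = 48.9, Q = 5, friction_scale = 0.01,
                    seed = 1L, sample_every = 10L, traj_every = 0L),
    remd = list(ladder = "default", replicas_per_temperature = 2L,
                n_cycles = 20L, steps_per_cycle = 1000L, dt = 4.89,
                seed = 1L, discard = 0.5),
    analysis = list(cutoff = 8, n_clusters = 10L, temperature = 300),
    output = list(prefix = "cntmd_run")
  ), class = "run_config")
}

.validate_config <- function(cfg) {
  bad_blocks <- setdiff(names(cfg), names(.config_schema))
  if (length(bad_blocks))
    stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "))
  for (b in names(cfg)) {
    bad <- setdiff(names(cfg[[b]]), .config_schema[[b]])
    if (length(bad))
      stop("unknown key(s) in block '", b, "': ", paste(bad, collapse = ", "))
  }
  def <- unclass(default_run_config())
  for (b in names(def)) {
    merged <- def[[b]]
    merged[names(cfg[[b]])] <- cfg[[b]]
    def[[b]] <- merged
  }
  with(def$dynamics, stopifnot(dt > 0, steps >= 0, T_set > 0, tau > 0, Q > 0))
  stopifnot(def$cnt$radius > 0, def$box$edge > 0)
  structure(def, class = "run_config")
}

#' Read a run configuration
#'
#' Parses the YAML config, rejects unknown blocks/keys and fills unset keys
#' from [default_run_config()]. A config round-trips: parse -> serialize ->
#' parse yields an identical structure.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  .validate_config(yaml::read_yaml(path))
}

#' Write a run configuration
#'
#' @param config a `run_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the simulation system a config describes
#'
#' Resolves the structure source (fixture generator or PDB file), the tube,
#' box, restraints and force field into a ready [cg_system()].
#'
#' @param config a `run_config`.
#' @return a `cg_system`.
#' @export
config_system <- function(config) {
  cfg <- .validate_config(unclass(config))
  box <- periodic_box(cfg$box$edge)
  if (identical(cfg$structure$source, "fixture")) {
    fx <- make_fixture(cfg$structure$kind, cfg$structure$n_residues,
                       placement = cfg$structure$placement,
                       radius = cfg$cnt$radius, box_edge = cfg$box$edge,
                       seed = cfg$structure$seed,
                       jitter = cfg$structure$jitter)
    chain <- fx$chain
  } else {
    pc <- read_pdb_ca(cfg$structure$pdb_path)
    chain <- build_chain(pc$sequence, pc$ca_positions)
  }
  cyl <- if (isTRUE(cfg$cnt$enabled)) {
    tab <- default_kihara_table()
    tab$epsilon <- ifelse(tab$type == "p", cfg$cnt$p_epsilon, cfg$cnt$sc_epsilon)
    tab$sigma <- ifelse(tab$type == "p", cfg$cnt$p_sigma, cfg$cnt$sc_sigma)
    cnt_cylinder(cfg$cnt$radius, tab, cfg$cnt$weight)
  } else NULL
  rs <- if (isTRUE(cfg$restraints$enabled))
    derive_restraints(chain, cutoff = cfg$restraints$cutoff,
                      min_sep = cfg$restraints$min_sep,
                      weight = cfg$restraints$weight,
                      halfwidth = cfg$restraints$halfwidth)
  else NULL
  cg_system(chain, cylinder = cyl, box = box, restraints = rs)
}
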