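# Temperature-tagged snapshot archive: the substrate for WHAM and all
# ensemble analyses, with a documented plain-text columnar on-disk layout.

#' Construct an ensemble archive
#'
#' Temperature-tagged snapshots with per-term energies and coordinates.
#' Records are kept sorted by (replica, step); every record's energy
#' breakdown satisfies `u_total = u_protein + w_cnt * u_cnt + w_restraint *
#' u_restraint`.
#'
#' @param snapshots data.frame with columns `replica`, `temp_index`,
#'   `temperature`, `step`, `u_protein`, `u_cnt`, `u_restraint`, `u_total`.
#' @param coords nsite x 3 x nrow(snapshots) array of dynamic-site
#'   coordinates (A), or `NULL` for energy-only archives.
#' @param topology list describing the system (at least `sequence`; typically
#'   also `w_cnt`, `w_restraint`, `R0`, `box`).
#' @param provenance list (seed, config hash, package version, ...).
#' @return object of class `ensemble_archive`.
#' @export
ensemble_archive <- function(snapshots, coords = NULL, topology = list(),
                             provenance = list()) {
  need <- c("replica", "temp_index", "temperature", "step", "u_protein",
            "u_cnt", "u_restraint", "u_total")
  miss <- setdiff(need, names(snapshots))
  if (length(miss)) stop("snapshot table lacks column(s): ",
                         paste(miss, collapse = ", "))
  o <- order(snapshots$replica, snapshots$step)
  snapshots <- snapshots[o, , drop = FALSE]
  rownames(snapshots) <- NULL
  if (!is.null(coords)) {
    stopifnot(length(dim(coords)) == 3, dim(coords)[3] == nrow(snapshots))
    coords <- coords[, , o, drop = FALSE]
    if (!all(is.finite(coords))) stop("archive coordinates must be finite")
  }
  w_cnt <- if (is.null(topology$w_cnt)) 1 else topology$w_cnt
  w_rest <- if (is.null(topology$w_restraint)) 0.006 else topology$w_restraint
  resid <- with(snapshots,
                abs(u_total - (u_protein + w_cnt * u_cnt + w_rest * u_restraint)))
  if (any(resid > 1e-8 * pmax(1, abs(snapshots$u_total))))
    stop("energy breakdown additivity violated in snapshot table")
  structure(list(snapshots = snapshots, coords = coords,
                 topology = topology, provenance = provenance),
            class = "ensemble_archive")
}

#' @export
print.ensemble_archive <- function(x, ...) {
  s <- x$snapshots
  cat(sprintf("ensemble_archive: %d snapshots, %d temperature(s), %d replica(s)%s\n",
              nrow(s), length(unique(s$temp_index)),
              length(unique(s$replica)),
              if (is.null(x$coords)) " (energies only)" else ""))
  invisible(x)
}

#' Keep the equilibrated tail of an archive
#'
#' Drops the first `discard` fraction of each replica's snapshots (by step),
#' mirroring the usual practice of analyzing only the last, equilibrated
#' part of each trajectory.
#'
#' @param archive an `ensemble_archive`.
#' @param discard fraction of each replica's records to drop (default 0.5).
#' @return filtered `ensemble_archive`.
#' @export
equilibrated_subset <- function(archive, discard = 0.5) {
  s <- archive$snapshots
  keep <- unlist(lapply(split(seq_len(nrow(s)), s$replica), function(ix) {
    ix[s$step[ix] >= stats::quantile(s$step[ix], discard, type = 1)]
  }))
  keep <- sort(unname(keep))
  ensemble_archive(s[keep, , drop = FALSE],
                   if (!is.null(archive$coords))
                     archive$coords[, , keep, drop = FALSE],
                   archive$topology, archive$provenance)
}

#' Write an archive to its columnar text format
#'
#' Layout: a `#CNTMD_ARCHIVE 1` magic line, `#TOPOLOGY` and `#PROVENANCE`
#' JSON header lines, a `#COLUMNS` line, then one CSV record per snapshot
#' (energies followed by the flattened coordinates in full double
#' precision). The round trip is lossless for all stored fields.
#'
#' @param archive an `ensemble_archive`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path) {
  s <- archive$snapshots
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#CNTMD_ARCHIVE 1", con)
  writeLines(paste0("#TOPOLOGY ",
                    jsonlite::toJSON(archive$topology, auto_unbox = TRUE,
                                     digits = NA)), con)
  writeLines(paste0("#PROVENANCE ",
                    jsonlite::toJSON(archive$provenance, auto_unbox = TRUE,
                                     digits = NA)), con)
  ecol <- c("replica", "temp_index", "temperature", "step", "u_protein",
            "u_cnt", "u_restraint", "u_total")
  nsite <- if (is.null(archive$coords)) 0L else dim(archive$coords)[1]
  ccol <- if (nsite) as.vector(t(outer(seq_len(nsite), c("x", "y", "z"),
                                       function(i, a) paste0(a, i))))
          else character(0)
  writeLines(paste0("#COLUMNS ", paste(c(ecol, ccol), collapse = ",")), con)
  m <- as.matrix(s[, ecol])
  if (nsite) {
    flat <- t(apply(archive$coords, 3, function(p) as.vector(t(p))))
    m <- cbind(m, flat)
  }
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), con)
  invisible(path)
}

#' Read an archive written by [write_archive()]
#'
#' @param path archive file.
#' @return an `ensemble_archive`.
#' @export
read_archive <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  lines <- readLines(path)
  if (!startsWith(lines[1], "#CNTMD_ARCHIVE"))
    stop(path, " is not an archive file")
  topo <- jsonlite::fromJSON(sub("^#TOPOLOGY ", "", lines[2]))
  prov <- jsonlite::fromJSON(sub("^#PROVENANCE ", "", lines[3]))
  cols <- strsplit(sub("^#COLUMNS ", "", lines[4]), ",")[[1]]
  body <- lines[-(1:4)]
  m <- matrix(as.numeric(unlist(strsplit(body, ","))), length(body),
              length(cols), byrow = TRUE)
  colnames(m) <- cols
  snaps <- as.data.frame(m[, 1:8, drop = FALSE])
  coords <- NULL
  if (length(cols) > 8) {
    nsite <- (length(cols) - 8) / 3
    coords <- array(NA_real_, c(nsite, 3, nrow(m)))
    for (k in seq_len(nrow(m)))
      coords[, , k] <- matrix(m[k, -(1:8)], nsite, 3, byrow = TRUE)
  }
  ensemble_archive(snaps, coords, topo, prov)
}
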