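# Structure and trajectory I/O: CA-trace PDB reading (via bio3d), multi-model
# PDB and XYZ trajectory writing.

#' Read a CA trace from a PDB file
#'
#' Extracts ordered CA coordinates and one-letter residue codes from the ATOM
#' records of a single-chain PDB file. Alternate locations other than blank
#' or `"A"` are skipped; insertion codes and multi-chain files are rejected.
#'
#' @param path PDB file path.
#' @return list with `sequence` (one-letter codes) and `ca_positions`
#'   (n x 3 matrix, A), ready for [build_chain()].
#' @export
read_pdb_ca <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!nrow(at)) stop("no CA atoms in ", path)
  at <- at[at$alt %in% c("", "A", NA), , drop = FALSE]
  if (length(unique(at$chain[!is.na(at$chain)])) > 1)
    stop("multiple chains in ", path, "; one chain per file is supported")
  ins <- at$insert
  if (any(!is.na(ins) & ins != ""))
    stop("insertion codes present in ", path, "; renumber the file first")
  codes <- .three_to_one[at$resid]
  if (any(is.na(codes)))
    stop("unknown residue name(s): ",
         paste(unique(at$resid[is.na(codes)]), collapse = ", "))
  list(sequence = unname(codes),
       ca_positions = unname(as.matrix(at[, c("x", "y", "z")])))
}

.pdb_atom_line <- function(serial, name, resname, resseq, xyz) {
  sprintf("ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, sprintf(" %-3s", name), resname, resseq,
          xyz[1], xyz[2], xyz[3])
}

# one frame of dynamic-site coordinates -> PDB ATOM lines (CA then CB sites)
.frame_lines <- function(pos, chain, has_sc) {
  n <- length(chain$sequence)
  res3 <- .one_to_three[chain$sequence]
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    serial <- serial + 1L
    lines <- c(lines, .pdb_atom_line(serial, "CA", res3[i], i, pos[i, ]))
  }
  sc_rows <- which(has_sc)
  for (k in seq_along(sc_rows)) {
    serial <- serial + 1L
    i <- sc_rows[k]
    lines <- c(lines, .pdb_atom_line(serial, "CB", res3[i], i, pos[n + k, ]))
  }
  lines
}

#' Write a trajectory
#'
#' Writes frames of dynamic-site coordinates as a multi-model PDB
#' (MODEL/ENDMDL blocks; CA records plus CB records for the side-chain
#' sites) or as XYZ (atom count + comment header per frame).
#'
#' @param frames nsite x 3 x nframes array (or a single nsite x 3 matrix).
#' @param chain the `chain_model` topology shared by all frames.
#' @param path output file.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, chain, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  nf <- dim(frames)[3]
  has_sc <- chain$sc_mass > 0
  n <- length(chain$sequence)
  stopifnot(dim(frames)[1] == n + sum(has_sc))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(.frame_lines(frames[, , f], chain, has_sc), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    nm <- c(rep("CA", n), rep("CB", sum(has_sc)))
    for (f in seq_len(nf)) {
      writeLines(as.character(dim(frames)[1]), con)
      writeLines(sprintf("frame %d", f), con)
      writeLines(sprintf("%s %12.6f %12.6f %12.6f", nm, frames[, 1, f],
                         frames[, 2, f], frames[, 3, f]), con)
    }
  }
  invisible(path)
}

#' Read a multi-model PDB trajectory written by [write_trajectory()]
#'
#' @param path PDB trajectory file.
#' @return nsite x 3 x nframes array of dynamic-site coordinates (CA sites
#'   first, then side-chain sites).
#' @export
read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) { starts <- 0L; ends <- length(lines) + 1L }
  stopifnot(length(starts) == length(ends))
  frames <- lapply(seq_along(starts), function(k) {
    blk <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    blk <- blk[startsWith(blk, "ATOM")]
    ca <- blk[substr(blk, 13, 16) == " CA "]
    cb <- blk[substr(blk, 13, 16) == " CB "]
    parse <- function(v) if (!length(v)) NULL else
      matrix(as.numeric(c(substr(v, 31, 38), substr(v, 39, 46),
                          substr(v, 47, 54))), length(v), 3)
    rbind(parse(ca), parse(cb))
  })
  array(unlist(frames), c(dim(frames[[1]]), length(frames)))
}
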