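# Physical constants and per-residue parameter tables shared package-wide.
# Units: length A, energy kcal/mol, mass amu, time fs (1 MTU = 48.9 fs).

#' Physical constants used throughout the package
#'
#' A single shared constants table. `R_KCAL` is the molar gas constant in
#' kcal/mol/K; `MTU_FS` is the coarse-grained molecular time unit in fs;
#' `ACC_CONV` converts a force in kcal/mol/A acting on a mass in amu into an
#' acceleration in A/fs^2 (so kinetic energy in kcal/mol is
#' `0.5 * m * v^2 / ACC_CONV` with v in A/fs).
#'
#' @format Named list with elements `R_KCAL`, `MTU_FS`, `ACC_CONV`.
#' @export
cnt_constants <- list(
  R_KCAL   = 1.98720425864083e-3,
  MTU_FS   = 48.9,
  # 1 kcal = 4184 J; (4184 J/mol/A) / (1e-3 kg/mol) -> m/s^2 -> A/fs^2
  ACC_CONV = 4.184e-4
)

# One-letter codes, average residue masses (amu) and side-chain masses.
# The backbone (N-CA-C'=O + H) share, ~56.04 amu, sits on the CA site; the
# remainder of the average residue mass sits on the side-chain site.
.aa_table <- local({
  res_mass <- c(
    A = 71.079,  R = 156.188, N = 114.104, D = 115.089, C = 103.139,
    Q = 128.131, E = 129.116, G = 57.052,  H = 137.141, I = 113.160,
    L = 113.160, K = 128.174, M = 131.193, F = 147.177, P = 97.117,
    S = 87.078,  T = 101.105, W = 186.213, Y = 163.176, V = 99.133
  )
  backbone <- 56.04
  sc_mass <- pmax(res_mass - backbone, 0)
  # glycine has no side-chain site of its own; its full mass rides on CA
  sc_mass[names(res_mass) == "G"] <- 0
  ca_mass <- ifelse(sc_mass > 0, backbone, res_mass)
  data.frame(
    code = names(res_mass),
    res_mass = unname(res_mass),
    ca_mass = unname(ca_mass),
    sc_mass = unname(sc_mass),
    # CA-SC placement distance (A); glycine's site coincides with CA
    sc_dist = ifelse(names(res_mass) == "G", 0, 2.0),
    stringsAsFactors = FALSE
  )
})

.three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.one_to_three <- stats::setNames(names(.three_to_one), unname(.three_to_one))

#' Amino-acid site parameters
#'
#' Per-residue masses and side-chain placement distances used by
#' [build_chain()]. Masses split the average residue mass between the
#' alpha-carbon site (backbone share) and the side-chain site; glycine carries
#' no separate side-chain site.
#'
#' @return data.frame with columns `code`, `res_mass`, `ca_mass`, `sc_mass`,
#'   `sc_dist`.
#' @export
aa_parameters <- function() .aa_table

.check_sequence <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  bad <- setdiff(unique(sequence), .aa_table$code)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  sequence
}
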