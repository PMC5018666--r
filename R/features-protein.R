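# average residue masses (Da); protein mass = sum + one water.
# X (unknown residue) contributes a documented flat 110.0 Da.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 110.0
)
WATER_MASS <- 18.01524

# Bjellqvist pKa values: charged side chains plus free termini
PKA_TABLE <- c(
  Nterm = 7.50, Cterm = 3.55,
  D = 4.05, E = 4.45, C = 9.00, Y = 10.00, H = 5.98, K = 10.00, R = 12.00
)

#' Molecular weight of a protein (average mass)
#'
#' Sum of average residue masses plus one water.  `X` contributes a flat
#' 110.0 Da.
#'
#' @param sequence Amino-acid string (non-empty).
#' @return Mass in daltons.  Divide by 1000 and round to one decimal for the
#'   kDa convention used in family characterization tables.
#' @export
#' @examples
#' molecular_weight("G") # 75.07
molecular_weight <- function(sequence) {
  if (!nzchar(sequence)) wrky_abort("cannot compute mass of an empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(chars, names(AA_RESIDUE_MASS))
  if (length(unknown) > 0) {
    wrky_abort(paste0("unknown residue(s): ", paste(unknown, collapse = ", ")))
  }
  sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
}

# net charge of a protein at a given pH (Henderson-Hasselbalch)
protein_charge <- function(counts, ph) {
  pos_ka <- c(PKA_TABLE["Nterm"], PKA_TABLE["K"], PKA_TABLE["R"], PKA_TABLE["H"])
  pos_n <- c(1, counts["K"], counts["R"], counts["H"])
  neg_ka <- c(PKA_TABLE["Cterm"], PKA_TABLE["D"], PKA_TABLE["E"],
              PKA_TABLE["C"], PKA_TABLE["Y"])
  neg_n <- c(1, counts["D"], counts["E"], counts["C"], counts["Y"])
  sum(pos_n / (1 + 10^(ph - pos_ka))) - sum(neg_n / (1 + 10^(neg_ka - ph)))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the net protein charge (free termini plus D, E, C,
#' Y, H, K, R side chains under a fixed Bjellqvist pKa table) crosses zero.
#' The charge curve is monotone decreasing in pH, so bisection on (0, 14)
#' converges to the unique root; iteration stops below 1e-4 pH.
#'
#' @param sequence Amino-acid string (non-empty).
#' @return The isoelectric pH (unrounded; report to two decimals).
#' @export
isoelectric_point <- function(sequence) {
  if (!nzchar(sequence)) wrky_abort("cannot compute pI of an empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  counts <- vapply(c("D", "E", "C", "Y", "H", "K", "R"),
                   function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (protein_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical properties for a proteome
#'
#' @param proteins Tibble with `id` and `sequence`.
#' @return Tibble: `id`, `length_aa`, `mw_kda` (one decimal), `pi`
#'   (two decimals).
#' @export
protein_properties <- function(proteins) {
  tibble(
    id = proteins$id,
    length_aa = nchar(proteins$sequence),
    mw_kda = round(map_dbl(proteins$sequence, molecular_weight) / 1000, 1),
    pi = round(map_dbl(proteins$sequence, isoelectric_point), 2)
  )
}
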