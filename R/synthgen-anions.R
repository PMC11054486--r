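## Rigid-geometry anion templates.
##
## Each anion is built from ideal internal coordinates (C-C 1.53 A, C-O 1.25,
## C-H 1.09, C-N 1.47, N-H 1.01; tetrahedral/trigonal angles) with a single
## free torsion: the classifying backbone dihedral chi (C-C-C-C in succinate,
## C-Calpha-Cbeta-Cgamma in the amino acids).  Partial charges are a fixed
## documented table chosen to sum to -2 per anion; only charge differences
## matter for the dipole analyses, so force-field fidelity is not attempted.

## NeRF placement: position D bonded to C with |CD| = bond, angle(B,C,D) =
## `angle` and dihedral(A,B,C,D) = `dihedral` (degrees, IUPAC sign).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- deg2rad(angle)
  dih <- deg2rad(dihedral)
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  n <- n / vnorm(n)
  p <- vcross(n, bc)
  c + bond * (-cos(ang) * bc + sin(ang) * (cos(dih) * p + sin(dih) * n))
}

## charge table per role within an anion (documented constants, sum = -2)
anion_charges <- list(
  SUC = c(C_carb = 0.70, O_carb = -0.80, C_chain = -0.20, H_C = 0.05),
  ASP = c(C_carb = 0.70, O_carb = -0.80, C_alpha = -0.25, C_beta = -0.25,
          N = -0.70, H_C = 0.10, H_N = 0.35),
  GLU = c(C_carb = 0.70, O_carb = -0.80, C_alpha = -0.25, C_beta = -0.25,
          C_gamma = -0.20, N = -0.70, H_C = 0.10, H_N = 0.35)
)

#' Build a rigid anion template
#'
#' Returns ideal-geometry coordinates for one anion with the classifying
#' backbone torsion set to `chi`.  The template is centered on the midpoint
#' of the two carboxylate carbons and aligned so that the vector joining them
#' points along +z; [generate_trajectory()] then orients it per frame.
#'
#' @param anion_type `"ASP"`, `"GLU"` or `"SUC"`.
#' @param chi Backbone dihedral in degrees (anti is near 180, gauche near
#'   +/-60).
#' @return List with `coords` (matrix n x 3), `elements`, `roles`, `charges`,
#'   and index vectors `carboxylate_carbons`, `dihedral`, `amino_n`,
#'   `carboxylate_groups` (local 1-based indices).
#' @export
anion_template <- function(anion_type = c("ASP", "GLU", "SUC"), chi = 180) {
  anion_type <- match.arg(anion_type)
  q <- anion_charges[[anion_type]]
  ## common backbone: C1 (carboxylate) - C2 - C3 - C4, torsion C1C2C3C4 = chi
  C1 <- c(0, 0, 0)
  C2 <- c(1.53, 0, 0)
  C3 <- C2 + 1.53 * c(cos(deg2rad(180 - 111)), sin(deg2rad(180 - 111)), 0)
  C4 <- place_atom(C1, C2, C3, 1.53, 111, chi)
  O11 <- place_atom(C3, C2, C1, 1.25, 117, 0)
  O12 <- place_atom(C3, C2, C1, 1.25, 117, 180)
  if (anion_type == "SUC") {
    O41 <- place_atom(C2, C3, C4, 1.25, 117, 0)
    O42 <- place_atom(C2, C3, C4, 1.25, 117, 180)
    H21 <- place_atom(C4, C3, C2, 1.09, 109.5, chi + 120)
    H22 <- place_atom(C4, C3, C2, 1.09, 109.5, chi - 120)
    H31 <- place_atom(C1, C2, C3, 1.09, 109.5, chi + 120)
    H32 <- place_atom(C1, C2, C3, 1.09, 109.5, chi - 120)
    coords <- rbind(C1, C2, C3, C4, O11, O12, O41, O42, H21, H22, H31, H32)
    elements <- c("C", "C", "C", "C", "O", "O", "O", "O", rep("H", 4))
    roles <- c("carboxylate_C", "other", "other", "carboxylate_C",
               rep("carboxylate_O", 4), rep("other", 4))
    charges <- c(q["C_carb"], q["C_chain"], q["C_chain"], q["C_carb"],
                 rep(q["O_carb"], 4), rep(q["H_C"], 4))
    carbs <- c(1L, 4L)
    quad <- 1:4
    amino <- NA_integer_
    groups <- list(list(C = 1L, O = c(5L, 6L)), list(C = 4L, O = c(7L, 8L)))
  } else if (anion_type == "ASP") {
    ## C4 is the side-chain carboxylate carbon (Cgamma)
    O41 <- place_atom(C2, C3, C4, 1.25, 117, 0)
    O42 <- place_atom(C2, C3, C4, 1.25, 117, 180)
    N <- place_atom(C4, C3, C2, 1.47, 109.5, chi + 120)
    H2 <- place_atom(C4, C3, C2, 1.09, 109.5, chi - 120)
    H31 <- place_atom(C1, C2, C3, 1.09, 109.5, chi + 120)
    H32 <- place_atom(C1, C2, C3, 1.09, 109.5, chi - 120)
    HN1 <- place_atom(C1, C2, N, 1.01, 107, 60)
    HN2 <- place_atom(C1, C2, N, 1.01, 107, 180)
    coords <- rbind(C1, C2, C3, C4, O11, O12, O41, O42, N,
                    H2, H31, H32, HN1, HN2)
    elements <- c("C", "C", "C", "C", "O", "O", "O", "O", "N", rep("H", 5))
    roles <- c("carboxylate_C", "other", "other", "carboxylate_C",
               rep("carboxylate_O", 4), "amino_N", rep("other", 5))
    charges <- c(q["C_carb"], q["C_alpha"], q["C_beta"], q["C_carb"],
                 rep(q["O_carb"], 4), q["N"],
                 rep(q["H_C"], 3), rep(q["H_N"], 2))
    carbs <- c(1L, 4L)
    quad <- 1:4
    amino <- 9L
    groups <- list(list(C = 1L, O = c(5L, 6L)), list(C = 4L, O = c(7L, 8L)))
  } else {
    ## GLU: one more chain carbon; terminal carboxylate on C5
    C5 <- place_atom(C2, C3, C4, 1.53, 111, 180)
    O51 <- place_atom(C3, C4, C5, 1.25, 117, 0)
    O52 <- place_atom(C3, C4, C5, 1.25, 117, 180)
    N <- place_atom(C4, C3, C2, 1.47, 109.5, chi + 120)
    H2 <- place_atom(C4, C3, C2, 1.09, 109.5, chi - 120)
    H31 <- place_atom(C1, C2, C3, 1.09, 109.5, chi + 120)
    H32 <- place_atom(C1, C2, C3, 1.09, 109.5, chi - 120)
    H41 <- place_atom(C2, C3, C4, 1.09, 109.5, 180 + 120)
    H42 <- place_atom(C2, C3, C4, 1.09, 109.5, 180 - 120)
    HN1 <- place_atom(C1, C2, N, 1.01, 107, 60)
    HN2 <- place_atom(C1, C2, N, 1.01, 107, 180)
    coords <- rbind(C1, C2, C3, C4, C5, O11, O12, O51, O52, N,
                    H2, H31, H32, H41, H42, HN1, HN2)
    elements <- c(rep("C", 5), rep("O", 4), "N", rep("H", 7))
    roles <- c("carboxylate_C", "other", "other", "other", "carboxylate_C",
               rep("carboxylate_O", 4), "amino_N", rep("other", 7))
    charges <- c(q["C_carb"], q["C_alpha"], q["C_beta"], q["C_gamma"],
                 q["C_carb"], rep(q["O_carb"], 4), q["N"],
                 rep(q["H_C"], 5), rep(q["H_N"], 2))
    carbs <- c(1L, 5L)
    quad <- 1:4
    amino <- 10L
    groups <- list(list(C = 1L, O = c(6L, 7L)), list(C = 5L, O = c(8L, 9L)))
  }
  rownames(coords) <- NULL
  ## center on the carboxylate-carbon midpoint and align their axis with +z
  axis <- coords[carbs[2], ] - coords[carbs[1], ]
  mid <- (coords[carbs[1], ] + coords[carbs[2], ]) / 2
  coords <- sweep(coords, 2, mid)
  coords <- coords %*% t(rot_align(axis, c(0, 0, 1)))
  list(coords = coords, elements = elements, roles = roles,
       charges = unname(charges), carboxylate_carbons = carbs,
       dihedral = quad, amino_n = amino, carboxylate_groups = groups)
}

## SPC/E-like 3-site water template (O at origin), net charge 0
water_template <- function() {
  list(
    coords = rbind(c(0, 0, 0),
                   c(0.8165, 0.5774, 0),
                   c(-0.8165, 0.5774, 0)),
    elements = c("O", "H", "H"),
    roles = c("water_O", "water_H", "water_H"),
    charges = c(-0.8476, 0.4238, 0.4238)
  )
}
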