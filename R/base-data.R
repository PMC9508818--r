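# Idealized planar base geometries in the standard base-fixed reference frame
# (x toward the major groove along the pseudo-dyad, y toward the sugar, z out
# of the base plane; origin at the pairing center). Units Angstrom. The frame
# convention matters only for self-consistency: every base-pair parameter in
# the package is defined relative to these frames, and the duplex generator
# builds from the same constants.

.base_xy <- function(m) {
  out <- cbind(m, 0)
  colnames(out) <- c("x", "y", "z")
  out
}

.std_bases <- list(
  A = .base_xy(matrix(c(
    -2.479, 5.346,
    -1.291, 4.498,
    0.024, 4.897,
    0.877, 3.902,
    0.071, 2.771,
    0.369, 1.398,
    1.611, 0.909,
    -0.668, 0.532,
    -1.912, 1.023,
    -2.320, 2.290,
    -1.267, 3.124
  ), ncol = 2, byrow = TRUE, dimnames = list(
    c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"), NULL
  ))),
  G = .base_xy(matrix(c(
    -2.477, 5.399,
    -1.289, 4.551,
    0.023, 4.962,
    0.870, 3.969,
    0.071, 2.833,
    0.424, 1.460,
    1.554, 0.955,
    -0.700, 0.641,
    -1.999, 1.087,
    -2.949, 0.139,
    -2.342, 2.364,
    -1.265, 3.177
  ), ncol = 2, byrow = TRUE, dimnames = list(
    c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"), NULL
  ))),
  T = .base_xy(matrix(c(
    -2.481, 5.354,
    -1.284, 4.500,
    -1.462, 3.135,
    -2.562, 2.608,
    -0.298, 2.407,
    0.994, 2.897,
    1.944, 2.119,
    1.106, 4.338,
    2.466, 4.961,
    -0.024, 5.057
  ), ncol = 2, byrow = TRUE, dimnames = list(
    c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"), NULL
  ))),
  C = .base_xy(matrix(c(
    -2.477, 5.402,
    -1.285, 4.542,
    -1.472, 3.158,
    -2.628, 2.709,
    -0.391, 2.344,
    0.837, 2.868,
    1.875, 2.027,
    1.056, 4.275,
    -0.023, 5.068
  ), ncol = 2, byrow = TRUE, dimnames = list(
    c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"), NULL
  )))
)

.purines <- c("A", "G")
.pyrimidines <- c("T", "C")

.base_ring_atoms <- list(
  purine = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# Canonical Watson-Crick heavy-atom hydrogen bonds, named from the purine side.
.wc_hbonds <- list(
  `A:T` = list(c("N6", "O4"), c("N1", "N3")),
  `G:C` = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2"))
)

.wc_partner <- c(A = "T", T = "A", G = "C", C = "G")

#' Standard base geometry
#'
#' Returns the embedded idealized planar geometry of a nucleobase in the
#' standard base-fixed reference frame used throughout the package.
#'
#' @param base One of `"A"`, `"T"`, `"G"`, `"C"`.
#' @return Matrix of atom coordinates (rows named by atom).
#' @export
standard_base <- function(base) {
  base <- toupper(base)
  if (!base %in% names(.std_bases)) {
    stop("no standard geometry for base '", base, "'", call. = FALSE)
  }
  .std_bases[[base]]
}

base_type_of <- function(base) {
  ifelse(toupper(base) %in% .purines, "purine", "pyrimidine")
}

ring_atoms_of <- function(base) {
  .base_ring_atoms[[base_type_of(base)]]
}

wc_hbond_atoms <- function(base1, base2) {
  b1 <- toupper(base1); b2 <- toupper(base2)
  # normalize to purine:pyrimidine order
  if (b1 %in% .purines && .wc_partner[[b1]] == b2) {
    bonds <- .wc_hbonds[[paste(b1, b2, sep = ":")]]
    if (!is.null(bonds)) return(list(order = c(1, 2), bonds = bonds))
  }
  if (b2 %in% .purines && .wc_partner[[b2]] == b1) {
    bonds <- .wc_hbonds[[paste(b2, b1, sep = ":")]]
    if (!is.null(bonds)) return(list(order = c(2, 1), bonds = bonds))
  }
  NULL
}
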