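# Altona-Sundaralingam pseudorotation analysis of five-membered sugar rings.
#
# The five endocyclic torsions of a furanose follow (to good approximation)
# the cosine series  nu_j = nu_max * cos(P + 144 * (j - 2)),  j = 0..4,
# so the pucker is summarized by a phase P (which atom is out of plane) and
# an amplitude nu_max (how far). nu2, the torsion about C2'-C3' with j = 2,
# is the reference: nu2 = nu_max * cos(P).

#' Endocyclic ring torsions from five ring-atom coordinates
#'
#' @param ring A 5 x 3 matrix of ring atom coordinates in the conventional
#'   order O4', C1', C2', C3', C4' (rows may be named; the order is what
#'   counts).
#' @return Named numeric vector `nu0`..`nu4` in degrees, with
#'   nu0 = C4'-O4'-C1'-C2', nu1 = O4'-C1'-C2'-C3', nu2 = C1'-C2'-C3'-C4',
#'   nu3 = C2'-C3'-C4'-O4', nu4 = C3'-C4'-O4'-C1'.
#' @export
ring_torsions <- function(ring) {
  stopifnot(is.matrix(ring), nrow(ring) == 5, ncol(ring) == 3)
  # ring order: O4'(1) C1'(2) C2'(3) C3'(4) C4'(5)
  idx <- list(
    nu0 = c(5, 1, 2, 3),
    nu1 = c(1, 2, 3, 4),
    nu2 = c(2, 3, 4, 5),
    nu3 = c(3, 4, 5, 1),
    nu4 = c(4, 5, 1, 2)
  )
  vapply(idx, function(q) dihedral(ring[q[1], ], ring[q[2], ], ring[q[3], ], ring[q[4], ]), 0)
}

#' Endocyclic torsions of an annotated nucleotide
#'
#' @param ann An `xna_annotated` object.
#' @param idx Row index into `annotated_residues(ann)`.
#' @return Named vector `nu0`..`nu4` (degrees).
#' @export
endocyclic_torsions <- function(ann, idx) {
  chem <- chem_of(ann, idx)
  m <- residue_coords(ann, idx)
  missing <- setdiff(chem$ring_atoms, rownames(m))
  if (length(missing)) {
    stop(
      "incomplete ring in ", ann$residues$resid[idx], " ",
      ann$residues$chain[idx], ":", ann$residues$resno[idx],
      ": missing atom(s) ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ring_torsions(m[chem$ring_atoms, , drop = FALSE])
}

#' Pseudorotation phase and amplitude from endocyclic torsions
#'
#' Uses the atan2 form, which is well-behaved where the tangent form blows up
#' (P near 90 or 270 degrees):
#' `P = atan2((nu4 + nu1) - (nu3 + nu0), 2 * nu2 * (sin 36 + sin 72))`,
#' mapped to \[0, 360); `nu_max = |nu2 / cos(P)|`, recovered from the
#' numerator term when nu2 is near zero. Rings flatter than `planarity`
#' (default 5 degrees on nu_max) are flagged degenerate with `P = NA`.
#'
#' @param nu Numeric 5-vector `nu0`..`nu4` (degrees).
#' @param planarity Amplitude floor (degrees) below which the pucker is
#'   degenerate.
#' @return List with `P` (degrees in \[0, 360), `NA` if degenerate),
#'   `nu_max` (degrees, >= 0), and `degenerate` (logical).
#' @export
pseudorotation <- function(nu, planarity = 5) {
  stopifnot(length(nu) == 5)
  nu <- as.numeric(nu)
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1]) # (nu4 + nu1) - (nu3 + nu0)
  den <- 2 * nu[3] * (sin(36 * DEG) + sin(72 * DEG))
  if (all(abs(nu) < 1e-9)) {
    return(list(P = NA_real_, nu_max = 0, degenerate = TRUE))
  }
  P <- wrap_angle_360(atan2(num, den) / DEG)
  nu_max <- if (abs(cos(P * DEG)) > 0.1) {
    abs(nu[3] / cos(P * DEG))
  } else {
    # near P = 90/270 the reference torsion vanishes; use the numerator term:
    # (nu4 + nu1) - (nu3 + nu0) = nu_max * sin(P) * 2 * (sin 36 + sin 72)
    abs(num / (2 * (sin(36 * DEG) + sin(72 * DEG)) * sin(P * DEG)))
  }
  if (nu_max < planarity) {
    return(list(P = NA_real_, nu_max = nu_max, degenerate = TRUE))
  }
  list(P = P, nu_max = nu_max, degenerate = FALSE)
}

# The 20 canonical envelope/twist states, one per 18-degree bin. Envelope
# states sit at bin centers 18, 54, ... (odd multiples of 18); twist states
# at 0, 36, ... Bin k covers [18k - 9, 18k + 9).
.pucker_states <- c(
  "C3'-endo/C2'-exo-twist", # 0
  "C3'-endo", # 18
  "C3'-endo/C4'-exo-twist", # 36
  "C4'-exo", # 54
  "O4'-endo/C4'-exo-twist", # 72
  "O4'-endo", # 90
  "C1'-exo/O4'-endo-twist", # 108
  "C1'-exo", # 126
  "C2'-endo/C1'-exo-twist", # 144
  "C2'-endo", # 162
  "C2'-endo/C3'-exo-twist", # 180
  "C3'-exo", # 198
  "C4'-endo/C3'-exo-twist", # 216
  "C4'-endo", # 234
  "O4'-exo/C4'-endo-twist", # 252
  "O4'-exo", # 270
  "C1'-endo/O4'-exo-twist", # 288
  "C1'-endo", # 306
  "C2'-exo/C1'-endo-twist", # 324
  "C2'-exo" # 342
)

#' Classify a sugar pucker on the pseudorotation wheel
#'
#' Bins P into the 20 canonical 18-degree envelope/twist states (C3'-endo
#' centered at 18 degrees, C4'-exo at 54, O4'-endo at 90, C2'-endo at 162,
#' ...) and assigns the wheel quadrant: north \[315, 45), east \[45, 135),
#' south \[135, 225), west \[225, 315).
#'
#' @param P Pseudorotation phase in degrees.
#' @param nu_max Amplitude in degrees; classification is refused below the
#'   planarity floor.
#' @param planarity Amplitude floor in degrees (default 5).
#' @return List with `conformer` (20-state bin), `envelope` (nearest pure
#'   envelope state, 36-degree bins -- the loose label common in the
#'   literature, where e.g. P = 181 is still called C2'-endo), and
#'   `quadrant`.
#' @export
classify_pucker <- function(P, nu_max, planarity = 5) {
  if (is.na(P) || nu_max < planarity) {
    stop("degenerate pucker (nu_max below planarity threshold): classification refused",
      call. = FALSE
    )
  }
  P <- wrap_angle_360(P)
  bin <- (floor((P + 9) / 18)) %% 20
  conformer <- .pucker_states[bin + 1]
  env_bin <- round((P - 18) / 36) %% 10 # nearest envelope center (18 + 36k)
  envelope <- .pucker_states[2 * env_bin + 2]
  quadrant <- if (P >= 315 || P < 45) {
    "north"
  } else if (P < 135) {
    "east"
  } else if (P < 225) {
    "south"
  } else {
    "west"
  }
  list(conformer = conformer, envelope = envelope, quadrant = quadrant)
}

#' Per-residue sugar pucker table
#'
#' Computes endocyclic torsions, pseudorotation phase/amplitude and conformer
#' classification for every annotated nucleotide.
#'
#' @param ann An `xna_annotated` object.
#' @param planarity Amplitude floor in degrees (default 5).
#' @return Tibble with one row per nucleotide: `chain`, `resno`, `ins`,
#'   `resid`, `chemistry_id`, `nu0`..`nu4`, `P`, `nu_max`, `conformer`,
#'   `quadrant`, `degenerate`.
#' @export
sugar_pucker <- function(ann, planarity = 5) {
  stopifnot(inherits(ann, "xna_annotated"))
  res <- ann$residues
  rows <- purrr::map(seq_len(nrow(res)), function(i) {
    nu <- endocyclic_torsions(ann, i)
    ps <- pseudorotation(nu, planarity = planarity)
    cls <- if (ps$degenerate) {
      list(
        conformer = NA_character_, envelope = NA_character_,
        quadrant = NA_character_
      )
    } else {
      classify_pucker(ps$P, ps$nu_max, planarity = planarity)
    }
    tibble::tibble(
      chain = res$chain[i], resno = res$resno[i], ins = res$ins[i],
      resid = res$resid[i], chemistry_id = res$chemistry_id[i],
      nu0 = unname(nu[1]), nu1 = unname(nu[2]), nu2 = unname(nu[3]),
      nu3 = unname(nu[4]), nu4 = unname(nu[5]),
      P = ps$P, nu_max = ps$nu_max,
      conformer = cls$conformer, envelope = cls$envelope,
      quadrant = cls$quadrant,
      degenerate = ps$degenerate
    )
  })
  dplyr::bind_rows(rows)
}

#' Pseudorotation-wheel plot coordinates
#'
#' Polar export of a pucker table (P as angle, nu_max as radius) for wheel
#' plots; also returns the Cartesian projection for plain scatter plots.
#'
#' @param pucker A tibble from [sugar_pucker()].
#' @return The table with added `wheel_x`, `wheel_y` columns.
#' @export
pucker_wheel_coords <- function(pucker) {
  dplyr::mutate(pucker,
    wheel_x = .data$nu_max * sin(.data$P * DEG),
    wheel_y = .data$nu_max * cos(.data$P * DEG)
  )
}
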