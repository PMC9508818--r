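# Base reference frames, Watson-Crick pair detection with heavy-atom
# hydrogen-bond distances, and base-pair / base-pair-step parameters.
#
# Frames: each observed base is least-squares fitted (Kabsch, on the base
# ring atoms) to the embedded standard geometry of its base type; the frame
# is the rigid transform carrying the standard frame onto the observed base.
# Pair and step parameters use the mid-frame construction: the "average"
# frame reached by rotating halfway between two frames, with the six rigid
# body descriptors read off as the rotation vector (tilt, roll, twist) and
# displacement (shift, slide, rise) expressed in the mid-frame. Positive
# twist is right-handed. The same construction is inverted exactly by the
# duplex generator, so build -> measure round-trips are tight.

flip_frame <- function(R) R %*% diag(c(1, -1, -1))

# Fit the standard base onto observed coordinates; returns frame = list(
# origin 3-vector, R 3x3 with columns x/y/z axes, fit rmsd).
fit_base_frame <- function(obs, base) {
  std <- standard_base(base)
  ring <- ring_atoms_of(base)
  common <- intersect(ring, rownames(obs))
  if (length(common) < length(ring)) {
    stop(
      "base frame refused: missing base atom(s) ",
      paste(setdiff(ring, rownames(obs)), collapse = ", "),
      call. = FALSE
    )
  }
  fit <- kabsch(std[common, , drop = FALSE], obs[common, , drop = FALSE])
  list(
    origin = as.vector(fit$translation),
    R = fit$rotation,
    fit_rmsd = fit$rmsd
  )
}

#' Base reference frame of an annotated nucleotide
#'
#' Least-squares fit of the observed base ring to the embedded standard
#' geometry of its base type. The returned rotation's columns are the frame
#' axes; the origin is the image of the standard frame origin.
#'
#' @param ann An `xna_annotated` object.
#' @param idx Row index into `annotated_residues(ann)`.
#' @return List with `origin`, `R` (3x3 proper rotation), `fit_rmsd`.
#' @export
base_frame <- function(ann, idx) {
  fit_base_frame(residue_coords(ann, idx), ann$residues$base[idx])
}

#' Detect Watson-Crick base pairs between two strands
#'
#' Candidate pairs are enumerated by complementarity (A-T, G-C) across the
#' two chains and accepted when every canonical heavy-atom hydrogen bond
#' (A-T: N6...O4 and N1...N3; G-C: O6...N4, N1...N3 and N2...O2) is at most
#' `cutoff` long and the base planes are roughly antiparallel (frame z-axes
#' dot product < 0).
#'
#' @param ann An `xna_annotated` object.
#' @param chain1,chain2 Chain identifiers of the two strands.
#' @param cutoff Heavy-atom H-bond acceptance cutoff in Angstrom
#'   (default 3.5).
#' @return Tibble with one row per accepted pair: residue identifiers for
#'   both strands, `hbonds` (list-column of per-bond tibbles with `atom_i`,
#'   `atom_j`, `dist`), `hbond_max`, `hbond_min`, and `z_dot`. An empty
#'   result is valid.
#' @export
find_basepairs <- function(ann, chain1, chain2, cutoff = 3.5) {
  stopifnot(inherits(ann, "xna_annotated"))
  res <- ann$residues
  i1 <- which(res$chain == chain1)
  i2 <- which(res$chain == chain2)
  rows <- list()
  for (i in i1) {
    ci <- residue_coords(ann, i)
    for (j in i2) {
      hb <- wc_hbond_atoms(res$base[i], res$base[j])
      if (is.null(hb)) next
      cj <- residue_coords(ann, j)
      coords <- list(ci, cj)[hb$order] # purine first, pyrimidine second
      dists <- purrr::map(hb$bonds, function(bd) {
        if (!bd[1] %in% rownames(coords[[1]]) || !bd[2] %in% rownames(coords[[2]])) {
          return(NULL)
        }
        tibble::tibble(
          atom_i = bd[1], atom_j = bd[2],
          dist = vnorm(coords[[1]][bd[1], ] - coords[[2]][bd[2], ])
        )
      })
      if (any(vapply(dists, is.null, TRUE))) next
      dists <- dplyr::bind_rows(dists)
      if (any(dists$dist > cutoff) || any(dists$dist <= 2.0)) next
      fi <- base_frame(ann, i)
      fj <- base_frame(ann, j)
      zdot <- sum(fi$R[, 3] * fj$R[, 3])
      if (zdot >= 0) next # parallel stacking, not a WC pair
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain_i = res$chain[i], resno_i = res$resno[i], resid_i = res$resid[i],
        base_i = res$base[i], idx_i = i,
        chain_j = res$chain[j], resno_j = res$resno[j], resid_j = res$resid[j],
        base_j = res$base[j], idx_j = j,
        hbonds = list(dists),
        hbond_min = min(dists$dist), hbond_max = max(dists$dist),
        z_dot = zdot
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      chain_i = character(), resno_i = integer(), resid_i = character(),
      base_i = character(), idx_i = integer(),
      chain_j = character(), resno_j = integer(), resid_j = character(),
      base_j = character(), idx_j = integer(),
      hbonds = list(), hbond_min = double(), hbond_max = double(),
      z_dot = double()
    ))
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$resno_i)
}

#' Long-format hydrogen-bond distance table
#' @param pairs Tibble from [find_basepairs()].
#' @return Tibble with one row per hydrogen bond.
#' @export
hbond_distances <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(tibble::tibble(
      chain_i = character(), resno_i = integer(), chain_j = character(),
      resno_j = integer(), atom_i = character(), atom_j = character(),
      dist = double()
    ))
  }
  pairs |>
    dplyr::select("chain_i", "resno_i", "chain_j", "resno_j", "hbonds") |>
    tidyr::unnest("hbonds")
}

# ---------------------------------------------------------------------------
# Frame algebra: six rigid-body descriptors between two frames via the
# mid-frame (half-rotation) construction.

# Parameters carrying frame1 onto frame2. Returns c(rot1, rot2, rot3 [deg],
# tra1, tra2, tra3 [A]) where rot is the relative rotation vector and tra the
# origin displacement, both expressed in the mid-frame.
frame_step <- function(f1, f2) {
  rel <- f2$R %*% t(f1$R) # lab-frame rotation from f1 to f2
  aa <- rotation_axis_angle(rel)
  Rm <- half_rotation(rel) %*% f1$R
  rot <- aa$angle * as.vector(t(Rm) %*% aa$axis)
  tra <- as.vector(t(Rm) %*% (f2$origin - f1$origin))
  list(rot = rot, tra = tra, mid = list(R = Rm, origin = (f1$origin + f2$origin) / 2))
}

# Inverse of frame_step: given frame1 and the six descriptors, construct
# frame2. Exact inverse of the construction above.
frame_step_apply <- function(f1, rot, tra) {
  gamma <- vnorm(rot)
  if (gamma < 1e-12) {
    Rm <- f1$R
    R2 <- f1$R
  } else {
    axis_lab <- as.vector(f1$R %*% (rot / gamma))
    rel <- rotation_about(axis_lab, gamma)
    R2 <- rel %*% f1$R
    Rm <- half_rotation(rel) %*% f1$R
  }
  o2 <- f1$origin + as.vector(Rm %*% tra)
  list(R = R2, origin = o2)
}

# Intra-pair parameters between strand-1 base frame f1 and strand-2 base
# frame f2 (f2 flipped about its x-axis so both frames point the same way).
# Order: shear, stretch, stagger, buckle, propeller, opening.
pair_params_frames <- function(f1, f2) {
  f2f <- list(R = flip_frame(f2$R), origin = f2$origin)
  st <- frame_step(f2f, f1)
  list(
    params = c(
      shear = st$tra[1], stretch = st$tra[2], stagger = st$tra[3],
      buckle = st$rot[1], propeller = st$rot[2], opening = st$rot[3]
    ),
    mid = st$mid
  )
}

#' Base-pair and base-pair-step parameters
#'
#' Computes the six intra-pair parameters (shear, stretch, stagger in
#' Angstrom; buckle, propeller, opening in degrees) for each accepted pair,
#' and the six step parameters (shift, slide, rise; tilt, roll, twist)
#' between consecutive pair mid-frames. Pairs are ordered by strand-1
#' residue number; positive twist is right-handed.
#'
#' @param ann An `xna_annotated` object.
#' @param pairs Tibble from [find_basepairs()].
#' @return List with `pairs` (per-pair parameter tibble) and `steps`
#'   (per-step tibble, empty when fewer than two pairs).
#' @export
pair_and_step_params <- function(ann, pairs) {
  if (nrow(pairs) == 0) {
    stop("no accepted base pairs", call. = FALSE)
  }
  per <- purrr::map(seq_len(nrow(pairs)), function(k) {
    f1 <- base_frame(ann, pairs$idx_i[k])
    f2 <- base_frame(ann, pairs$idx_j[k])
    pp <- pair_params_frames(f1, f2)
    list(
      row = dplyr::bind_cols(
        pairs[k, c(
          "chain_i", "resno_i", "resid_i", "chain_j", "resno_j", "resid_j"
        )],
        tibble::as_tibble(as.list(pp$params))
      ),
      mid = pp$mid
    )
  })
  pair_tbl <- dplyr::bind_rows(purrr::map(per, "row"))
  mids <- purrr::map(per, "mid")
  steps <- if (length(mids) >= 2) {
    dplyr::bind_rows(purrr::map(seq_len(length(mids) - 1), function(k) {
      st <- frame_step(mids[[k]], mids[[k + 1]])
      tibble::tibble(
        resno_i = pair_tbl$resno_i[k], resno_j = pair_tbl$resno_i[k + 1],
        shift = st$tra[1], slide = st$tra[2], rise = st$tra[3],
        tilt = st$rot[1], roll = st$rot[2], twist = st$rot[3]
      )
    }))
  } else {
    tibble::tibble(
      resno_i = integer(), resno_j = integer(),
      shift = double(), slide = double(), rise = double(),
      tilt = double(), roll = double(), twist = double()
    )
  }
  list(pairs = pair_tbl, steps = steps)
}
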