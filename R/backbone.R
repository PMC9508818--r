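# Chemistry-specific exocyclic backbone torsions, glycosidic chi,
# phosphorus-phosphorus spacings, and chi/delta A/B-form classification.

# Resolve one torsion atom reference for residue idx. Returns list(coord) or
# list(fail = "reason").
resolve_torsion_atom <- function(ann, idx, ref) {
  res <- ann$residues
  get_from <- function(j, name, what) {
    if (is.na(j)) {
      return(list(fail = paste0("chain terminus (no ", what, " neighbor)")))
    }
    co <- atom_coord(ann, j, name)
    if (is.null(co)) {
      return(list(fail = paste0("missing atom ", name, " in neighbor ", res$resno[j])))
    }
    list(coord = co)
  }
  if (ref == "@donor-1") {
    j <- res$prev[idx]
    if (is.na(j)) {
      return(list(fail = "chain terminus (no upstream neighbor)"))
    }
    return(get_from(j, chem_of(ann, j)$linkage_donor, "upstream"))
  }
  if (ref == "@p+1") {
    j <- res$nxt[idx]
    if (is.na(j)) {
      return(list(fail = "chain terminus (no downstream neighbor)"))
    }
    return(get_from(j, chem_of(ann, j)$phosphorus_atom, "downstream"))
  }
  if (ref == "@afterp+1") {
    j <- res$nxt[idx]
    if (is.na(j)) {
      return(list(fail = "chain terminus (no downstream neighbor)"))
    }
    return(get_from(j, chem_of(ann, j)$backbone_path[2], "downstream"))
  }
  if (grepl("-1$", ref)) {
    return(get_from(res$prev[idx], sub("-1$", "", ref), "upstream"))
  }
  if (grepl("\\+1$", ref)) {
    return(get_from(res$nxt[idx], sub("\\+1$", "", ref), "downstream"))
  }
  co <- atom_coord(ann, idx, ref)
  if (is.null(co)) {
    return(list(fail = paste0("missing atom ", ref)))
  }
  list(coord = co)
}

# Compute one named torsion for residue idx: list(value, status).
measure_torsion <- function(ann, idx, atom_refs) {
  pts <- vector("list", 4)
  for (k in 1:4) {
    r <- resolve_torsion_atom(ann, idx, atom_refs[k])
    if (!is.null(r$fail)) {
      return(list(value = NA_real_, status = r$fail))
    }
    pts[[k]] <- r$coord
  }
  list(
    value = dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
    status = "measured"
  )
}

#' Exocyclic backbone torsions and glycosidic chi for one nucleotide
#'
#' Every torsion declared in the residue's chemistry definition is either
#' measured or explicitly marked unmeasurable (chain terminus or missing
#' atom) -- never silently absent. Chi uses O4'-C1'-N9-C4 for purines and
#' O4'-C1'-N1-C2 for pyrimidines.
#'
#' @param ann An `xna_annotated` object.
#' @param idx Row index into `annotated_residues(ann)`.
#' @return Tibble with one row per torsion (`torsion`, `value`, `status`)
#'   including `chi`, plus the attribute `"delta_analog"` naming the
#'   sugar-coupled torsion for this chemistry.
#' @export
exocyclic_torsions <- function(ann, idx) {
  chem <- chem_of(ann, idx)
  rows <- purrr::imap(chem$torsions, function(refs, nm) {
    m <- measure_torsion(ann, idx, refs)
    tibble::tibble(torsion = nm, value = m$value, status = m$status)
  })
  quad <- if (ann$residues$base_type[idx] == "purine") {
    chem$glycosidic_quad_purine
  } else {
    chem$glycosidic_quad_pyrimidine
  }
  chi <- measure_torsion(ann, idx, quad)
  out <- dplyr::bind_rows(c(rows, list(
    tibble::tibble(torsion = "chi", value = chi$value, status = chi$status)
  )))
  attr(out, "delta_analog") <- chem$delta_analog
  out
}

#' Per-residue backbone torsion table
#'
#' Wide table: one row per annotated nucleotide, one column per torsion label
#' occurring in any chemistry present, plus `chi` and `delta_like` (the value
#' of each chemistry's declared delta-analog). Unmeasurable torsions are `NA`
#' with the reason collected in `notes`; labels not defined for a residue's
#' chemistry are `NA` without a note.
#'
#' @param ann An `xna_annotated` object.
#' @return Tibble, one row per nucleotide.
#' @export
backbone_torsions <- function(ann) {
  stopifnot(inherits(ann, "xna_annotated"))
  res <- ann$residues
  rows <- purrr::map(seq_len(nrow(res)), function(i) {
    tor <- exocyclic_torsions(ann, i)
    da <- attr(tor, "delta_analog")
    wide <- tidyr::pivot_wider(tor[, c("torsion", "value")],
      names_from = "torsion", values_from = "value"
    )
    bad <- tor[tor$status != "measured", ]
    notes <- if (nrow(bad)) {
      paste(paste0(bad$torsion, ": ", bad$status), collapse = "; ")
    } else {
      ""
    }
    dplyr::bind_cols(
      tibble::tibble(
        chain = res$chain[i], resno = res$resno[i], ins = res$ins[i],
        resid = res$resid[i], chemistry_id = res$chemistry_id[i]
      ),
      wide,
      tibble::tibble(
        delta_like = tor$value[tor$torsion == da],
        notes = notes
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Phosphorus-phosphorus backbone spacings
#'
#' Euclidean distance between the bridging phosphorus atoms (phosphate or
#' phosphonate) of consecutive linked residues, one value per backbone step.
#' Steps whose phosphorus is missing are reported unmeasurable rather than
#' dropped.
#'
#' @param ann An `xna_annotated` object.
#' @return Tibble: `chain`, `resno_i`, `resid_i`, `resno_j`, `resid_j`,
#'   `p_p_distance` (Angstrom, `NA` if unmeasurable), `status`.
#' @export
p_p_distances <- function(ann) {
  stopifnot(inherits(ann, "xna_annotated"))
  res <- ann$residues
  steps <- which(!is.na(res$nxt))
  rows <- purrr::map(steps, function(i) {
    j <- res$nxt[i]
    pi_ <- atom_coord(ann, i, chem_of(ann, i)$phosphorus_atom)
    pj <- atom_coord(ann, j, chem_of(ann, j)$phosphorus_atom)
    if (is.null(pi_) || is.null(pj)) {
      miss <- c(
        if (is.null(pi_)) paste0(res$resno[i], ":", chem_of(ann, i)$phosphorus_atom),
        if (is.null(pj)) paste0(res$resno[j], ":", chem_of(ann, j)$phosphorus_atom)
      )
      d <- NA_real_
      status <- paste0("missing phosphorus (", paste(miss, collapse = ", "), ")")
    } else {
      d <- vnorm(pi_ - pj)
      status <- "measured"
    }
    tibble::tibble(
      chain = res$chain[i],
      resno_i = res$resno[i], resid_i = res$resid[i],
      resno_j = res$resno[j], resid_j = res$resid[j],
      p_p_distance = d, status = status
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      chain = character(), resno_i = integer(), resid_i = character(),
      resno_j = integer(), resid_j = character(),
      p_p_distance = double(), status = character()
    )
  }
  out
}

#' Default chi/delta A/B-form region boundaries
#'
#' Conventional fiber-diffraction-derived rectangles in the (chi, delta)
#' plane. Chi is taken in (-180, 180] with wraparound handled.
#'
#' @return Named list of the two regions.
#' @export
chi_delta_regions <- function() {
  list(
    A = list(delta = c(55, 110), chi = c(-190, -138)),
    B = list(delta = c(110, 175), chi = c(-140, -70))
  )
}

#' Classify (chi, delta) into A-like / B-like / intermediate
#'
#' Rectangular regions, half-open on delta with the boundary assigned to the
#' B side (delta = 110 is B-like). Chi intervals may extend below -180 to
#' express wraparound; the input is compared modulo 360.
#'
#' @param chi,delta Angles in degrees (vectorized).
#' @param regions Region list as from [chi_delta_regions()].
#' @return Character vector: `"A-like"`, `"B-like"` or `"intermediate"`;
#'   `NA` inputs are an error (classification refused).
#' @export
chi_delta_classify <- function(chi, delta, regions = chi_delta_regions()) {
  if (any(is.na(chi)) || any(is.na(delta))) {
    stop("chi/delta unmeasurable: classification refused", call. = FALSE)
  }
  in_chi <- function(x, lim) {
    # compare on a wrapped circle: test x, x - 360, x + 360 against [lo, hi]
    any((c(x, x - 360, x + 360) >= lim[1]) & (c(x, x - 360, x + 360) <= lim[2]))
  }
  vapply(seq_along(chi), function(i) {
    ch <- wrap_angle(chi[i])
    de <- delta[i]
    # B checked first so the shared delta boundary at 110 lands in B
    if (de >= regions$B$delta[1] && de <= regions$B$delta[2] &&
      in_chi(ch, regions$B$chi)) {
      return("B-like")
    }
    if (de >= regions$A$delta[1] && de < regions$A$delta[2] &&
      in_chi(ch, regions$A$chi)) {
      return("A-like")
    }
    "intermediate"
  }, "")
}

#' Add form classification to a backbone torsion table
#'
#' @param torsions Tibble from [backbone_torsions()].
#' @param regions Region list as from [chi_delta_regions()].
#' @return The table with a `form` column (`NA` where chi or delta_like is
#'   unmeasurable).
#' @export
classify_form <- function(torsions, regions = chi_delta_regions()) {
  form <- rep(NA_character_, nrow(torsions))
  ok <- !is.na(torsions$chi) & !is.na(torsions$delta_like)
  if (any(ok)) {
    form[ok] <- chi_delta_classify(
      torsions$chi[ok], torsions$delta_like[ok],
      regions = regions
    )
  }
  dplyr::mutate(torsions, form = form)
}
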