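# Structure model: tidy atom tables read from PDB/mmCIF, altloc resolution,
# and chemistry annotation against the registry.
#
# A structure is a tibble with one row per atom and columns:
#   record  "ATOM" or "HETATM"
#   chain   chain identifier
#   resno   author residue number (integer)
#   ins     insertion code ("" if none)
#   resid   residue code as deposited
#   elety   atom name, primed characters as deposited
#   elesy   element symbol
#   alt     altloc label ("" if none)
#   x, y, z coordinates (Angstrom)
#   o       occupancy
#   b       isotropic B-factor (Angstrom^2)

residue_key <- function(chain, resno, ins) paste(chain, resno, ins, sep = "|")

new_structure_tbl <- function(df) {
  tibble::new_tibble(df, class = "xna_structure")
}

#' @export
print.xna_structure <- function(x, ...) {
  cat(
    "<xna_structure> ", nrow(x), " atoms, ",
    dplyr::n_distinct(residue_key(x$chain, x$resno, x$ins)), " residues, ",
    dplyr::n_distinct(x$chain), " chain(s)\n",
    sep = ""
  )
  NextMethod()
}

#' Read a macromolecular structure into a tidy atom table
#'
#' Parses PDB or mmCIF (via bio3d) into one row per atom. Heteroatoms
#' (ligands, waters, ions) are retained with their deposited residue codes;
#' author numbering and altloc labels are preserved. Only the first model of
#' a multi-model file is read.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return An atom tibble (class `xna_structure`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) {
      stop("could not parse '", path, "' as ", format, ": ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("empty structure: ", path, call. = FALSE)
  }
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  new_structure_tbl(tibble::tibble(
    record = as.character(at$type),
    chain = blank(at$chain),
    resno = as.integer(at$resno),
    ins = blank(at$insert),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesy = blank(at$elesy),
    alt = blank(at$alt),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b)
  ))
}

#' Write a structure as PDB or normalized mmCIF
#'
#' PDB output goes through bio3d; mmCIF output is a minimal `atom_site` loop
#' with author numbering in both auth and label fields.
#'
#' @param atoms An atom tibble.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  n <- nrow(atoms)
  if (format == "pdb") {
    xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
    bio3d::write.pdb(
      file = path,
      type = atoms$record,
      eleno = seq_len(n),
      elety = atoms$elety,
      alt = ifelse(atoms$alt == "", "", atoms$alt),
      resid = atoms$resid,
      chain = atoms$chain,
      resno = atoms$resno,
      insert = ifelse(atoms$ins == "", "", atoms$ins),
      o = atoms$o,
      b = atoms$b,
      elesy = atoms$elesy,
      xyz = xyz
    )
  } else {
    # canonical wwPDB atom_site column order; primed atom names are legal
    # bare CIF values so no quoting is needed
    fmtnum <- function(v) formatC(v, format = "f", digits = 3)
    dot <- function(v) ifelse(v == "" | is.na(v), ".", v)
    lines <- c(
      "data_xnageom",
      "#",
      "loop_",
      "_atom_site.group_PDB",
      "_atom_site.id",
      "_atom_site.type_symbol",
      "_atom_site.label_atom_id",
      "_atom_site.label_alt_id",
      "_atom_site.label_comp_id",
      "_atom_site.label_asym_id",
      "_atom_site.label_entity_id",
      "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x",
      "_atom_site.Cartn_y",
      "_atom_site.Cartn_z",
      "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv",
      "_atom_site.pdbx_formal_charge",
      "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id",
      "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id",
      "_atom_site.pdbx_PDB_model_num",
      paste(
        atoms$record, seq_len(n), dot(atoms$elesy), atoms$elety,
        dot(atoms$alt), atoms$resid, atoms$chain, "1", atoms$resno,
        dot(atoms$ins),
        fmtnum(atoms$x), fmtnum(atoms$y), fmtnum(atoms$z),
        formatC(atoms$o, format = "f", digits = 2),
        formatC(atoms$b, format = "f", digits = 2),
        "?", atoms$resno, atoms$resid, atoms$chain, atoms$elety, "1"
      ),
      "#"
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Resolve alternate conformations
#'
#' Collapses altloc groups so each atom appears exactly once. With the
#' default `highest_occupancy` policy the highest-occupancy conformer wins,
#' ties broken by altloc label ascending (so `A` beats `B` at equal
#' occupancy); with `label` the lexicographically first altloc label is kept.
#' A report of residues that carried alternates is attached as the
#' `"altloc_report"` attribute (see [altloc_report()]). Structures without
#' altlocs pass through unchanged.
#'
#' @param atoms An atom tibble.
#' @param policy `"highest_occupancy"` or `"label"`.
#' @return The atom tibble with one row per atom.
#' @export
resolve_altlocs <- function(atoms, policy = c("highest_occupancy", "label")) {
  policy <- match.arg(policy)
  has_alt <- atoms$alt != ""
  report <- atoms |>
    dplyr::filter(.data$alt != "") |>
    dplyr::distinct(.data$chain, .data$resno, .data$ins, .data$resid, .data$alt) |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins, .data$resid) |>
    dplyr::summarise(
      altlocs = paste(sort(unique(.data$alt)), collapse = ","),
      .groups = "drop"
    )
  if (!any(has_alt)) {
    attr(atoms, "altloc_report") <- report
    return(atoms)
  }
  resolved <- atoms |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins, .data$resid, .data$elety) |>
    dplyr::arrange(
      if (policy == "highest_occupancy") -.data$o else 0,
      .data$alt,
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord") |>
    dplyr::mutate(alt = "")
  out <- new_structure_tbl(resolved)
  attr(out, "altloc_report") <- report
  out
}

#' Altloc resolution report
#' @param atoms A structure previously passed through [resolve_altlocs()].
#' @return Tibble of residues that had alternate conformations.
#' @export
altloc_report <- function(atoms) {
  rep <- attr(atoms, "altloc_report")
  if (is.null(rep)) {
    stop("no altloc report: run resolve_altlocs() first", call. = FALSE)
  }
  rep
}

# ---------------------------------------------------------------------------
# Chemistry annotation

#' Annotate nucleic residues with their backbone chemistry
#'
#' Looks every residue code up in the registry and, for nucleic residues,
#' records the chemistry, base, base type and backbone neighbor links.
#' Neighbors are established by covalent proximity of the declared linkage
#' atoms (donor of residue i to bridging phosphorus of residue j, distance
#' below `link_cutoff`), not by sequence numbering, so chemistry junctions
#' (e.g. a DNA primer extended with pTNA) link correctly.
#'
#' @param atoms An atom tibble (altlocs should be resolved first).
#' @param registry A `chemistry_registry`; default [default_registry()].
#' @param strict If `TRUE`, a nucleic-looking residue code missing from the
#'   registry is an error; if `FALSE` unknown codes are skipped with a
#'   warning. Codes are "nucleic-looking" when the residue contains the five
#'   ring atoms O4'/C1'/C2'/C3'/C4'.
#' @param link_cutoff Covalent bond threshold in Angstrom (default 2.0).
#' @return An `xna_annotated` object: list with `atoms` (the input tibble) and
#'   `residues`, a tibble with one row per annotated nucleotide carrying
#'   `chain`, `resno`, `ins`, `resid`, `chemistry_id`, `base`, `base_type`,
#'   and `prev`/`nxt` row indices of backbone neighbors (NA at termini).
#' @export
annotate_chemistry <- function(atoms, registry = default_registry(),
                               strict = TRUE, link_cutoff = 2.0) {
  res_tbl <- tibble::as_tibble(atoms) |>
    dplyr::distinct(.data$chain, .data$resno, .data$ins, .data$resid)
  known <- vapply(
    res_tbl$resid,
    function(rn) !is.null(registry_lookup(registry, rn)), TRUE
  )
  # nucleic-looking but unknown?
  ring <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  if (any(!known)) {
    unknown <- res_tbl[!known, ]
    looks_nucleic <- vapply(seq_len(nrow(unknown)), function(i) {
      sel <- atoms$chain == unknown$chain[i] &
        atoms$resno == unknown$resno[i] & atoms$ins == unknown$ins[i]
      all(ring %in% atoms$elety[sel])
    }, TRUE)
    if (any(looks_nucleic)) {
      codes <- unique(unknown$resid[looks_nucleic])
      if (strict) {
        stop(
          "unknown chemistry for nucleic residue code(s): ",
          paste(codes, collapse = ", "),
          " (add them to the registry or use strict = FALSE)",
          call. = FALSE
        )
      }
      warning(
        "skipping nucleic residue code(s) missing from registry: ",
        paste(codes, collapse = ", "),
        call. = FALSE
      )
    }
  }
  res_tbl <- res_tbl[known, , drop = FALSE]
  if (nrow(res_tbl) == 0) {
    return(structure(
      list(atoms = atoms, residues = tibble::tibble(
        chain = character(), resno = integer(), ins = character(),
        resid = character(), chemistry_id = character(), base = character(),
        base_type = character(), prev = integer(), nxt = integer()
      ), registry = registry),
      class = "xna_annotated"
    ))
  }
  info <- lapply(res_tbl$resid, function(rn) registry_lookup(registry, rn))
  residues <- res_tbl |>
    dplyr::mutate(
      chemistry_id = vapply(info, function(x) x$chemistry$chemistry_id, ""),
      base = vapply(info, function(x) x$base, ""),
      base_type = base_type_of(.data$base)
    )

  # backbone links by covalent proximity of donor(i) -> phosphorus(j)
  n <- nrow(residues)
  residues$prev <- NA_integer_
  residues$nxt <- NA_integer_
  donor_xyz <- matrix(NA_real_, n, 3)
  p_xyz <- matrix(NA_real_, n, 3)
  after_xyz <- matrix(NA_real_, n, 3) # backbone atom bonded to P, fallback
  for (i in seq_len(n)) {
    chem <- registry$chemistries[[residues$chemistry_id[i]]]
    sel <- atoms$chain == residues$chain[i] &
      atoms$resno == residues$resno[i] & atoms$ins == residues$ins[i]
    d <- which(sel & atoms$elety == chem$linkage_donor)
    p <- which(sel & atoms$elety == chem$phosphorus_atom)
    a <- which(sel & atoms$elety == chem$backbone_path[2])
    if (length(d)) donor_xyz[i, ] <- c(atoms$x[d[1]], atoms$y[d[1]], atoms$z[d[1]])
    if (length(p)) p_xyz[i, ] <- c(atoms$x[p[1]], atoms$y[p[1]], atoms$z[p[1]])
    if (length(a)) after_xyz[i, ] <- c(atoms$x[a[1]], atoms$y[a[1]], atoms$z[a[1]])
  }
  for (i in seq_len(n)) {
    if (anyNA(donor_xyz[i, ])) next
    same_chain <- which(residues$chain == residues$chain[i] & seq_len(n) != i)
    for (j in same_chain) {
      hit <- if (!anyNA(p_xyz[j, ])) {
        vnorm(donor_xyz[i, ] - p_xyz[j, ]) < link_cutoff
      } else if (!anyNA(after_xyz[j, ])) {
        # phosphorus unmodelled: the donor and the next backbone atom are
        # 1-3 neighbors across the absent P, roughly two bond lengths apart
        vnorm(donor_xyz[i, ] - after_xyz[j, ]) < link_cutoff + 1.0
      } else {
        FALSE
      }
      if (hit) {
        residues$nxt[i] <- j
        residues$prev[j] <- i
        break
      }
    }
  }
  structure(list(atoms = atoms, residues = residues, registry = registry),
    class = "xna_annotated"
  )
}

#' @export
print.xna_annotated <- function(x, ...) {
  cat(
    "<xna_annotated> ", nrow(x$residues), " annotated nucleotides (",
    paste(unique(x$residues$chemistry_id), collapse = ", "), "), ",
    nrow(x$atoms), " atoms total\n",
    sep = ""
  )
  invisible(x)
}

#' Annotated-residue table
#' @param ann An `xna_annotated` object.
#' @return The per-residue annotation tibble.
#' @export
annotated_residues <- function(ann) {
  stopifnot(inherits(ann, "xna_annotated"))
  ann$residues
}

#' Write the chemistry-annotation report as JSON
#' @param ann An `xna_annotated` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_report <- function(ann, path) {
  res <- ann$residues
  obj <- list(
    n_residues = nrow(res),
    chemistries = as.list(table(res$chemistry_id)),
    residues = as.data.frame(
      dplyr::mutate(res,
        linked_prev = !is.na(.data$prev),
        linked_next = !is.na(.data$nxt),
        prev = NULL, nxt = NULL
      )
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# Coordinates of one annotated residue's atoms as a named n x 3 matrix.
residue_coords <- function(ann, idx) {
  r <- ann$residues[idx, ]
  sel <- ann$atoms$chain == r$chain & ann$atoms$resno == r$resno &
    ann$atoms$ins == r$ins
  m <- as.matrix(ann$atoms[sel, c("x", "y", "z")])
  rownames(m) <- ann$atoms$elety[sel]
  m
}

# Fetch one atom's coordinates from residue idx (NULL if absent).
atom_coord <- function(ann, idx, name) {
  m <- residue_coords(ann, idx)
  if (!name %in% rownames(m)) {
    return(NULL)
  }
  m[name, ]
}

chem_of <- function(ann, idx) {
  ann$registry$chemistries[[ann$residues$chemistry_id[idx]]]
}
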