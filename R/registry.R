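# Chemistry registry: which residue codes belong to which backbone chemistry,
# and how each chemistry's repeat unit is wired (ring atoms, backbone path,
# inter-residue linkage, named torsions, glycosidic quads).
#
# Torsion atom references use residue-offset suffixes: a bare name refers to
# this residue; "name-1" / "name+1" refer to the backbone neighbors. Three
# symbolic tokens keep torsions well-defined across chemistry junctions
# (e.g. a DNA primer extended with pTNA residues):
#   "@donor-1"   the previous residue's linkage donor atom (O3' for DNA,
#                O2' for TNA/pTNA)
#   "@p+1"       the next residue's bridging phosphorus
#   "@afterp+1"  the next residue's backbone atom bonded to its phosphorus

#' Define a backbone chemistry
#'
#' @param chemistry_id Identifier, e.g. `"DNA"`, `"TNA"`, `"pTNA"`.
#' @param ring_atoms Ordered 5 atom names of the furanose ring, convention
#'   O4'-C1'-C2'-C3'-C4'.
#' @param backbone_path Ordered atom names of one repeat unit, starting at the
#'   bridging phosphorus.
#' @param linkage_donor Atom of this residue that bonds the next residue's
#'   phosphorus.
#' @param phosphorus_atom Name of the bridging phosphorus (phosphate or
#'   phosphonate).
#' @param torsions Named list; each element a character vector of 4 atom
#'   references (see file header for the offset syntax).
#' @param delta_analog Name of the torsion (in `torsions`) that couples to the
#'   sugar pucker and plays the role of delta in A/B-form analysis.
#' @param glycosidic_quad_purine,glycosidic_quad_pyrimidine 4 atom names each;
#'   the last two live on the base.
#' @return A `chemistry_definition` list.
#' @export
chemistry_definition <- function(chemistry_id, ring_atoms, backbone_path,
                                 linkage_donor, phosphorus_atom,
                                 torsions, delta_analog,
                                 glycosidic_quad_purine = c("O4'", "C1'", "N9", "C4"),
                                 glycosidic_quad_pyrimidine = c("O4'", "C1'", "N1", "C2")) {
  stopifnot(length(ring_atoms) == 5)
  if (!delta_analog %in% names(torsions)) {
    stop("delta_analog '", delta_analog, "' is not a declared torsion", call. = FALSE)
  }
  bad <- names(torsions)[vapply(torsions, length, 1L) != 4]
  if (length(bad)) {
    stop("torsion(s) ", paste(bad, collapse = ", "), " must have exactly 4 atoms",
      call. = FALSE
    )
  }
  structure(
    list(
      chemistry_id = chemistry_id,
      ring_atoms = ring_atoms,
      backbone_path = backbone_path,
      linkage_donor = linkage_donor,
      phosphorus_atom = phosphorus_atom,
      torsions = torsions,
      torsion_names = names(torsions),
      delta_analog = delta_analog,
      glycosidic_quad_purine = glycosidic_quad_purine,
      glycosidic_quad_pyrimidine = glycosidic_quad_pyrimidine
    ),
    class = "chemistry_definition"
  )
}

.dna_def <- function() {
  chemistry_definition(
    chemistry_id = "DNA",
    ring_atoms = c("O4'", "C1'", "C2'", "C3'", "C4'"),
    backbone_path = c("P", "O5'", "C5'", "C4'", "C3'", "O3'"),
    linkage_donor = "O3'",
    phosphorus_atom = "P",
    torsions = list(
      alpha = c("@donor-1", "P", "O5'", "C5'"),
      beta = c("P", "O5'", "C5'", "C4'"),
      gamma = c("O5'", "C5'", "C4'", "C3'"),
      delta = c("C5'", "C4'", "C3'", "O3'"),
      epsilon = c("C4'", "C3'", "O3'", "@p+1"),
      zeta = c("C3'", "O3'", "@p+1", "@afterp+1")
    ),
    delta_analog = "delta"
  )
}

# TNA: threofuranose, 3'->2' phosphodiester, five-atom repeat P-O3'-C3'-C2'-O2'.
# Torsion labels follow the nucleic-acid convention that delta is the
# sugar-coupled torsion and epsilon/zeta flank the downstream linkage; with a
# five-atom repeat there is no gamma-analog bond, so gamma is absent by design.
.tna_def <- function() {
  chemistry_definition(
    chemistry_id = "TNA",
    ring_atoms = c("O4'", "C1'", "C2'", "C3'", "C4'"),
    backbone_path = c("P", "O3'", "C3'", "C2'", "O2'"),
    linkage_donor = "O2'",
    phosphorus_atom = "P",
    torsions = list(
      alpha = c("@donor-1", "P", "O3'", "C3'"),
      beta = c("P", "O3'", "C3'", "C2'"),
      delta = c("O3'", "C3'", "C2'", "O2'"),
      epsilon = c("C3'", "C2'", "O2'", "@p+1"),
      zeta = c("C2'", "O2'", "@p+1", "@afterp+1")
    ),
    delta_analog = "delta"
  )
}

# pTNA: threofuranose, 3'->2' phosphonomethyl linkage; a methylene (C6') sits
# between O3' and the phosphonate phosphorus, giving a six-atom repeat
# P-C6'-O3'-C3'-C2'-O2'.
.ptna_def <- function() {
  chemistry_definition(
    chemistry_id = "pTNA",
    ring_atoms = c("O4'", "C1'", "C2'", "C3'", "C4'"),
    backbone_path = c("P", "C6'", "O3'", "C3'", "C2'", "O2'"),
    linkage_donor = "O2'",
    phosphorus_atom = "P",
    torsions = list(
      alpha = c("@donor-1", "P", "C6'", "O3'"),
      beta = c("P", "C6'", "O3'", "C3'"),
      gamma = c("C6'", "O3'", "C3'", "C2'"),
      delta = c("O3'", "C3'", "C2'", "O2'"),
      epsilon = c("C3'", "C2'", "O2'", "@p+1"),
      zeta = c("C2'", "O2'", "@p+1", "@afterp+1")
    ),
    delta_analog = "delta"
  )
}

#' Default chemistry registry
#'
#' Built-in residue-code mapping for DNA plus template definitions for TNA and
#' pTNA. The DNA codes are the wwPDB standard (`DA`, `DT`, `DG`, `DC`). The
#' TNA and pTNA adenosine codes deposited with real structures are ligand
#' codes that must be read from the files themselves; the registry therefore
#' ships the synthetic placeholder codes used by this package's generator
#' (`TA`/`TT`/`TG`/`TC` for TNA, `PA`/`PT`/`PG`/`PC` for pTNA) and expects
#' users analysing deposited models to add the real codes with
#' [registry_add_residue()] or a registry file.
#'
#' @return A `chemistry_registry` object.
#' @export
default_registry <- function() {
  chems <- list(DNA = .dna_def(), TNA = .tna_def(), pTNA = .ptna_def())
  res <- tibble::tibble(
    res_name = c(
      "DA", "DT", "DG", "DC",
      "TA", "TT", "TG", "TC",
      "PA", "PT", "PG", "PC"
    ),
    chemistry_id = rep(c("DNA", "TNA", "pTNA"), each = 4),
    base = rep(c("A", "T", "G", "C"), 3)
  )
  structure(list(chemistries = chems, residues = res),
    class = "chemistry_registry"
  )
}

#' Add or override a residue-code mapping in a registry
#'
#' @param registry A `chemistry_registry`.
#' @param res_name Residue code as deposited (case-sensitive).
#' @param chemistry_id A chemistry already present in the registry.
#' @param base Base letter `A`/`T`/`G`/`C`.
#' @return The updated registry.
#' @export
registry_add_residue <- function(registry, res_name, chemistry_id, base) {
  stopifnot(inherits(registry, "chemistry_registry"))
  if (!chemistry_id %in% names(registry$chemistries)) {
    stop("unknown chemistry_id '", chemistry_id, "'", call. = FALSE)
  }
  res <- registry$residues
  res <- res[res$res_name != res_name, ]
  registry$residues <- dplyr::bind_rows(
    res,
    tibble::tibble(res_name = res_name, chemistry_id = chemistry_id, base = toupper(base))
  )
  registry
}

registry_lookup <- function(registry, res_name) {
  hit <- registry$residues[registry$residues$res_name == res_name, ]
  if (nrow(hit) == 0) {
    return(NULL)
  }
  list(
    chemistry = registry$chemistries[[hit$chemistry_id[1]]],
    base = hit$base[1]
  )
}

#' Write a registry to JSON or YAML
#'
#' Atom names are stored bit-exact (primed characters per PDB convention).
#'
#' @param registry A `chemistry_registry`.
#' @param path Output path; extension `.json`, `.yml` or `.yaml` selects the
#'   format.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  obj <- list(
    chemistries = lapply(registry$chemistries, function(ch) {
      ch <- unclass(ch)
      ch$torsion_names <- NULL
      ch
    }),
    residues = as.data.frame(registry$residues)
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a registry from JSON or YAML
#'
#' @param path File written by [write_registry()] (or hand-authored in the
#'   same layout).
#' @return A `chemistry_registry`.
#' @export
read_registry <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  }
  chems <- lapply(obj$chemistries, function(ch) {
    tors <- lapply(ch$torsions, function(tv) unlist(tv, use.names = FALSE))
    chemistry_definition(
      chemistry_id = ch$chemistry_id,
      ring_atoms = unlist(ch$ring_atoms),
      backbone_path = unlist(ch$backbone_path),
      linkage_donor = ch$linkage_donor,
      phosphorus_atom = ch$phosphorus_atom,
      torsions = tors,
      delta_analog = ch$delta_analog,
      glycosidic_quad_purine = unlist(ch$glycosidic_quad_purine),
      glycosidic_quad_pyrimidine = unlist(ch$glycosidic_quad_pyrimidine)
    )
  })
  res <- tibble::as_tibble(obj$residues)
  structure(list(chemistries = chems, residues = res),
    class = "chemistry_registry"
  )
}

#' @export
print.chemistry_registry <- function(x, ...) {
  cat(
    "<chemistry_registry> ", length(x$chemistries), " chemistries, ",
    nrow(x$residues), " residue codes\n",
    sep = ""
  )
  invisible(x)
}
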