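# Analysis pipeline: one configured run over a structure produces the full
# set of report tables (pucker, torsions, spacings, pairs, steps) plus a
# traceable summary; multiple reports can be compared side by side.

#' Configuration for an analysis run
#'
#' @param input Path to a PDB/mmCIF file, or an atom tibble.
#' @param registry Chemistry registry (default [default_registry()]).
#' @param primer_chain,template_chain Chain identifiers of the two nucleic
#'   strands; both `NULL` skips pairing analysis.
#' @param altloc_policy Passed to [resolve_altlocs()].
#' @param hbond_cutoff Heavy-atom H-bond cutoff in Angstrom (default 3.5).
#' @param regions Chi/delta form boundaries (default [chi_delta_regions()]).
#' @param link_cutoff Covalent link threshold in Angstrom (default 2.0).
#' @param output_dir Directory for CSV/JSON export, or `NULL` for none.
#' @param label Free-text run label used in file names and comparisons.
#' @return A `run_config` list.
#' @export
run_config <- function(input, registry = default_registry(),
                       primer_chain = NULL, template_chain = NULL,
                       altloc_policy = "highest_occupancy",
                       hbond_cutoff = 3.5, regions = chi_delta_regions(),
                       link_cutoff = 2.0, output_dir = NULL,
                       label = "run") {
  structure(
    list(
      input = input, registry = registry,
      primer_chain = primer_chain, template_chain = template_chain,
      altloc_policy = altloc_policy, hbond_cutoff = hbond_cutoff,
      regions = regions, link_cutoff = link_cutoff,
      output_dir = output_dir, label = label
    ),
    class = "run_config"
  )
}

#' Run the full conformational analysis
#'
#' Stages, in order: read / altloc resolution / chemistry annotation; sugar
#' pucker table; backbone torsion and P-P spacing tables; Watson-Crick pair,
#' H-bond and pair/step parameter tables (when both strand chains are
#' configured). Referenced chains are verified before any computation; a
#' missing chain aborts the run with no partial outputs. When `output_dir`
#' is set, one CSV per table and a JSON summary are written; every number in
#' the summary is copied from exactly one table row, never recomputed.
#'
#' @param config A `run_config`.
#' @return An `xna_report`: list with `label`, `tables` (named list of
#'   tibbles), `summary`, and `annotated` (the `xna_annotated` object).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  atoms <- if (is.character(config$input)) {
    read_structure(config$input)
  } else {
    config$input
  }
  # pre-flight: all referenced chains must resolve before any stage runs
  want <- c(config$primer_chain, config$template_chain)
  missing <- setdiff(want, unique(atoms$chain))
  if (length(missing)) {
    stop(
      "pre-flight failure: chain(s) not present in input: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  atoms <- resolve_altlocs(atoms, policy = config$altloc_policy)
  alt_rep <- altloc_report(atoms)
  ann <- annotate_chemistry(atoms,
    registry = config$registry,
    strict = FALSE, link_cutoff = config$link_cutoff
  )
  pucker <- pucker_wheel_coords(sugar_pucker(ann))
  torsions <- classify_form(backbone_torsions(ann), regions = config$regions)
  spacings <- p_p_distances(ann)
  tables <- list(
    pucker = pucker, torsions = torsions, spacings = spacings,
    altlocs = alt_rep
  )
  if (!is.null(config$primer_chain) && !is.null(config$template_chain)) {
    pairs <- find_basepairs(ann, config$primer_chain, config$template_chain,
      cutoff = config$hbond_cutoff
    )
    tables$hbonds <- hbond_distances(pairs)
    if (nrow(pairs) > 0) {
      ps <- pair_and_step_params(ann, pairs)
      tables$pairs <- dplyr::select(
        dplyr::left_join(ps$pairs,
          pairs[, c("resno_i", "hbond_min", "hbond_max")],
          by = "resno_i"
        ), -dplyr::any_of("idx_i")
      )
      tables$steps <- ps$steps
    } else {
      tables$pairs <- tibble::tibble()
      tables$steps <- tibble::tibble()
    }
  }
  summary <- list(
    label = config$label,
    n_atoms = nrow(atoms),
    n_nucleotides = nrow(ann$residues),
    chemistries = as.list(table(ann$residues$chemistry_id)),
    n_altloc_residues = nrow(alt_rep),
    n_pairs = if (!is.null(tables$pairs)) nrow(tables$pairs) else NA_integer_,
    mean_p_p_distance = mean(spacings$p_p_distance, na.rm = TRUE),
    config_hash = rlang::hash(config[setdiff(names(config), "input")])
  )
  report <- structure(
    list(
      label = config$label, config = config, tables = tables,
      summary = summary, annotated = ann
    ),
    class = "xna_report"
  )
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  report
}

#' @export
print.xna_report <- function(x, ...) {
  cat("<xna_report> '", x$label, "': ", sep = "")
  cat(paste0(names(x$tables), " (", vapply(x$tables, nrow, 1L), ")"),
    sep = ", "
  )
  cat("\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per table plus a JSON summary, prefixed with the run label.
#'
#' @param report An `xna_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables)) {
    tbl <- report$tables[[nm]]
    if (!nrow(tbl)) next
    tbl <- tbl[, !vapply(tbl, is.list, TRUE), drop = FALSE]
    utils::write.csv(tbl,
      file.path(dir, paste0(report$label, "_", nm, ".csv")),
      row.names = FALSE
    )
  }
  jsonlite::write_json(
    report$summary,
    file.path(dir, paste0(report$label, "_summary.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' Compare analysis reports across structures
#'
#' Joins the per-position pucker, chi/delta and spacing columns of two or
#' more reports into a side-by-side table (matched on chain and residue
#' number) and computes the pairwise C-alpha RMSD matrix where protein
#' C-alpha atoms are present. Reports must share nucleic chain identifiers
#' (selection semantics); mismatches are an error.
#'
#' @param reports Named list of `xna_report` objects (>= 2).
#' @param max_rounds,sigma_cutoff Outlier-rejection settings for the RMSD
#'   matrix (see [align_calpha()]).
#' @return List with `positions` (side-by-side tibble) and `rmsd` (matrix,
#'   `NA` where no common C-alpha pairing exists).
#' @export
compare_structures <- function(reports, max_rounds = 5, sigma_cutoff = 2.0) {
  stopifnot(length(reports) >= 2)
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- vapply(reports, function(r) r$label, "")
  }
  sel <- lapply(reports, function(r) {
    sort(c(r$config$primer_chain, r$config$template_chain))
  })
  if (length(unique(vapply(sel, paste, "", collapse = "|"))) > 1) {
    stop("mismatched selections: reports use different nucleic chain ids",
      call. = FALSE
    )
  }
  per <- purrr::imap(reports, function(r, nm) {
    p <- r$tables$pucker[, c("chain", "resno", "P", "nu_max", "conformer")]
    t <- r$tables$torsions[, c("chain", "resno", "chi", "delta_like", "form")]
    s <- r$tables$spacings[, c("chain", "resno_i", "p_p_distance")]
    out <- dplyr::left_join(p, t, by = c("chain", "resno")) |>
      dplyr::left_join(s, by = c("chain", "resno" = "resno_i"))
    dplyr::rename_with(out, function(cn) paste0(cn, ".", nm), -c("chain", "resno"))
  })
  positions <- purrr::reduce(per, dplyr::full_join, by = c("chain", "resno")) |>
    dplyr::arrange(.data$chain, .data$resno)
  n <- length(reports)
  rmsd <- matrix(NA_real_, n, n, dimnames = list(names(reports), names(reports)))
  diag(rmsd) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fit <- tryCatch(
        align_calpha(
          reports[[i]]$annotated$atoms, reports[[j]]$annotated$atoms,
          max_rounds = max_rounds, sigma_cutoff = sigma_cutoff
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) rmsd[i, j] <- rmsd[j, i] <- fit$rmsd
    }
  }
  list(positions = positions, rmsd = rmsd)
}

#' Concordance analysis for the deposited polymerase complexes
#'
#' Recomputes, from local copies of the deposited post-catalytic polymerase
#' structures, the quantities reported for them: pseudorotation phases of
#' the two extension nucleotides (primer positions 12 and 13), the P-P
#' distance of the 12-13 backbone step, pairwise protein C-alpha RMSDs,
#' the delta-torsion drop between the two DNA extension residues, and the
#' heavy-atom H-bond distances of the extension base pairs. The deposited
#' ligand codes for the TNA and pTNA adenosines must be present in
#' `registry` (read them from the files and add with
#' [registry_add_residue()]); they are not shipped because they can only be
#' taken from the deposited models themselves.
#'
#' @param paths Named character vector of local file paths; recognized names
#'   are `ptna` (Kod-RI/pTNA), `dna` (Kod-RI/DNA), `tna` (Kod-RI/TNA) and
#'   optionally `ptna_rsga` (Kod-RSGA/pTNA).
#' @param registry Registry containing every deposited residue code.
#' @param primer_chain,template_chain Nucleic chain identifiers shared by
#'   the deposited models.
#' @return List of tibbles: `pucker` (P at positions 12/13 per structure),
#'   `spacing` (12-13 P-P distance per structure), `rmsd` (pairwise
#'   C-alpha RMSD), `delta_drop` (DNA delta(13) - delta(12), shortest signed
#'   difference), `hbonds` (extension-pair H-bond distances).
#' @export
concordance_analysis <- function(paths, registry,
                              primer_chain = "B", template_chain = "C") {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(
      "deposited structure file(s) not found: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  reports <- purrr::imap(paths, function(p, nm) {
    run_analysis(run_config(p,
      registry = registry,
      primer_chain = primer_chain, template_chain = template_chain,
      label = nm
    ))
  })
  pick12_13 <- function(tbl) {
    dplyr::filter(tbl, .data$chain == primer_chain, .data$resno %in% c(12L, 13L))
  }
  pucker <- purrr::imap(reports, function(r, nm) {
    dplyr::mutate(
      pick12_13(r$tables$pucker)[, c("resno", "resid", "P", "nu_max", "conformer")],
      structure = nm, .before = 1
    )
  }) |> dplyr::bind_rows()
  spacing <- purrr::imap(reports, function(r, nm) {
    s <- dplyr::filter(
      r$tables$spacings,
      .data$chain == primer_chain, .data$resno_i == 12L, .data$resno_j == 13L
    )
    dplyr::mutate(s[, c("resno_i", "resno_j", "p_p_distance")],
      structure = nm, .before = 1
    )
  }) |> dplyr::bind_rows()
  cmp <- compare_structures(reports)
  delta_drop <- if ("dna" %in% names(reports)) {
    t <- pick12_13(reports[["dna"]]$tables$torsions)
    if (nrow(t) == 2) {
      angle_diff(t$delta_like[t$resno == 13L], t$delta_like[t$resno == 12L])
    } else {
      NA_real_
    }
  } else {
    NA_real_
  }
  hbonds <- purrr::imap(reports, function(r, nm) {
    h <- dplyr::filter(
      r$tables$hbonds,
      .data$chain_i == primer_chain, .data$resno_i %in% c(12L, 13L)
    )
    dplyr::mutate(h, structure = nm, .before = 1)
  }) |> dplyr::bind_rows()
  list(
    pucker = pucker, spacing = spacing, rmsd = cmp$rmsd,
    delta_drop = delta_drop, hbonds = hbonds
  )
}
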