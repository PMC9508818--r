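# Rigid-body superposition: Kabsch least-squares fit (reflections excluded),
# iterative outlier rejection for global C-alpha alignment, and local
# alignment on a named residue selection.

new_superposition <- function(rotation, translation, rmsd, n_retained,
                              n_initial, rejection_rounds, retained) {
  structure(
    list(
      rotation = rotation, translation = translation, rmsd = rmsd,
      n_retained = n_retained, n_initial = n_initial,
      rejection_rounds = rejection_rounds, retained = retained
    ),
    class = "xna_superposition"
  )
}

#' @export
print.xna_superposition <- function(x, ...) {
  cat(
    "<xna_superposition> rmsd ", format(x$rmsd, digits = 4), " A over ",
    x$n_retained, "/", x$n_initial, " atoms (",
    nrow(x$rejection_rounds), " rejection round(s))\n",
    sep = ""
  )
  invisible(x)
}

#' Kabsch superposition of two paired point sets
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `R a + t` against `b` over all paired points. The reflection branch of
#' the SVD solution is excluded by determinant correction, so chirality is
#' preserved.
#'
#' @param a,b Equal-size n x 3 coordinate matrices (n >= 3, not collinear).
#' @return An `xna_superposition` object. `$rotation` and `$translation`
#'   map `a` onto `b`.
#' @export
kabsch <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3) {
    stop("coordinate sets must be equal-size n x 3 matrices", call. = FALSE)
  }
  n <- nrow(a)
  if (n < 3) stop("need at least 3 point pairs", call. = FALSE)
  ca <- colMeans(a)
  cb <- colMeans(b)
  A <- sweep(a, 2, ca)
  B <- sweep(b, 2, cb)
  if (min(svd(A)$d) < 1e-9 && sort(svd(A)$d, decreasing = TRUE)[2] < 1e-9) {
    stop("degenerate configuration: points are collinear", call. = FALSE)
  }
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  dimnames(R) <- NULL
  t_vec <- unname(cb - as.vector(R %*% ca))
  fitted <- sweep(a %*% t(R), 2, -t_vec)
  dev <- sqrt(rowSums((fitted - b)^2))
  rmsd <- sqrt(mean(dev^2))
  res <- new_superposition(
    rotation = R, translation = t_vec, rmsd = rmsd,
    n_retained = n, n_initial = n,
    rejection_rounds = tibble::tibble(
      round = integer(), rejected = integer(), rmsd = double()
    ),
    retained = seq_len(n)
  )
  res$deviations <- dev
  res
}

# Kabsch with iterative outlier rejection on a paired coordinate set.
# min_rmsd is a numerical floor: once the retained set fits essentially
# perfectly there is nothing left to reject, and a threshold proportional
# to a near-zero RMSD would discard atoms on floating-point jitter alone.
kabsch_reject <- function(a, b, max_rounds = 5, sigma_cutoff = 2.0,
                          min_rmsd = 1e-6) {
  n <- nrow(a)
  keep <- seq_len(n)
  fit <- kabsch(a, b)
  rounds <- list()
  if (max_rounds > 0) {
    for (r in seq_len(max_rounds)) {
      if (fit$rmsd < min_rmsd) break
      dev <- fit$deviations
      thr <- sigma_cutoff * fit$rmsd
      out <- dev > thr
      if (!any(out) || sum(!out) < 3) break
      keep <- keep[!out]
      fit <- kabsch(a[keep, , drop = FALSE], b[keep, , drop = FALSE])
      rounds[[r]] <- tibble::tibble(
        round = r, rejected = sum(out), rmsd = fit$rmsd
      )
    }
  }
  res <- new_superposition(
    rotation = fit$rotation, translation = fit$translation, rmsd = fit$rmsd,
    n_retained = length(keep), n_initial = n,
    rejection_rounds = if (length(rounds)) {
      dplyr::bind_rows(rounds)
    } else {
      tibble::tibble(round = integer(), rejected = integer(), rmsd = double())
    },
    retained = keep
  )
  res$deviations <- fit$deviations
  res
}

#' Global C-alpha alignment with iterative outlier rejection
#'
#' Pairs C-alpha atoms by chain and author residue number (residues unbuilt
#' in either model drop out of the pairing automatically), performs an
#' initial Kabsch fit, then up to `max_rounds` cycles rejecting pairs whose
#' deviation exceeds `sigma_cutoff` times the current RMSD, refitting after
#' each rejection, stopping when nothing is rejected.
#'
#' @param atoms_a,atoms_b Atom tibbles.
#' @param chains Optional chain filter applied to both structures.
#' @param max_rounds Maximum rejection cycles (default 5; 0 disables
#'   rejection, making the result identical to [kabsch()] on the full
#'   pairing).
#' @param sigma_cutoff Rejection multiplier on the current RMSD (default 2).
#' @return An `xna_superposition`; `$pairing` holds the matched residue
#'   table.
#' @export
align_calpha <- function(atoms_a, atoms_b, chains = NULL,
                         max_rounds = 5, sigma_cutoff = 2.0) {
  pick <- function(atoms) {
    ca <- dplyr::filter(atoms, .data$elety == "CA")
    if (!is.null(chains)) ca <- dplyr::filter(ca, .data$chain %in% chains)
    dplyr::distinct(ca, .data$chain, .data$resno, .data$ins, .keep_all = TRUE)
  }
  ca_a <- pick(atoms_a)
  ca_b <- pick(atoms_b)
  merged <- dplyr::inner_join(
    ca_a, ca_b,
    by = c("chain", "resno", "ins"), suffix = c("_a", "_b")
  )
  if (nrow(merged) < 3) {
    stop("C-alpha pairing yields fewer than 3 atoms", call. = FALSE)
  }
  a <- as.matrix(merged[, c("x_a", "y_a", "z_a")])
  b <- as.matrix(merged[, c("x_b", "y_b", "z_b")])
  res <- kabsch_reject(a, b, max_rounds = max_rounds, sigma_cutoff = sigma_cutoff)
  res$pairing <- merged[, c("chain", "resno", "ins")]
  res
}

#' Local superposition on a named residue selection
#'
#' Superposes on the shared heavy atoms (element != H, matched by atom name)
#' of the selected residues only, and returns the whole of structure A
#' transformed into B's frame for overlay export.
#'
#' @param atoms_a,atoms_b Atom tibbles.
#' @param selection Tibble (or data.frame) with columns `chain` and `resno`
#'   naming the residues to fit on; every entry must resolve in both
#'   structures.
#' @return An `xna_superposition` with `$transformed` (structure A moved
#'   onto B) and `$atoms_used` (the matched atom table).
#' @export
align_local <- function(atoms_a, atoms_b, selection) {
  selection <- tibble::as_tibble(selection)
  stopifnot(all(c("chain", "resno") %in% names(selection)))
  pick <- function(atoms, who) {
    sel <- dplyr::inner_join(atoms, selection, by = c("chain", "resno"))
    found <- dplyr::distinct(sel, .data$chain, .data$resno)
    missing <- dplyr::anti_join(selection, found, by = c("chain", "resno"))
    if (nrow(missing)) {
      stop(
        "selection not resolvable in structure ", who, ": ",
        paste(paste0(missing$chain, ":", missing$resno), collapse = ", "),
        call. = FALSE
      )
    }
    dplyr::filter(sel, !.data$elesy %in% c("H", "D"))
  }
  sa <- pick(atoms_a, "A")
  sb <- pick(atoms_b, "B")
  merged <- dplyr::inner_join(
    sa, sb,
    by = c("chain", "resno", "ins", "elety"), suffix = c("_a", "_b")
  )
  if (nrow(merged) < 3) {
    stop("selection shares fewer than 3 heavy atoms", call. = FALSE)
  }
  a <- as.matrix(merged[, c("x_a", "y_a", "z_a")])
  b <- as.matrix(merged[, c("x_b", "y_b", "z_b")])
  res <- kabsch(a, b)
  res$atoms_used <- merged[, c("chain", "resno", "ins", "elety")]
  res$transformed <- transform_atoms(atoms_a, res$rotation, res$translation)
  res
}

#' Write a superposition report as JSON
#' @param fit An `xna_superposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_superposition_report <- function(fit, path) {
  obj <- list(
    rmsd = fit$rmsd,
    n_retained = fit$n_retained,
    n_initial = fit$n_initial,
    rotation = fit$rotation,
    translation = fit$translation,
    rejection_rounds = as.data.frame(fit$rejection_rounds)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a superposition: one row per rejection round
#' @param x An `xna_superposition`.
#' @param ... Unused.
#' @return Tibble of rejection rounds (round, rejected, rmsd).
#' @export
tidy.xna_superposition <- function(x, ...) {
  x$rejection_rounds
}

#' One-row summary of a superposition fit
#' @param x An `xna_superposition`.
#' @param ... Unused.
#' @return One-row tibble: rmsd, n_retained, n_initial, n_rounds,
#'   rotation_angle (degrees).
#' @export
glance.xna_superposition <- function(x, ...) {
  aa <- rotation_axis_angle(x$rotation)
  tibble::tibble(
    rmsd = x$rmsd,
    n_retained = x$n_retained,
    n_initial = x$n_initial,
    n_rounds = nrow(x$rejection_rounds),
    rotation_angle = aa$angle
  )
}
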