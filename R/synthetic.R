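# Synthetic-structure generator: furanose rings at prescribed pseudorotation
# state, idealized multi-chemistry duplexes at prescribed base-pair and step
# parameters, Gaussian perturbation, and a toy C-alpha cloud. Everything is
# deterministic given its arguments (and seed, where noise is requested), so
# generated fixtures double as oracles: the build tables record exactly what
# was constructed.

# Idealized small-molecule constants (Angstrom / degrees). One table; the
# whole generator reads from here.
.gen_const <- list(
  len_CC = 1.525, # ring and exocyclic C-C
  len_CO = 1.420, # ring and ester C-O
  len_PO = 1.600, # phosphate P-O
  len_PC = 1.800, # phosphonate P-C
  len_CN = 1.470, # glycosidic C1'-N
  ang_sub = 109.47, # target angle of exocyclic substituents to ring bonds
  ang_COC = 118.0, # C-O-C ester angle
  ang_OCC = 110.0 # O-C-C
)

# Out-of-plane substituent side per chemistry: +1/-1 multiplies the ring
# normal (cross of the two ring-bond directions). The DNA signs give the
# beta-D-2'-deoxyribose arrangement (base and C5' on the same face, O3' on
# the other); the threose signs give an idealized alpha-L-threofuranose with
# the 2'/3' substituents trans (threo diol) and the backbone able to
# propagate 3'->2' along the helix.
.sugar_signs <- list(
  DNA = list(base = +1, sub1 = -1, sub2 = +1), # sub1 = O3' on C3', sub2 = C5' on C4'
  TNA = list(base = +1, sub1 = +1, sub2 = -1), # sub1 = O3' on C3', sub2 = O2' on C2'
  pTNA = list(base = +1, sub1 = +1, sub2 = -1)
)

# Direction of a tetrahedral substituent on ring atom X with ring neighbors
# A and B, out-of-plane side `side`. The in-plane tilt is solved so the
# substituent-to-ring-bond angle hits `target` degrees.
substituent_dir <- function(X, A, B, side, target = .gen_const$ang_sub) {
  u1 <- unitize(A - X)
  u2 <- unitize(B - X)
  bis <- unitize(-(u1 + u2))
  nrm <- unitize(cross3(u1, u2))
  ch <- sum(bis * u1) # cos of bisector-to-bond angle
  ca <- cos(target * DEG) / ch
  ca <- max(-1, min(1, ca))
  sa <- sqrt(1 - ca^2)
  unitize(ca * bis + side * sa * nrm)
}

# Embed a 5-ring with target endocyclic torsions nu0..nu4 by constrained
# least squares: three internal bond angles and the two chain-defining
# torsions are free; bond lengths are restrained to the ideal values but may
# flex by a few hundredths of an Angstrom, because the cosine series is not
# exactly closable on a fixed-length ring at large amplitude and the
# torsions are the quantity under test. Ring order O4'(1) C1'(2) C2'(3)
# C3'(4) C4'(5); bonds O4'-C1' CO, C1'-C2'/C2'-C3'/C3'-C4' CC, C4'-O4' CO.
.ring_cache <- new.env(parent = emptyenv())

embed_ring <- function(nu_target, max_resid = 0.5) {
  key <- paste(round(nu_target, 6), collapse = "|")
  hit <- get0(key, envir = .ring_cache)
  if (!is.null(hit)) {
    return(hit)
  }
  L0 <- c(.gen_const$len_CO, .gen_const$len_CC, .gen_const$len_CC,
    .gen_const$len_CC, .gen_const$len_CO)
  build <- function(par) {
    th <- par[1:3] # angles at C1', C2', C3'
    t1 <- par[4] # torsion O4'-C1'-C2'-C3' (nu1)
    t2 <- par[5] # torsion C1'-C2'-C3'-C4' (nu2)
    L <- L0
    L[1:4] <- L0[1:4] + par[6:9]
    p1 <- c(0, 0, 0)
    p2 <- c(L[1], 0, 0)
    p3 <- p2 + L[2] * c(-cos(th[1] * DEG), sin(th[1] * DEG), 0)
    p4 <- place_atom(p1, p2, p3, L[3], th[2], t1)
    p5 <- place_atom(p2, p3, p4, L[4], th[3], t2)
    rbind(p1, p2, p3, p4, p5)
  }
  objective <- function(par) {
    ring <- build(par)
    closure <- vnorm(ring[5, ] - ring[1, ]) - L0[5]
    nu <- tryCatch(ring_torsions(ring), error = function(e) rep(1e3, 5))
    sum(wrap_angle(nu - nu_target)^2) + 100 * (sum(par[6:9]^2) + closure^2)
  }
  start <- c(103, 103, 103, nu_target[2], nu_target[3], 0, 0, 0, 0)
  fit <- stats::nlminb(start, objective,
    control = list(iter.max = 2000, rel.tol = 1e-15)
  )
  ring <- build(fit$par)
  achieved <- ring_torsions(ring)
  resid <- max(abs(wrap_angle(achieved - nu_target)))
  closure_err <- abs(vnorm(ring[5, ] - ring[1, ]) - L0[5])
  len_err <- max(abs(fit$par[6:9]), closure_err)
  if (resid > max_resid || len_err > 0.08) {
    stop(
      "ring embedding failed: max torsion residual ",
      format(resid, digits = 3), " deg, max bond-length deviation ",
      format(len_err, digits = 3), " A",
      call. = FALSE
    )
  }
  rownames(ring) <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  attr(ring, "achieved_nu") <- achieved
  assign(key, ring, envir = .ring_cache)
  ring
}

# Assemble one nucleotide: base at `frame`, sugar ring at pucker (P, nu_max)
# glued to the base at glycosidic torsion chi, plus backbone substituents
# ("linkage stubs") for the chemistry. Returns a named coordinate matrix
# with attribute "achieved_nu".
build_nucleotide <- function(base, chemistry = "DNA", P = 162, nu_max = 38,
                             chi = -105, frame = list(R = diag(3), origin = c(0, 0, 0))) {
  if (nu_max < 5 || nu_max > 60) {
    stop("nu_max must be in [5, 60] degrees", call. = FALSE)
  }
  sg <- .sugar_signs[[chemistry]]
  if (is.null(sg)) stop("unknown generator chemistry '", chemistry, "'", call. = FALSE)
  nu_t <- nu_max * cos((P + 144 * ((0:4) - 2)) * DEG)
  ring <- embed_ring(nu_t)
  achieved <- attr(ring, "achieved_nu")

  # glycosidic nitrogen direction in ring-local coordinates
  n_name <- if (base_type_of(base) == "purine") "N9" else "N1"
  n_dir <- substituent_dir(ring["C1'", ], ring["O4'", ], ring["C2'", ], sg$base)
  n_loc <- ring["C1'", ] + .gen_const$len_CN * n_dir

  # rigid transform: ring C1'->N axis onto base C1'->N axis
  bmat <- standard_base(base)
  bxyz <- apply_rigid(bmat, frame$R, frame$origin)
  rownames(bxyz) <- rownames(bmat)
  v_ring <- unitize(n_loc - ring["C1'", ])
  v_base <- unitize(bxyz[n_name, ] - bxyz["C1'", ])
  ax <- cross3(v_ring, v_base)
  R1 <- if (vnorm(ax) < 1e-9) {
    if (sum(v_ring * v_base) > 0) diag(3) else rotation_about(orth_any(v_ring), 180)
  } else {
    rotation_about(ax, acos(max(-1, min(1, sum(v_ring * v_base)))) / DEG)
  }
  shift1 <- bxyz["C1'", ] - as.vector(R1 %*% ring["C1'", ])
  ring1 <- sweep(ring %*% t(R1), 2, -shift1)
  rownames(ring1) <- rownames(ring)
  # spin about the glycosidic bond to hit chi: O4'-C1'-N-C(4|2)
  c_ref <- if (n_name == "N9") "C4" else "C2"
  cur <- dihedral(ring1["O4'", ], ring1["C1'", ], bxyz[n_name, ], bxyz[c_ref, ])
  spin <- rotation_about(v_base, -angle_diff(chi, cur))
  piv <- bxyz["C1'", ]
  ring2 <- sweep(sweep(ring1, 2, piv) %*% t(spin), 2, -piv)
  rownames(ring2) <- rownames(ring)
  # verify chi landed (sign convention of the spin fixed by construction)
  cur2 <- dihedral(ring2["O4'", ], ring2["C1'", ], bxyz[n_name, ], bxyz[c_ref, ])
  if (abs(angle_diff(cur2, chi)) > 1e-6) {
    spin <- rotation_about(v_base, angle_diff(chi, cur))
    ring2 <- sweep(sweep(ring1, 2, piv) %*% t(spin), 2, -piv)
    rownames(ring2) <- rownames(ring)
  }

  # backbone substituents
  out <- rbind(bxyz, ring2[c("O4'", "C2'", "C3'", "C4'"), , drop = FALSE])
  # note: C1' present from the base block
  if (chemistry == "DNA") {
    o3 <- ring2["C3'", ] + .gen_const$len_CO *
      substituent_dir(ring2["C3'", ], ring2["C2'", ], ring2["C4'", ], sg$sub1)
    c5 <- ring2["C4'", ] + .gen_const$len_CC *
      substituent_dir(ring2["C4'", ], ring2["C3'", ], ring2["O4'", ], sg$sub2)
    o5 <- place_atom(ring2["C3'", ], ring2["C4'", ], c5,
      .gen_const$len_CO, .gen_const$ang_OCC, 54
    ) # gamma ~ +54 (gauche+)
    out <- rbind(out, `O3'` = o3, `C5'` = c5, `O5'` = o5)
  } else {
    o3 <- ring2["C3'", ] + .gen_const$len_CO *
      substituent_dir(ring2["C3'", ], ring2["C2'", ], ring2["C4'", ], sg$sub1)
    o2 <- ring2["C2'", ] + .gen_const$len_CO *
      substituent_dir(ring2["C2'", ], ring2["C1'", ], ring2["C3'", ], sg$sub2)
    out <- rbind(out, `O3'` = o3, `O2'` = o2)
    # pTNA's phosphonate methylene (C6') is placed with the bridging P when
    # residues are linked: like a 5'-phosphate, it belongs to the linkage.
  }
  attr(out, "achieved_nu") <- achieved
  attr(out, "n_name") <- n_name
  out
}

orth_any <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(cross3(v, w))
}

#' Generate a single furanose nucleotide at a prescribed pucker
#'
#' Builds the five-membered ring by constrained Cartesian embedding (fixed
#' bond lengths, adjustable bond angles, least-squares closure) so the
#' endocyclic torsions hit the Altona-Sundaralingam cosine series
#' `nu_j = nu_max * cos(P + 144 (j - 2))`, then attaches the base and the
#' chemistry's linkage stubs. Embedding failure is an error, never a silent
#' approximation.
#'
#' @param P Target pseudorotation phase (degrees).
#' @param nu_max Target amplitude (degrees), in \[5, 60\].
#' @param chemistry `"DNA"`, `"TNA"` or `"pTNA"`.
#' @param base Base letter (default `"A"`).
#' @param chi Glycosidic torsion (degrees, default -105).
#' @param chain,resno Identifiers for the emitted residue.
#' @return An atom tibble (one residue) with attributes `"achieved_nu"` (the
#'   realized endocyclic torsions) and `"target_nu"`.
#' @export
make_furanose <- function(P, nu_max, chemistry = "DNA", base = "A",
                          chi = -105, chain = "A", resno = 1L) {
  m <- build_nucleotide(base, chemistry, P = P, nu_max = nu_max, chi = chi)
  resid <- .residue_code(chemistry, base)
  atoms <- coords_to_atoms(m, chain = chain, resno = resno, resid = resid)
  attr(atoms, "achieved_nu") <- attr(m, "achieved_nu")
  attr(atoms, "target_nu") <- nu_max * cos((P + 144 * ((0:4) - 2)) * DEG)
  atoms
}

.residue_code <- function(chemistry, base) {
  pre <- c(DNA = "D", TNA = "T", pTNA = "P")[[chemistry]]
  paste0(pre, toupper(base))
}

element_of <- function(name) {
  substr(gsub("[^A-Za-z].*$", "", name), 1, 1)
}

coords_to_atoms <- function(m, chain, resno, resid) {
  nm <- rownames(m)
  new_structure_tbl(tibble::tibble(
    record = "ATOM",
    chain = chain, resno = as.integer(resno), ins = "",
    resid = resid, elety = nm,
    elesy = unname(vapply(nm, element_of, "")),
    alt = "",
    x = unname(m[, 1]), y = unname(m[, 2]), z = unname(m[, 3]),
    o = 1, b = 0
  ))
}

#' Specification for a synthetic duplex
#'
#' Collects every knob of [make_duplex()] with the package's standard
#' conditions as defaults: an idealized B-form helix (twist 36 degrees, rise
#' 3.4 Angstrom, all other step parameters zero), ideal Watson-Crick pair
#' geometry (all six intra-pair parameters zero, giving heavy-atom H-bond
#' distances near 2.9 Angstrom), C2'-endo DNA sugars (P = 162) with
#' anti glycosidic chi = -105, and C3'-endo-region threose sugars
#' (P = 20, chi = -120) for TNA/pTNA strands.
#'
#' @param seq1 Strand-1 sequence (string or letter vector), 5'->3' (3'->2'
#'   for threose chemistries).
#' @param chemistry1 Chemistry per strand-1 residue: one id or a vector
#'   (chimeric strands allowed, e.g. DNA primer + pTNA extensions).
#' @param chemistry2 Chemistry of strand 2 (single id; default `"DNA"`).
#' @param step_params Data frame / tibble with columns shift, slide, rise,
#'   tilt, roll, twist; one row per step (recycled from one row), or `NULL`
#'   for the B-form default.
#' @param pair_params Same layout for shear, stretch, stagger, buckle,
#'   propeller, opening; one row per pair, default all zero.
#' @param pucker1,pucker2 Tibbles with columns `P`, `nu_max` (one row per
#'   residue, recycled from one row), or `NULL` for the chemistry default.
#' @param chi1,chi2 Glycosidic torsions (scalar or per-residue).
#' @return A `duplex_spec` list.
#' @export
duplex_spec <- function(seq1, chemistry1 = "DNA", chemistry2 = "DNA",
                        step_params = NULL, pair_params = NULL,
                        pucker1 = NULL, pucker2 = NULL,
                        chi1 = NULL, chi2 = NULL) {
  s1 <- toupper(if (length(seq1) == 1) strsplit(seq1, "")[[1]] else seq1)
  if (!all(s1 %in% c("A", "T", "G", "C"))) {
    stop("sequence letters must be A/T/G/C", call. = FALSE)
  }
  n <- length(s1)
  chem1 <- rep_len(chemistry1, n)
  def_pucker <- function(chem) {
    if (chem == "DNA") c(P = 162, nu_max = 38) else c(P = 20, nu_max = 35)
  }
  def_chi <- function(chem) if (chem == "DNA") -105 else -120
  fill_pucker <- function(p, chems) {
    if (is.null(p)) {
      tibble::tibble(
        P = vapply(chems, function(c) def_pucker(c)[["P"]], 0),
        nu_max = vapply(chems, function(c) def_pucker(c)[["nu_max"]], 0)
      )
    } else {
      p <- tibble::as_tibble(p)
      tibble::tibble(P = rep_len(p$P, n), nu_max = rep_len(p$nu_max, n))
    }
  }
  sp_default <- tibble::tibble(
    shift = 0, slide = 0, rise = 3.4, tilt = 0, roll = 0, twist = 36
  )
  pp_default <- tibble::tibble(
    shear = 0, stretch = 0, stagger = 0, buckle = 0, propeller = 0, opening = 0
  )
  expand <- function(x, default, rows) {
    x <- if (is.null(x)) default else tibble::as_tibble(x)
    dplyr::slice(x, rep_len(seq_len(nrow(x)), rows))
  }
  structure(list(
    seq1 = s1,
    seq2 = unname(.wc_partner[s1]), # pair-order complement of strand 1
    chemistry1 = chem1,
    chemistry2 = rep_len(chemistry2, n),
    step_params = expand(step_params, sp_default, max(n - 1, 0)),
    pair_params = expand(pair_params, pp_default, n),
    pucker1 = fill_pucker(pucker1, chem1),
    pucker2 = fill_pucker(pucker2, rep_len(chemistry2, n)),
    chi1 = rep_len(if (is.null(chi1)) vapply(chem1, def_chi, 0) else chi1, n),
    chi2 = rep_len(if (is.null(chi2)) def_chi(chemistry2[1]) else chi2, n)
  ), class = "duplex_spec")
}

# Solve the bridging position bonded to q1 (length l1) and q2 (length l2);
# the out-of-plane side points away from `ref` (e.g. the helix interior).
bridge_point <- function(q1, q2, l1, l2, ref) {
  d <- vnorm(q2 - q1)
  u <- unitize(q2 - q1)
  if (d >= l1 + l2) {
    return(q1 + u * (d * l1 / (l1 + l2))) # strained: best-effort on the chord
  }
  a <- (d^2 + l1^2 - l2^2) / (2 * d)
  h <- sqrt(max(0, l1^2 - a^2))
  mid <- q1 + a * u
  w <- (mid - ref) - sum((mid - ref) * u) * u
  w <- if (vnorm(w) < 1e-6) orth_any(u) else unitize(w)
  mid + h * w
}

# Solve a two-atom bridge q1 - a1 - a2 - q2 with target bond lengths
# (l1, l12, l2) and soft angle restraints, by least squares from a chord
# initialization displaced away from `ref`.
bridge_two <- function(q1, q2, l1, l12, l2, ref,
                       ang1 = 104, ang2 = 112) {
  d <- vnorm(q2 - q1)
  u <- unitize(q2 - q1)
  w <- (q1 + q2) / 2 - ref
  w <- w - sum(w * u) * u
  w <- if (vnorm(w) < 1e-6) orth_any(u) else unitize(w)
  bulge <- max(0.2, (l1 + l12 + l2 - d) / 2)
  start <- c(
    q1 + u * (d * l1 / (l1 + l12 + l2)) + w * bulge,
    q1 + u * (d * (l1 + l12) / (l1 + l12 + l2)) + w * bulge
  )
  obj <- function(p) {
    a1 <- p[1:3]
    a2 <- p[4:6]
    e <- c(
      vnorm(a1 - q1) - l1, vnorm(a2 - a1) - l12, vnorm(q2 - a2) - l2
    )
    ang <- c(
      bond_angle(q1, a1, a2) - ang1,
      bond_angle(a1, a2, q2) - ang2
    )
    sum(e^2) + 1e-4 * sum(ang^2)
  }
  fit <- stats::optim(start, obj,
    method = "BFGS",
    control = list(maxit = 500, reltol = 1e-14)
  )
  list(a1 = fit$par[1:3], a2 = fit$par[4:6])
}

#' Build an idealized duplex from a specification
#'
#' Base pairs are constructed from the embedded standard base geometries at
#' the spec's intra-pair parameters; consecutive pairs are placed by the
#' spec's step parameters via the mid-frame construction; sugars are attached
#' at the spec's pucker and chi; bridging phosphorus atoms (phosphate, or
#' phosphonate with its methylene for pTNA) are placed to satisfy both
#' linkage bonds. Strand 1 is chain `"A"` numbered 1..n in build order;
#' strand 2 is chain `"B"` numbered so its own backbone direction runs
#' antiparallel (residue paired with pair k has resno n - k + 1).
#'
#' @param spec A `duplex_spec`.
#' @return An atom tibble with attribute `"build"`: a list carrying the spec,
#'   the per-pair base frames, and the generator's connectivity table
#'   (chain, resno donor -> resno acceptor) -- the oracle for link and
#'   round-trip tests.
#' @export
make_duplex <- function(spec) {
  stopifnot(inherits(spec, "duplex_spec"))
  n <- length(spec$seq1)
  if (n < 1) stop("empty sequence", call. = FALSE)
  if (!all(spec$seq2 == unname(.wc_partner[spec$seq1]))) {
    stop("strands are not complementary", call. = FALSE)
  }
  # pair mid-frames by step propagation
  mids <- vector("list", n)
  mids[[1]] <- list(R = diag(3), origin = c(0, 0, 0))
  for (k in seq_len(n - 1)) {
    sp <- spec$step_params[k, ]
    mids[[k + 1]] <- frame_step_apply(
      mids[[k]],
      rot = c(sp$tilt, sp$roll, sp$twist),
      tra = c(sp$shift, sp$slide, sp$rise)
    )
  }
  # strand base frames from pair parameters
  f1 <- vector("list", n)
  f2 <- vector("list", n)
  for (k in seq_len(n)) {
    pp <- spec$pair_params[k, ]
    rot <- c(pp$buckle, pp$propeller, pp$opening)
    tra <- c(pp$shear, pp$stretch, pp$stagger)
    gamma <- vnorm(rot)
    M <- mids[[k]]
    if (gamma < 1e-12) {
      R1 <- M$R
      R2f <- M$R
    } else {
      axis_lab <- as.vector(M$R %*% (rot / gamma))
      R1 <- rotation_about(axis_lab, gamma / 2) %*% M$R
      R2f <- rotation_about(axis_lab, -gamma / 2) %*% M$R
    }
    o1 <- M$origin + as.vector(M$R %*% tra) / 2
    o2 <- M$origin - as.vector(M$R %*% tra) / 2
    f1[[k]] <- list(R = R1, origin = o1)
    f2[[k]] <- list(R = flip_frame(R2f), origin = o2)
  }
  # nucleotides
  res1 <- vector("list", n)
  res2 <- vector("list", n)
  for (k in seq_len(n)) {
    res1[[k]] <- build_nucleotide(
      spec$seq1[k], spec$chemistry1[k],
      P = spec$pucker1$P[k], nu_max = spec$pucker1$nu_max[k],
      chi = spec$chi1[k], frame = f1[[k]]
    )
    res2[[k]] <- build_nucleotide(
      spec$seq2[k], spec$chemistry2[k],
      P = spec$pucker2$P[k], nu_max = spec$pucker2$nu_max[k],
      chi = spec$chi2[k], frame = f2[[k]]
    )
  }
  # bridging phosphorus: strand 1 runs with pair order, strand 2 against it
  add_p <- function(res_list, i_from, i_to, chem_from, chem_to, mids_pair) {
    donor_name <- if (chem_from == "DNA") "O3'" else "O2'"
    q1 <- res_list[[i_from]][donor_name, ]
    ref <- mids_pair$origin
    if (chem_to == "pTNA") {
      # phosphonate: donor - P - C6'(methylene) - O3'
      br <- bridge_two(
        q1, res_list[[i_to]]["O3'", ],
        .gen_const$len_PO, .gen_const$len_PC, .gen_const$len_CO, ref
      )
      res_list[[i_to]] <- rbind(res_list[[i_to]], P = br$a1, `C6'` = br$a2)
    } else {
      acceptor_name <- if (chem_to == "DNA") "O5'" else "O3'"
      q2 <- res_list[[i_to]][acceptor_name, ]
      P <- bridge_point(q1, q2, .gen_const$len_PO, .gen_const$len_PO, ref)
      res_list[[i_to]] <- rbind(res_list[[i_to]], P = P)
    }
    res_list
  }
  for (k in seq_len(n - 1)) {
    res1 <- add_p(res1, k, k + 1, spec$chemistry1[k], spec$chemistry1[k + 1], mids[[k]])
  }
  # strand 2's own 5'->3' order is pair order n, n-1, ..., 1
  for (k in rev(seq_len(n))[-n]) {
    res2 <- add_p(res2, k, k - 1, spec$chemistry2[k], spec$chemistry2[k - 1], mids[[k]])
  }
  atoms1 <- purrr::map(seq_len(n), function(k) {
    coords_to_atoms(res1[[k]],
      chain = "A", resno = k,
      resid = .residue_code(spec$chemistry1[k], spec$seq1[k])
    )
  })
  atoms2 <- purrr::map(seq_len(n), function(k) {
    coords_to_atoms(res2[[k]],
      chain = "B", resno = n - k + 1,
      resid = .residue_code(spec$chemistry2[k], spec$seq2[k])
    )
  })
  out <- new_structure_tbl(dplyr::bind_rows(c(atoms1, rev(atoms2))))
  connectivity <- dplyr::bind_rows(
    if (n > 1) {
      tibble::tibble(
        chain = "A", resno_donor = seq_len(n - 1), resno_acceptor = 2:n
      )
    },
    if (n > 1) {
      tibble::tibble(
        chain = "B", resno_donor = seq_len(n - 1), resno_acceptor = 2:n
      )
    }
  )
  attr(out, "build") <- list(
    spec = spec, pair_mids = mids, frames1 = f1, frames2 = f2,
    connectivity = connectivity
  )
  out
}

#' Perturb coordinates with isotropic Gaussian noise
#'
#' I.i.d. normal displacement per atom coordinate, reproducible under the
#' seed. `sigma = 0` returns the input unchanged.
#'
#' @param atoms An atom tibble.
#' @param sigma Noise standard deviation (Angstrom, per coordinate).
#' @param seed Integer seed.
#' @return The perturbed atom tibble.
#' @export
perturb <- function(atoms, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) {
    return(atoms)
  }
  n <- nrow(atoms)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(seed)
  atoms$x <- atoms$x + stats::rnorm(n, 0, sigma)
  atoms$y <- atoms$y + stats::rnorm(n, 0, sigma)
  atoms$z <- atoms$z + stats::rnorm(n, 0, sigma)
  atoms
}

#' Toy C-alpha cloud for superposition tests
#'
#' A seeded random walk with 3.8 Angstrom steps (the canonical C-alpha
#' spacing), one CA atom per residue.
#'
#' @param n Number of residues.
#' @param seed Integer seed.
#' @param chain Chain identifier.
#' @return An atom tibble of CA atoms, resno 1..n.
#' @export
make_ca_cloud <- function(n, seed = 1L, chain = "P") {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(seed)
  steps <- matrix(stats::rnorm(3 * n), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  xyz <- apply(steps, 2, cumsum)
  if (n == 1) xyz <- matrix(xyz, ncol = 3)
  new_structure_tbl(tibble::tibble(
    record = "ATOM", chain = chain, resno = seq_len(n), ins = "",
    resid = "ALA", elety = "CA", elesy = "C", alt = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0
  ))
}
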