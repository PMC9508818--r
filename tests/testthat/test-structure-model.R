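test_that("PDB round-trip preserves structure to format precision", {
  dup <- bdna_duplex()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(dup, p)
  back <- read_structure(p)
  expect_equal(nrow(back), nrow(dup))
  expect_equal(back$resid, dup$resid)
  expect_equal(back$elety, dup$elety)
  expect_equal(back$resno, dup$resno)
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
    as.matrix(dup[, c("x", "y", "z")]),
    tolerance = 1e-3, ignore_attr = TRUE
  )
})

test_that("the same content as PDB and as mmCIF parses identically", {
  dup <- bdna_duplex()
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".cif")
  write_structure(dup, p1)
  write_structure(dup, p2)
  a <- read_structure(p1)
  b <- read_structure(p2)
  expect_equal(a$elety, b$elety)
  expect_equal(a$resno, b$resno)
  expect_equal(as.matrix(a[, c("x", "y", "z")]),
    as.matrix(b[, c("x", "y", "z")]),
    ignore_attr = TRUE
  )
})

test_that("missing and unparsable files raise format errors", {
  expect_error(read_structure("no/such/file.pdb"), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure at all", bad)
  expect_error(read_structure(bad))
})

test_that("altloc resolution keeps one conformer and reports the residue", {
  dup <- bdna_duplex()
  # no altlocs: identity, empty report
  same <- resolve_altlocs(dup)
  expect_equal(nrow(same), nrow(dup))
  expect_equal(nrow(altloc_report(same)), 0)
  # plant a dual conformation on one atom: A at 0.6, B at 0.4
  alt <- dup
  i <- which(alt$chain == "A" & alt$resno == 2 & alt$elety == "C1'")
  extra <- alt[i, ]
  extra$x <- extra$x + 0.8
  alt$alt[i] <- "A"
  alt$o[i] <- 0.6
  extra$alt <- "B"
  extra$o <- 0.4
  alt <- dplyr::bind_rows(alt, extra)
  res <- resolve_altlocs(alt, policy = "highest_occupancy")
  expect_equal(nrow(res), nrow(dup))
  kept <- res[res$chain == "A" & res$resno == 2 & res$elety == "C1'", ]
  expect_equal(kept$x, dup$x[i])
  rep <- altloc_report(res)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$resno, 2L)
  expect_equal(rep$altlocs, "A,B")
  # equal occupancy: label ascending wins (A)
  alt$o[alt$alt != ""] <- 0.5
  res2 <- resolve_altlocs(alt, policy = "highest_occupancy")
  kept2 <- res2[res2$chain == "A" & res2$resno == 2 & res2$elety == "C1'", ]
  expect_equal(kept2$x, dup$x[i])
  # altloc resolution never drops a residue
  expect_equal(
    dplyr::n_distinct(paste(res$chain, res$resno)),
    dplyr::n_distinct(paste(dup$chain, dup$resno))
  )
})

test_that("chemistry annotation assigns ids and symmetric neighbor links", {
  ann <- bdna_annotated()
  res <- annotated_residues(ann)
  expect_true(all(res$chemistry_id == "DNA"))
  # symmetry: a$nxt == b iff b$prev == a
  for (i in seq_len(nrow(res))) {
    if (!is.na(res$nxt[i])) expect_equal(res$prev[res$nxt[i]], i)
    if (!is.na(res$prev[i])) expect_equal(res$nxt[res$prev[i]], i)
  }
  # links follow build order within each chain (established by proximity)
  a_chain <- res[res$chain == "A", ]
  expect_equal(a_chain$nxt[order(a_chain$resno)][1:9], 2:10)
})

test_that("a chimeric DNA/pTNA strand links across the chemistry junction", {
  chim <- make_duplex(
    duplex_spec("ATGCAA", chemistry1 = c(rep("DNA", 4), "pTNA", "pTNA"))
  )
  ann <- annotate_chemistry(chim)
  res <- annotated_residues(ann)
  a <- res[res$chain == "A", ]
  a <- a[order(a$resno), ]
  expect_equal(a$chemistry_id, c(rep("DNA", 4), "pTNA", "pTNA"))
  # the generator's connectivity table is the oracle
  conn <- attr(chim, "build")$connectivity
  conn_a <- conn[conn$chain == "A", ]
  for (k in seq_len(nrow(conn_a))) {
    i <- which(res$chain == "A" & res$resno == conn_a$resno_donor[k])
    j <- which(res$chain == "A" & res$resno == conn_a$resno_acceptor[k])
    expect_equal(res$nxt[i], j)
  }
})

test_that("unknown nucleic residue codes error in strict mode, warn otherwise", {
  dup <- bdna_duplex()
  odd <- dup
  odd$resid[odd$chain == "A" & odd$resno == 3] <- "XNA"
  expect_error(annotate_chemistry(odd), "XNA")
  expect_warning(ann <- annotate_chemistry(odd, strict = FALSE), "XNA")
  expect_equal(sum(annotated_residues(ann)$chain == "A"), 9)
})

test_that("registry files round-trip through JSON and YAML", {
  reg <- default_registry()
  reg <- registry_add_residue(reg, "QQA", "pTNA", "A")
  for (ext in c(".json", ".yaml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_registry(reg, f)
    back <- read_registry(f)
    expect_equal(names(back$chemistries), names(reg$chemistries))
    expect_equal(
      back$chemistries$pTNA$torsions, reg$chemistries$pTNA$torsions
    )
    expect_true("QQA" %in% back$residues$res_name)
  }
})
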