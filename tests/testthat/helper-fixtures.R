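# Shared fixtures, built once per test run. Everything is generated in code;
# there are no stored coordinate files.

# cosine-series torsions for a pucker state
nu_series <- function(P, nu_max) nu_max * cos((P + 144 * ((0:4) - 2)) * pi / 180)

# one idealized B-form DNA duplex reused across tests
bdna_duplex <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_duplex(duplex_spec("ATGCATGCAT"))
    val
  }
})

bdna_annotated <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- annotate_chemistry(bdna_duplex())
    val
  }
})

random_proper_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

rigidly_move <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]
  atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}
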