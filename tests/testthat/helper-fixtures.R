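# Shared fixtures (built once per test run) and independent geometry
# oracles used to cross-check the encoder.

fixture_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "pfvmkit-test-corpus")
      unlink(dir, recursive = TRUE)
      cache <<- as.character(make_fixture_library(10, seed = 42, out_dir = dir))
    }
    cache
  }
})

fixture_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_db(fixture_corpus())
    cache
  }
})

fixture_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- index_library(fixture_corpus())
    cache
  }
})

# independent torsion oracle: projection onto the plane normal to the
# central bond (praxeolitic formulation), distinct from the package's
# cross-product implementation
oracle_torsion <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

# independent bend oracle via the law of cosines on the three distances
oracle_bend <- function(p1, p2, p3) {
  a <- sqrt(sum((p1 - p2)^2)); b <- sqrt(sum((p3 - p2)^2))
  c2 <- sum((p1 - p3)^2)
  acos(min(1, max(-1, (a^2 + b^2 - c2) / (2 * a * b)))) * 180 / pi
}

trace_coords <- function(trace) as.matrix(trace$residues[, c("x", "y", "z")])

# rigidly transform a trace by a seeded random rotation + translation
random_rigid_motion <- function(trace, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, 0, 20)
  xyz <- trace_coords(trace) %*% R
  xyz <- sweep(xyz, 2, shift, "+")
  out <- trace
  out$residues$x <- xyz[, 1]; out$residues$y <- xyz[, 2]; out$residues$z <- xyz[, 3]
  out
}

random_pfsc_chars <- function(n, seed, codes = setdiff(pfsc_alphabet()$codes, "$")) {
  set.seed(seed)
  paste(sample(codes, n, replace = TRUE), collapse = "")
}
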