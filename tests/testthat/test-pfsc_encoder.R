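# PFSC encoder: alphabet structure, descriptor geometry, quantization,
# invariances and the independent brute-force oracle.

test_that("alphabet has 27 codes, all six classes populated, $ undefined", {
  ab <- pfsc_alphabet()
  expect_length(ab$codes, 27)
  expect_length(unique(ab$codes), 27)
  expect_setequal(ab$codes, c(LETTERS, "$"))
  expect_identical(classify_code("$", ab), "undefined")
  expect_identical(classify_code("A", ab), "helix")
  expect_identical(classify_code("B", ab), "strand")
  classes <- c("helix", "alike-helix", "strand", "alike-strand", "irregular")
  for (cl in classes) expect_gte(sum(ab$class_of == cl), 1)
  expect_error(classify_code("?", ab), "unknown")
})

test_that("ideal helix window descriptors match the frozen reference triple", {
  tr <- make_ideal_backbone(list(c("helix", 20)))
  for (i in c(1, 8, 16)) {
    d <- compute_window_descriptors(tr, i)
    expect_true(d$defined)
    expect_equal(d$tau1, 51.515, tolerance = 1e-3)
    expect_equal(d$tau2, 51.515, tolerance = 1e-3)
    expect_equal(d$theta, 71.665, tolerance = 1e-3)
  }
  expect_error(compute_window_descriptors(tr, 17), "out of range")
})

test_that("collinear points give theta 180 and torsions 0 by convention", {
  res <- data.frame(seq_index = 1:5, resname = "GLY", aa1 = "G",
                    x = 3.8 * (0:4), y = 0, z = 0, has_ca = TRUE)
  # collinear Ca are also spaced validly, so no break flags
  tr <- ca_trace(res)
  d <- compute_window_descriptors(tr, 1)
  expect_equal(d$theta, 180)
  expect_equal(d$tau1, 0)
  expect_identical(as.character(encode_chain(tr)), "$")  # degenerate cell
})

test_that("windows with missing Ca or internal breaks are undefined", {
  tr <- make_ideal_backbone(list(c("helix", 12)))
  tr$residues$has_ca[6] <- FALSE
  tr$residues[6, c("x", "y", "z")] <- NA
  d <- compute_window_descriptors(tr, 4)
  expect_false(d$defined)
  s <- as.character(encode_chain(tr))
  expect_identical(s, paste0("A", strrep("$", 5), "AA"))
})

test_that("noise-free helix and strand encode to constant distinct strings", {
  h <- encode_chain(make_ideal_backbone(list(c("helix", 20))))
  s <- encode_chain(make_ideal_backbone(list(c("strand", 20))))
  expect_identical(as.character(h), strrep("A", 16))
  expect_identical(as.character(s), strrep("B", 16))
})

test_that("string length is N - 4 for every fixture chain", {
  for (seed in 1:8) {
    n <- 5 + (seed * 7) %% 40
    tr <- make_ideal_backbone(backbone_spec(list(c("coil", n)), noise_deg = 0,
                                            seed = seed))
    expect_equal(nchar(encode_chain(tr)), n - 4)
  }
  expect_error(encode_chain(make_ideal_backbone(list(c("helix", 5)))[c(1)]),
               "ca_trace")
  short <- make_ideal_backbone(list(c("helix", 6)))
  short$residues <- short$residues[1:4, ]
  short$breaks <- short$breaks[1:3]
  expect_error(encode_chain(short), "at least 5")
})

test_that("encoding is invariant under rigid motion and residue identity", {
  tr <- make_ideal_backbone(backbone_spec(
    list(c("helix", 10), c("coil", 8), c("strand", 10)), noise_deg = 2,
    seed = 9))
  s0 <- as.character(encode_chain(tr))
  for (seed in 1:10) {
    moved <- random_rigid_motion(tr, seed)
    expect_identical(as.character(encode_chain(moved)), s0)
  }
  relabel <- tr
  relabel$residues$aa1 <- rep("W", length(tr))
  expect_identical(as.character(encode_chain(relabel)), s0)
})

test_that("jittered backbones (noise <= 5 deg) encode like their ideal parent", {
  for (kind in c("helix", "strand")) {
    segs <- list(c(kind, 25))
    ideal <- as.character(encode_chain(make_ideal_backbone(backbone_spec(segs))))
    for (seed in 1:15) {
      j <- make_ideal_backbone(backbone_spec(segs, noise_deg = 5, seed = seed))
      expect_identical(as.character(encode_chain(j)), ideal)
    }
  }
})

test_that("encoder agrees with a brute-force descriptor + bin oracle", {
  ab <- pfsc_alphabet()
  tau_bin <- function(tau) {
    u <- (tau - (-30)) %% 360
    if (u == 0) u <- 360
    u <- u - 30
    findInterval(u, c(-30, 120, 240, 330), left.open = TRUE,
                 rightmost.closed = TRUE)
  }
  theta_bin <- function(th) min(3, findInterval(th, c(0, 100, 145, 180),
                                                rightmost.closed = TRUE))
  for (seed in 1:25) {
    tr <- make_ideal_backbone(backbone_spec(list(c("coil", 7)), noise_deg = 4,
                                            seed = seed))
    xyz <- trace_coords(tr)
    got <- strsplit(as.character(encode_chain(tr)), "")[[1]]
    for (i in 1:3) {
      t1 <- oracle_torsion(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ], xyz[i + 3, ])
      t2 <- oracle_torsion(xyz[i + 1, ], xyz[i + 2, ], xyz[i + 3, ], xyz[i + 4, ])
      th <- oracle_bend(xyz[i, ], xyz[i + 2, ], xyz[i + 4, ])
      bins <- c(tau_bin(t1), tau_bin(t2), theta_bin(th))
      cell <- ab$cells
      want <- cell$code[cell$i1 == bins[1] & cell$i2 == bins[2] &
                        cell$i3 == bins[3]]
      expect_identical(got[i], want)
    }
  }
})

test_that("perturbing one Ca changes at most 5 consecutive symbols", {
  tr <- make_ideal_backbone(backbone_spec(
    list(c("helix", 12), c("coil", 6), c("strand", 12)), noise_deg = 2,
    seed = 13))
  s0 <- strsplit(as.character(encode_chain(tr)), "")[[1]]
  set.seed(99)
  for (rep in 1:10) {
    k <- sample(seq_len(length(tr)), 1)
    mod <- tr
    mod$residues[k, c("x", "y", "z")] <-
      mod$residues[k, c("x", "y", "z")] + rnorm(3, 0, 0.3)
    mod <- ca_trace(mod$residues, mod$chain_id, mod$source_id)
    s1 <- strsplit(as.character(encode_chain(mod)), "")[[1]]
    changed <- which(s0 != s1)
    expect_lte(length(changed), 5)
    if (length(changed) > 1)
      expect_lte(max(changed) - min(changed), 4)
    # only windows containing residue k may differ
    if (length(changed) > 0) {
      expect_gte(min(changed), k - 4)
      expect_lte(max(changed), k)
    }
  }
})

test_that("pfsc files round-trip single and multiple records", {
  s1 <- pfsc_string("AAABBB", source_id = "m1")
  s2 <- pfsc_string("ABAB$A", source_id = "m2")
  f <- withr::local_tempfile(fileext = ".pfsc")
  write_pfsc(list(s1, s2), f)
  back <- read_pfsc(f)
  expect_identical(names(back), c("m1", "m2"))
  expect_identical(as.character(back$m2), "ABAB$A")
})
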