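# Library indexing, fragmentation, conformation-homology search and
# Ca-model assembly.

test_that("library entries satisfy the string-length law and build deterministically", {
  lib <- fixture_library()
  expect_gte(length(lib$entries), 10)
  for (e in lib$entries)
    expect_equal(nchar(e$string), length(e$trace) - 4)
  set.seed(5)
  lib2 <- index_library(sample(fixture_corpus()))
  expect_identical(lapply(lib2$entries, function(e) e[c("source_id", "string")]),
                   lapply(lib$entries, function(e) e[c("source_id", "string")]))
  expect_error(index_library(character(0)), "non-empty")
})

test_that("fragment spans cover the full range with sufficient overlap", {
  s189 <- random_pfsc_chars(185, seed = 1)   # a 189-residue chain
  spans <- split_into_fragments(s189, target_len = 45, overlap = 4)
  expect_equal(nrow(spans), 5)               # ceil((189-45)/41) + 1
  expect_equal(spans$start[1], 1)
  expect_equal(spans$end[nrow(spans)], 189)
  short <- split_into_fragments(random_pfsc_chars(26, seed = 2), 45, 4)
  expect_identical(short, data.frame(start = 1L, end = 30L))
  set.seed(8)
  for (rep in 1:10) {
    n_win <- sample(30:300, 1)
    sp <- split_into_fragments(random_pfsc_chars(n_win, seed = rep + 10),
                               target_len = 45, overlap = 4)
    covered <- unique(unlist(Map(seq, sp$start, sp$end)))
    expect_setequal(covered, seq_len(n_win + 4))
    if (nrow(sp) > 1)
      for (j in 2:nrow(sp))
        expect_gte(sp$end[j - 1] - sp$start[j] + 1, 4)
  }
  expect_error(split_into_fragments(s189, overlap = 3), "at least 4")
})

test_that("a library string retrieves itself with score 1.0", {
  lib <- fixture_library()
  for (e in lib$entries[c(1, 5, 9)]) {
    hits <- search_fragments(lib, e$string, span = c(1, nchar(e$string) + 4))
    expect_gte(nrow(hits), 1)
    expect_equal(hits$score[1], 1.0)
    expect_identical(hits$source_id[1], e$source_id)
    expect_equal(hits$source_start[1], 1)
  }
  none <- search_fragments(lib, lib$entries[[1]]$string, threshold = 1.01)
  expect_equal(nrow(none), 0)
})

test_that("exhaustive hits equal a brute-force scan of all source windows", {
  lib <- fixture_library()
  q <- substr(lib$entries[[3]]$string, 5, 24)
  model <- similarity_model()
  hits <- search_fragments(lib, q, threshold = 0.60)
  brute <- list()
  for (e in seq_along(lib$entries)) {
    s <- lib$entries[[e]]$string
    if (nchar(s) < nchar(q)) next
    for (off in seq_len(nchar(s) - nchar(q) + 1)) {
      sc <- pfsa_score(q, substr(s, off, off + nchar(q) - 1), model)$score
      if (sc > 0.60)
        brute[[length(brute) + 1]] <-
          data.frame(source_id = lib$entries[[e]]$source_id,
                     source_start = off, score = sc)
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(-brute$score, brute$source_id, brute$source_start), ]
  expect_equal(nrow(hits), nrow(brute))
  expect_equal(hits$score, brute$score)
  expect_identical(hits$source_id, brute$source_id)
  expect_equal(hits$source_start, brute$source_start)
})

test_that("seeded search is a subset of exhaustive search", {
  lib <- fixture_library()
  q <- substr(lib$entries[[2]]$string, 1, 30)
  ex <- search_fragments(lib, q, threshold = 0.70)
  se <- search_fragments(lib, q, threshold = 0.70, method = "seeded")
  key <- function(h) paste(h$source_id, h$source_start)
  expect_true(all(key(se) %in% key(ex)))
  expect_true(paste(lib$entries[[2]]$source_id, 1) %in% key(se))
})

test_that("fragments cut from one structure reassemble to it exactly", {
  big <- make_ideal_backbone(backbone_spec(
    list(c("helix", 30), c("coil", 10), c("strand", 30), c("coil", 10),
         c("helix", 20)), seed = 11))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ca_model(big, f)
  lib <- index_library(c(fixture_corpus(), f))
  s <- encode_chain(big)
  spans <- split_into_fragments(s)
  ens <- build_ensemble(lib, setNames(list(s), "given"),
                        sequence = paste(big$residues$aa1, collapse = ""))
  expect_length(ens$models, 1)
  got <- ens$models[[1]]
  expect_equal(length(got), length(big))
  # identity splice: same structure up to the arbitrary global frame
  aligned <- pfvmkit:::superpose_onto(trace_coords(big), trace_coords(got),
                                      seq_len(length(big)), seq_len(length(big)))
  expect_lt(pfvmkit:::rmsd_xyz(aligned, trace_coords(big)), 0.1)
  # junction residuals are recomputable from the provenance
  expect_true(all(ens$provenance$score == 1))
  expect_identical(unique(ens$provenance$member), "given")
  expect_equal(nrow(ens$provenance), nrow(spans))
})

test_that("single-span assembly returns the fragment unchanged", {
  tr <- make_ideal_backbone(list(c("helix", 30)))
  spans <- data.frame(start = 1L, end = 30L)
  out <- assemble_model(list(tr), spans)
  expect_equal(trace_coords(out), trace_coords(tr))
  expect_length(attr(out, "junction_rmsd"), 0)
})

test_that("assembly junction residuals match direct recomputation", {
  tr <- make_ideal_backbone(backbone_spec(
    list(c("helix", 20), c("coil", 8), c("strand", 20)), noise_deg = 2,
    seed = 21))
  xyz <- trace_coords(tr)
  cut <- function(a, b) {
    res <- tr$residues[a:b, ]
    res$seq_index <- seq_len(nrow(res))
    ca_trace(res)
  }
  spans <- data.frame(start = c(1L, 21L), end = c(26L, 48L))
  frag2 <- cut(21, 48)
  # jitter fragment 2's frame: assembly must superpose it back
  moved <- random_rigid_motion(frag2, seed = 2)
  out <- assemble_model(list(cut(1, 26), moved), spans)
  jr <- attr(out, "junction_rmsd")
  expect_length(jr, 1)
  ov <- 21:26
  direct <- pfvmkit:::rmsd_xyz(trace_coords(out)[ov, ], xyz[ov, ])
  expect_equal(jr, direct, tolerance = 1e-6)
  expect_lt(jr, 1e-6)   # same rigid body, so the overlap fits exactly
  spans_bad <- data.frame(start = c(1L, 25L), end = c(26L, 48L))
  expect_error(assemble_model(list(cut(1, 26), cut(25, 48)), spans_bad),
               "too small")
})

test_that("ensembles record provenance and validate against a given structure", {
  lib <- fixture_library()
  db <- fixture_db()
  tr <- read_structure(fixture_corpus()[4])[[1]]
  m <- build_pfvm(paste(tr$residues$aa1, collapse = ""), db)
  cs <- suppressWarnings(generate_variants(m, k = 3))
  ens <- build_ensemble(lib, cs, sequence = m$sequence)
  expect_lte(length(ens$models), 3)
  expect_true(all(c("member", "source_id", "score", "threshold_used")
                  %in% names(ens$provenance)))
  expect_true(all(vapply(ens$models, length, integer(1)) == nchar(m$sequence)))
  # the encoding of the given structure itself validates at 1.00
  given <- encode_chain(tr)
  members <- c(conformation_strings(cs), list(given = given))
  v <- validate_ensemble(members, given)
  expect_equal(v$max_score, 1.0)
  # the argmax member reproduces the given conformation exactly
  expect_identical(as.character(members[[v$argmax]]), as.character(given))
})
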