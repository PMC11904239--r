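# Fold-variation matrix: construction, containment, locality, exact
# conformation counting, comparison and rendering.

# hand-built pfvm for exact-arithmetic tests
toy_pfvm <- function(depths, counts = NULL) {
  codes <- setdiff(pfsc_alphabet()$codes, "$")
  columns <- lapply(seq_along(depths), function(i) {
    d <- depths[i]
    cnt <- if (is.null(counts)) rev(seq_len(d)) else counts[[i]]
    list(position = i, pentamer = strrep("A", 5),
         entries = data.frame(code = codes[seq_len(d)], count = cnt,
                              stringsAsFactors = FALSE),
         synthetic = FALSE)
  })
  structure(list(sequence = strrep("A", length(depths) + 4),
                 columns = columns), class = "pfvm")
}

test_that("a sequence of N residues yields N - 4 ranked columns", {
  db <- fixture_db()
  tr <- read_structure(fixture_corpus()[2])[[1]]
  seq1 <- paste(tr$residues$aa1, collapse = "")
  m <- build_pfvm(seq1, db)
  expect_length(m$columns, nchar(seq1) - 4)
  for (i in seq_along(m$columns)) {
    cl <- m$columns[[i]]
    expect_identical(cl$pentamer, substr(seq1, i, i + 4))
    expect_gte(nrow(cl$entries), 1)
    expect_true(all(diff(cl$entries$count) <= 0))
  }
  m5 <- build_pfvm("AEGKV", db)
  expect_length(m5$columns, 1)
  expect_error(build_pfvm("AEGK", db), "at least 5")
})

test_that("a corpus structure's own encoding is contained in its PFVM", {
  db <- fixture_db()
  for (f in fixture_corpus()[c(1, 4, 8)]) {
    tr <- read_structure(f)[[1]]
    s <- strsplit(as.character(encode_chain(tr)), "")[[1]]
    m <- build_pfvm(paste(tr$residues$aa1, collapse = ""), db)
    for (i in seq_along(s)) {
      if (s[i] == "$") next
      expect_true(s[i] %in% m$columns[[i]]$entries$code,
                  label = sprintf("%s column %d contains %s", f, i, s[i]))
    }
  }
})

test_that("one sequence mutation perturbs at most 5 columns", {
  db <- fixture_db()
  tr <- read_structure(fixture_corpus()[5])[[1]]
  seq1 <- paste(tr$residues$aa1, collapse = "")
  m0 <- build_pfvm(seq1, db)
  set.seed(7)
  for (rep in 1:6) {
    k <- sample(nchar(seq1), 1)
    mut <- seq1
    substr(mut, k, k) <- sample(setdiff(c("A", "E", "G", "K", "L", "V", "W"),
                                        substr(seq1, k, k)), 1)
    m1 <- build_pfvm(mut, db)
    differs <- vapply(seq_along(m0$columns), function(i)
      !identical(m0$columns[[i]]$entries, m1$columns[[i]]$entries) ||
        !identical(m0$columns[[i]]$pentamer, m1$columns[[i]]$pentamer),
      logical(1))
    expect_lte(sum(differs), 5)
    # touched columns are exactly the windows covering the mutated residue
    expect_true(all(which(differs) >= k - 4 & which(differs) <= k))
  }
})

test_that("conformation counts are exact big-integer column products", {
  expect_identical(format(count_conformations(toy_pfvm(c(2, 3, 1, 4)))), "24")
  expect_identical(format(count_conformations(toy_pfvm(rep(1, 10)))), "1")
  # 25^40 needs exact arithmetic: compare digit string with a spelled-out
  # power computed by repeated decimal-string doubling-free multiplication
  m <- toy_pfvm(rep(25, 40))
  long_mult <- function(dec, k) {   # decimal string times small integer
    digits <- rev(as.integer(strsplit(dec, "")[[1]]))
    carry <- 0; out <- integer(0)
    for (d in digits) {
      v <- d * k + carry
      out <- c(out, v %% 10); carry <- v %/% 10
    }
    while (carry > 0) { out <- c(out, carry %% 10); carry <- carry %/% 10 }
    paste(rev(out), collapse = "")
  }
  want <- "1"
  for (i in 1:40) want <- long_mult(want, 25)
  expect_identical(format(count_conformations(m)), want)
  mag <- conformation_count_magnitude(m)
  expect_equal(mag$exponent, floor(40 * log10(25)))
  expect_equal(mag$mantissa * 10^mag$exponent, 25^40, tolerance = 1e-12)
})

test_that("count equals brute-force enumeration size on small matrices", {
  db <- fixture_db()
  tr <- read_structure(fixture_corpus()[1])[[1]]
  m <- build_pfvm(substr(paste(tr$residues$aa1, collapse = ""), 1, 20), db)
  n <- as.numeric(format(count_conformations(m)))
  if (n <= 1e4) {
    strings <- pfvmkit:::enumerate_conformations(m)
    expect_equal(length(unique(strings)), n)
  }
  mtoy <- toy_pfvm(c(3, 2, 2))
  expect_length(pfvmkit:::enumerate_conformations(mtoy), 12)
})

test_that("comparison to a reference reproduces Hamming distances", {
  ref <- random_pfsc_chars(40, seed = 1)
  same <- compare_to_reference(list(ref), ref)[[1]]
  expect_false(any(same$mask))
  expect_equal(same$count, 0)
  one <- ref
  substr(one, 17, 17) <- if (substr(ref, 17, 17) == "A") "B" else "A"
  r1 <- compare_to_reference(list(one), ref)[[1]]
  expect_equal(r1$count, 1)
  expect_equal(which(r1$mask), 17)
  set.seed(2)
  for (rep in 1:10) {
    s <- random_pfsc_chars(40, seed = 100 + rep)
    got <- compare_to_reference(list(s), ref)[[1]]$count
    want <- sum(strsplit(s, "")[[1]] != strsplit(ref, "")[[1]])
    expect_equal(got, want)
  }
  expect_error(compare_to_reference(list("AB"), ref), "length")
})

test_that("rendering flags mismatches and marks synthetic columns", {
  m <- toy_pfvm(c(2, 1, 3))
  m$columns[[2]]$synthetic <- TRUE
  top <- as.character(top_string(m))
  r0 <- render_pfvm(m, reference = top)
  expect_false(grepl("\\^", strsplit(r0$text, "\n")[[1]][
    grep("^mism", strsplit(r0$text, "\n")[[1]])]))
  other <- top
  substr(other, 1, 1) <- "Z"
  r1 <- render_pfvm(m, reference = other)
  expect_true(grepl("ffff99", r1$html))      # yellow mismatch background
  expect_false(grepl("ffff99", r0$html))
  expect_equal(lengths(regmatches(r1$html, gregexpr("<td", r1$html))),
               3 * max(2, 1, 3))             # one cell per (column, rank)
  expect_true(grepl("\\*", r1$text))         # synthetic marker
  expect_error(render_pfvm(m, reference = "AB"), "does not match")
})

test_that("the TSV export restores the matrix", {
  db <- fixture_db()
  tr <- read_structure(fixture_corpus()[3])[[1]]
  m <- build_pfvm(paste(tr$residues$aa1, collapse = ""), db)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pfvm_tsv(m, f)
  back <- read_pfvm_tsv(f)
  expect_identical(back$sequence, m$sequence)
  expect_equal(length(back$columns), length(m$columns))
  for (i in seq_along(m$columns)) {
    expect_identical(back$columns[[i]]$entries, m$columns[[i]]$entries)
    expect_identical(back$columns[[i]]$pentamer, m$columns[[i]]$pentamer)
  }
  expect_identical(format(count_conformations(back)),
                   format(count_conformations(m)))
})
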