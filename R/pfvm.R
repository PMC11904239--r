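# Protein folding variation matrix: ranked fold-variant columns along a
# sequence, exact conformation counts, rendering and reference comparison.

#' Build the protein folding variation matrix for a sequence
#'
#' A five-residue window slides along the sequence one residue per step
#' from the N-terminus; each window's pentamer is looked up in the fold
#' pattern database and its ranked patterns become one matrix column. A
#' sequence of N residues yields N - 4 columns. Pentamers absent from the
#' database (or containing `X`) receive synthetic backoff columns, flagged
#' as such.
#'
#' @param sequence one-letter amino-acid string of length >= 5.
#' @param db a [build_db()] result.
#' @param k_backoff backoff depth for unseen pentamers
#'   (see [query_pentamer()]).
#' @return Object of class `pfvm` with `sequence` and `columns`; each
#'   column holds `position` (1-based first residue of the window),
#'   `pentamer`, `entries` (ranked data.frame(code, count)), `synthetic`.
#' @export
build_pfvm <- function(sequence, db, k_backoff = 5L) {
  stopifnot(inherits(db, "pentamer_db"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 5) stop("sequence must have at least 5 residues")
  columns <- vector("list", n - 4L)
  for (i in seq_len(n - 4L)) {
    p <- substr(sequence, i, i + 4L)
    rec <- if (grepl("X", p, fixed = TRUE)) {
      if (nrow(db$background) == 0) stop("empty database: cannot back off")
      list(pentamer = p, patterns = head(db$background, k_backoff),
           synthetic = TRUE)
    } else query_pentamer(db, p, k_backoff)
    columns[[i]] <- list(position = i, pentamer = p,
                         entries = rec$patterns, synthetic = rec$synthetic)
  }
  structure(list(sequence = sequence, columns = columns), class = "pfvm")
}

#' @export
print.pfvm <- function(x, ...) {
  depths <- vapply(x$columns, function(cl) nrow(cl$entries), integer(1))
  syn <- vapply(x$columns, function(cl) cl$synthetic, logical(1))
  cat(sprintf("PFVM: %d residues, %d columns (depth 1-%d, median %g), %d synthetic column(s)\n",
              nchar(x$sequence), length(x$columns), max(depths),
              stats::median(depths), sum(syn)))
  cnt <- count_conformations(x)
  sc <- big_scientific(cnt)
  cat(sprintf("conformation space: %.3g x 10^%d strings\n", sc$mantissa, sc$exponent))
  invisible(x)
}

# per-column depth vector
pfvm_depths <- function(m) vapply(m$columns, function(cl) nrow(cl$entries), integer(1))

#' Exact number of conformation strings encoded by a PFVM
#'
#' The exact big-integer product over columns of the number of fold
#' variants in each column: every choice of one symbol per column is one
#' conformation string.
#'
#' @param m a [build_pfvm()] result.
#' @return A `big_integer`; use `format()` for the decimal value or
#'   [conformation_count_magnitude()] for a mantissa/exponent view.
#' @export
count_conformations <- function(m) {
  stopifnot(inherits(m, "pfvm"))
  out <- big_integer(1L)
  for (d in pfvm_depths(m)) out <- big_mul_small(out, d)
  out
}

#' Mantissa/exponent view of a conformation count
#'
#' @param x a `big_integer` (or a `pfvm`, counted first).
#' @return List with `mantissa` (in \[1, 10)) and integer `exponent`, i.e.
#'   the count is `mantissa x 10^exponent`.
#' @export
conformation_count_magnitude <- function(x) {
  if (inherits(x, "pfvm")) x <- count_conformations(x)
  stopifnot(inherits(x, "big_integer"))
  big_scientific(x)
}

#' Compare conformation strings against a reference
#'
#' @param strings list of [pfsc_string()] (or character), all the same
#'   length as `reference`.
#' @param reference a [pfsc_string()] or character scalar.
#' @return List per string: `mask` (logical mismatch vector) and `count`.
#' @export
compare_to_reference <- function(strings, reference) {
  ref <- strsplit(as_pfsc_chars(reference), "")[[1]]
  if (inherits(strings, "pfsc_string") || is.character(strings))
    strings <- list(strings)
  lapply(strings, function(s) {
    ch <- strsplit(as_pfsc_chars(s), "")[[1]]
    if (length(ch) != length(ref))
      stop("string length ", length(ch), " does not match reference length ",
           length(ref))
    mask <- ch != ref
    list(mask = mask, count = sum(mask))
  })
}

#' Render a PFVM as plain text or HTML
#'
#' The plain-text view prints columns top-to-bottom by rank with class
#' names spelled out in a legend; the HTML view styles each cell by fold
#' class (helix/alike-helix/strand/alike-strand/irregular/undefined) and,
#' when a reference conformation string is supplied, gives cells whose
#' rank-1 code differs from the reference a yellow background. Synthetic
#' (backoff) columns are marked with `*`.
#'
#' @param m a [build_pfvm()] result.
#' @param reference optional [pfsc_string()] of length equal to the number
#'   of columns; its symbols are flagged where they differ from rank 1.
#' @param alphabet alphabet used for class styling.
#' @return List with `text` and `html` character scalars.
#' @export
render_pfvm <- function(m, reference = NULL, alphabet = default_alphabet()) {
  stopifnot(inherits(m, "pfvm"))
  ncol <- length(m$columns)
  ref <- NULL
  if (!is.null(reference)) {
    ref <- strsplit(as_pfsc_chars(reference), "")[[1]]
    if (length(ref) != ncol)
      stop("reference length ", length(ref), " does not match ", ncol, " columns")
  }
  depth <- max(pfvm_depths(m))
  grid <- matrix(" ", nrow = depth, ncol = ncol)
  for (j in seq_len(ncol)) {
    e <- m$columns[[j]]$entries$code
    grid[seq_along(e), j] <- e
  }
  syn <- vapply(m$columns, function(cl) cl$synthetic, logical(1))
  txt <- c(sprintf("PFVM: %d columns (windows of 5 residues); '*' marks backoff columns",
                   ncol),
           paste0("seq  ", m$sequence),
           paste0("syn  ", paste(ifelse(syn, "*", " "), collapse = "")),
           vapply(seq_len(depth), function(r)
             sprintf("r%02d  %s", r, paste(grid[r, ], collapse = "")),
             character(1)))
  if (!is.null(ref))
    txt <- c(txt, paste0("ref  ", paste(ref, collapse = "")),
             paste0("mism ", paste(ifelse(grid[1, ] != ref, "^", " "),
                                   collapse = "")))

  style <- c(helix = "#d62728", `alike-helix` = "#ff9896",
             strand = "#1f77b4", `alike-strand` = "#aec7e8",
             irregular = "#000000", undefined = "#7f7f7f")
  rows <- character(depth)
  for (r in seq_len(depth)) {
    cells <- character(ncol)
    for (j in seq_len(ncol)) {
      ch <- grid[r, j]
      if (ch == " ") { cells[j] <- "<td></td>"; next }
      cl <- unname(alphabet$class_of[ch])
      bg <- if (!is.null(ref) && r == 1 && ch != ref[j])
        " background:#ffff99;" else ""
      cells[j] <- sprintf('<td class="%s" style="color:%s;%s">%s</td>',
                          cl, style[[cl]], bg, ch)
    }
    rows[r] <- paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }
  hdr <- paste0("<tr>", paste(sprintf("<th>%s</th>",
                                      ifelse(syn, "*", "")), collapse = ""),
                "</tr>")
  html <- paste0("<table class=\"pfvm\">", hdr,
                 paste(rows, collapse = ""), "</table>")
  list(text = paste(txt, collapse = "\n"), html = html)
}

#' Export a PFVM as a tidy TSV table
#'
#' One row per (column, rank) entry with columns `position`, `pentamer`,
#' `rank`, `code`, `count`, `synthetic`. [read_pfvm_tsv()] restores the
#' `pfvm` object (sequence reconstructed from the window pentamers).
#'
#' @param m a [build_pfvm()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pfvm_tsv <- function(m, path) {
  stopifnot(inherits(m, "pfvm"))
  rows <- do.call(rbind, lapply(m$columns, function(cl)
    data.frame(position = cl$position, pentamer = cl$pentamer,
               rank = seq_len(nrow(cl$entries)), code = cl$entries$code,
               count = cl$entries$count, synthetic = cl$synthetic,
               stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PFVM from its TSV export
#' @param path file written by [write_pfvm_tsv()] (columns `position`,
#'   `pentamer`, `rank`, `code`, `count`, `synthetic`).
#' @return A `pfvm`.
#' @export
read_pfvm_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read PFVM table: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(pentamer = "character", code = "character"))
  need <- c("position", "pentamer", "rank", "code", "count", "synthetic")
  if (!all(need %in% names(df))) stop("malformed PFVM table: ", path)
  pos <- sort(unique(df$position))
  if (!identical(pos, seq_along(pos))) stop("non-contiguous PFVM positions in ", path)
  columns <- lapply(pos, function(i) {
    sub <- df[df$position == i, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    list(position = i, pentamer = sub$pentamer[1],
         entries = data.frame(code = sub$code, count = sub$count,
                              stringsAsFactors = FALSE),
         synthetic = any(sub$synthetic))
  })
  pent <- vapply(columns, function(cl) cl$pentamer, character(1))
  sequence <- paste0(substr(pent, 1, 1)[-length(pent)] |> paste(collapse = ""),
                     pent[length(pent)])
  structure(list(sequence = sequence, columns = columns), class = "pfvm")
}
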