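# Conformation-string generation from a PFVM: the rank-1 string, a
# per-column log-probability score, single-substitution neighborhoods and
# exact top-k beam search.

#' The rank-1 conformation string of a PFVM
#'
#' Concatenates each column's rank-1 code: the single most favorable
#' conformation encoded by the matrix, conventionally named `PFVM-01`.
#'
#' @param m a [build_pfvm()] result.
#' @return A [pfsc_string()].
#' @export
top_string <- function(m) {
  stopifnot(inherits(m, "pfvm"))
  pfsc_string(paste(vapply(m$columns, function(cl) cl$entries$code[1],
                           character(1)), collapse = ""),
              source_id = "PFVM-01")
}

#' Log-probability score of a conformation string under a PFVM
#'
#' Each column is read as a categorical distribution proportional to its
#' pattern counts; the score of a string is the sum over columns of the
#' log probability of its symbol. The rank-1 string maximizes the score.
#'
#' @param m a [build_pfvm()] result.
#' @param s a [pfsc_string()] or character scalar, one symbol per column,
#'   column-wise contained in `m`.
#' @return Numeric log score (<= 0; 0 when every column has one variant).
#' @export
string_log_score <- function(m, s) {
  stopifnot(inherits(m, "pfvm"))
  ch <- strsplit(as_pfsc_chars(s), "")[[1]]
  if (length(ch) != length(m$columns))
    stop("string length ", length(ch), " does not match ",
         length(m$columns), " columns")
  total <- 0
  for (j in seq_along(ch)) {
    e <- m$columns[[j]]$entries
    k <- match(ch[j], e$code)
    if (is.na(k))
      stop("symbol ", ch[j], " at column ", j, " is not contained in the PFVM")
    total <- total + log(e$count[k] / sum(e$count))
  }
  total
}

# all strings of a small PFVM (guarded); used by tests and exact oracles
enumerate_conformations <- function(m, limit = 1e4) {
  stopifnot(inherits(m, "pfvm"))
  if (big_log10(count_conformations(m)) > log10(limit))
    stop("conformation space exceeds enumeration limit of ", limit)
  cols <- lapply(m$columns, function(cl) cl$entries$code)
  grid <- expand.grid(rev(cols), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(cols)), drop = FALSE], 1, paste, collapse = "")
}

#' Generate a ranked set of conformation strings from a PFVM
#'
#' Mode `single_sub` returns the rank-1 string (`PFVM-01`) plus strings
#' differing from it in exactly one column, substituting ranks
#' `2..max_rank`, ordered by log score. Mode `beam` runs an exact beam
#' search (beam width >= k) over the per-column probability model and
#' returns the k highest-scoring distinct strings. `PFVM-01` is always
#' member 1; ties are broken deterministically by column index then code
#' rank. If fewer than `k` distinct strings exist, all are returned with a
#' warning.
#'
#' @param m a [build_pfvm()] result.
#' @param k requested number of conformations (default 10).
#' @param max_rank deepest column rank used for substitutions (default 3).
#' @param mode `"beam"` (exact top-k) or `"single_sub"`.
#' @return Object of class `conformation_set`: data.frame `members` with
#'   columns `name`, `string`, `log_score`, plus the generating mode.
#' @export
generate_variants <- function(m, k = 10L, max_rank = 3L,
                              mode = c("beam", "single_sub")) {
  stopifnot(inherits(m, "pfvm"), k >= 1, max_rank >= 1)
  mode <- match.arg(mode)
  ncol <- length(m$columns)
  top <- as.character(top_string(m))
  depths <- pmin(pfvm_depths(m), max_rank)

  if (mode == "single_sub") {
    strings <- top
    col_id <- 0L; rank_id <- 1L
    for (j in seq_len(ncol)) {
      d <- depths[j]
      if (d < 2) next
      for (r in 2:d) {
        s <- top
        substr(s, j, j) <- m$columns[[j]]$entries$code[r]
        strings <- c(strings, s)
        col_id <- c(col_id, j); rank_id <- c(rank_id, r)
      }
    }
    score <- vapply(strings, function(s) string_log_score(m, s), numeric(1))
    ord <- order(-score, col_id, rank_id)
    ord <- c(1L, setdiff(ord, 1L))     # PFVM-01 stays member 1
    strings <- strings[ord]; score <- score[ord]
    if (length(strings) < k)
      warning("only ", length(strings), " distinct strings available; ",
              "returning all")
    keep <- seq_len(min(k, length(strings)))
    strings <- strings[keep]; score <- score[keep]
  } else {
    # exact k-best over an additive independent-column score: keeping the
    # top-k scoring prefixes at every column is sufficient
    logp <- lapply(seq_len(ncol), function(j) {
      e <- m$columns[[j]]$entries
      r <- seq_len(depths[j])
      log(e$count[r] / sum(e$count))
    })
    beam <- data.frame(s = "", score = 0, tie = "", stringsAsFactors = FALSE)
    for (j in seq_len(ncol)) {
      e <- m$columns[[j]]$entries
      cand <- do.call(rbind, lapply(seq_len(depths[j]), function(r)
        data.frame(s = paste0(beam$s, e$code[r]),
                   score = beam$score + logp[[j]][r],
                   tie = paste0(beam$tie, sprintf("%02d", r)),
                   stringsAsFactors = FALSE)))
      cand <- cand[order(-cand$score, cand$tie), , drop = FALSE]
      beam <- head(cand, k)
    }
    if (nrow(beam) < k)
      warning("only ", nrow(beam), " distinct strings available; returning all")
    # PFVM-01 is the exact maximizer; guarantee it leads the member list
    ord <- c(which(beam$s == top), which(beam$s != top))
    strings <- beam$s[ord]; score <- beam$score[ord]
  }

  names <- sprintf("PFVM-%02d", seq_along(strings))
  names[strings == top] <- "PFVM-01"
  members <- data.frame(name = names, string = strings, log_score = score,
                        stringsAsFactors = FALSE)
  rownames(members) <- NULL
  structure(list(members = members, mode = mode, pfvm_id = m$sequence),
            class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat(sprintf("Conformation set (%s): %d member(s) of length %d\n",
              x$mode, nrow(x$members), nchar(x$members$string[1])))
  show <- head(x$members, 10)
  for (i in seq_len(nrow(show)))
    cat(sprintf("  %-8s %8.3f  %s\n", show$name[i], show$log_score[i],
                substr(show$string[i], 1, 60)))
  invisible(x)
}

#' Conformation set members as PFSC strings
#' @param x a [generate_variants()] result.
#' @return Named list of [pfsc_string()].
#' @export
conformation_strings <- function(x) {
  stopifnot(inherits(x, "conformation_set"))
  setNames(lapply(seq_len(nrow(x$members)), function(i)
    pfsc_string(x$members$string[i], source_id = x$members$name[i])),
    x$members$name)
}
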