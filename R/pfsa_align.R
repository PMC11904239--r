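# Protein folding structural alignment (PFSA): a normalized [0, 1]
# similarity score between two PFSC conformation strings. Identical
# conformations score 1.00; > 0.70 is the conventional acceptance
# threshold for a conformational homolog.

#' Similarity model for PFSA scoring
#'
#' Position weights: identical codes score `w_identical` (1.0); different
#' codes of the same fold class `w_class` (0.8); a helix/alike-helix or
#' strand/alike-strand pairing `w_alike` (0.5); anything else 0. The
#' undefined symbol `$` scores 0 against everything. Unequal-length
#' strings are globally aligned with affine gap penalties; gapped positions
#' contribute weight 0.
#'
#' @param w_identical,w_class,w_alike class-weight calibration in \[0, 1\],
#'   non-increasing.
#' @param gap_open,gap_extend affine gap penalties (<= 0) applied during
#'   global alignment of unequal-length strings.
#' @param alphabet a [pfsc_alphabet()] supplying the class map.
#' @return Object of class `similarity_model` holding the full 27 x 27
#'   symbol weight matrix.
#' @export
similarity_model <- function(w_identical = 1.0, w_class = 0.8, w_alike = 0.5,
                             gap_open = -0.5, gap_extend = -0.1,
                             alphabet = default_alphabet()) {
  stopifnot(w_identical >= w_class, w_class >= w_alike, w_alike >= 0,
            w_identical <= 1, gap_open <= 0, gap_extend <= 0)
  codes <- alphabet$codes
  cls <- alphabet$class_of
  w <- matrix(0, 27, 27, dimnames = list(codes, codes))
  alike <- function(a, b) {
    (a == "helix" && b == "alike-helix") || (a == "alike-helix" && b == "helix") ||
    (a == "strand" && b == "alike-strand") || (a == "alike-strand" && b == "strand")
  }
  for (a in codes) for (b in codes) {
    if (a == "$" || b == "$") { w[a, b] <- 0; next }
    w[a, b] <- if (a == b) w_identical
      else if (cls[[a]] == cls[[b]]) w_class
      else if (alike(cls[[a]], cls[[b]])) w_alike
      else 0
  }
  structure(list(weight = w, gap_open = gap_open, gap_extend = gap_extend),
            class = "similarity_model")
}

default_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- similarity_model()
    cache
  }
})

#' PFSA score between two conformation strings
#'
#' Equal-length strings are compared position by position; the score is the
#' mean position weight, so identical strings (without `$`) score exactly
#' 1.0. Unequal-length strings are globally aligned (affine gaps,
#' [Biostrings::pairwiseAlignment()]) and the summed weight is normalized
#' by the longer string length, which keeps the 0.70 acceptance threshold
#' meaningful for partial matches. The score is symmetric.
#'
#' @param a,b [pfsc_string()] objects or character scalars.
#' @param model a [similarity_model()].
#' @return Object of class `pfsa_alignment`: `score` in \[0, 1\],
#'   `aligned_pairs` (data.frame `i`, `j`, `NA` at gaps),
#'   `per_position_weight`.
#' @examples
#' s <- encode_chain(make_ideal_backbone(list(c("helix", 20))))
#' pfsa_score(s, s)$score  # 1
#' @export
pfsa_score <- function(a, b, model = default_model()) {
  stopifnot(inherits(model, "similarity_model"))
  sa <- as_pfsc_chars(a); sb <- as_pfsc_chars(b)
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("cannot align an empty string")
  w <- model$weight
  ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
  if (!all(ca %in% rownames(w)) || !all(cb %in% rownames(w)))
    stop("string contains symbols outside the PFSC alphabet")
  if (nchar(sa) == nchar(sb)) {
    weights <- w[cbind(ca, cb)]
    pairs <- data.frame(i = seq_along(ca), j = seq_along(cb))
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::BString(sa), Biostrings::BString(sb),
      substitutionMatrix = w, type = "global",
      gapOpening = -model$gap_open, gapExtension = -model$gap_extend)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    weights <- numeric(length(pa))
    i <- 0L; j <- 0L
    pairs <- data.frame(i = rep(NA_integer_, length(pa)),
                        j = rep(NA_integer_, length(pa)))
    for (k in seq_along(pa)) {
      gap_a <- pa[k] == "-"; gap_b <- pb[k] == "-"
      if (!gap_a) i <- i + 1L
      if (!gap_b) j <- j + 1L
      if (!gap_a) pairs$i[k] <- i
      if (!gap_b) pairs$j[k] <- j
      weights[k] <- if (gap_a || gap_b) 0 else w[pa[k], pb[k]]
    }
  }
  score <- sum(weights) / max(nchar(sa), nchar(sb))
  structure(list(score = score, aligned_pairs = pairs,
                 per_position_weight = weights),
            class = "pfsa_alignment")
}

#' @export
print.pfsa_alignment <- function(x, ...) {
  cat(sprintf("PFSA alignment: score %.3f over %d aligned position(s)\n",
              x$score, nrow(x$aligned_pairs)))
  invisible(x)
}

#' Pairwise PFSA score matrix
#'
#' @param strings list of two or more [pfsc_string()] (or character).
#' @param model a [similarity_model()].
#' @return Symmetric numeric matrix of PFSA scores; the diagonal holds each
#'   string's self-score (1.0 unless the string contains `$`).
#' @export
pairwise_matrix <- function(strings, model = default_model()) {
  n <- length(strings)
  if (n < 2) stop("need at least two strings")
  nms <- names(strings)
  if (is.null(nms))
    nms <- vapply(seq_len(n), function(i) {
      s <- strings[[i]]
      if (inherits(s, "pfsc_string") && nzchar(s$source_id)) s$source_id
      else paste0("s", i)
    }, character(1))
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) {
    m[i, i] <- pfsa_score(strings[[i]], strings[[i]], model)$score
    if (i < n) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- pfsa_score(strings[[i]], strings[[j]], model)$score
    }
  }
  m
}
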