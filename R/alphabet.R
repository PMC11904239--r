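#' The 27-symbol protein folding shape code alphabet
#'
#' A PFSC alphabet quantizes the local geometry of five consecutive Cα atoms
#' into one of 27 folding shapes, written as the 26 letters `A`-`Z` plus
#' `$`. Each window of five Cα atoms is summarized by three descriptors:
#' two consecutive Cα pseudo-torsions (`tau1` over residues i..i+3, `tau2`
#' over i+1..i+4, IUPAC sign, degrees) and the pseudo-bend angle `theta` at
#' the central residue over Cα(i), Cα(i+2), Cα(i+4). Each descriptor is cut
#' into three bins, giving a 3 x 3 x 3 cube of 27 cells; 26 cells carry a
#' letter and the cell containing degenerate (near-collinear) geometry is
#' merged with the undefined symbol `$`, which also marks windows with
#' missing atoms or chain breaks.
#'
#' Pseudo-torsions are binned on the circle with the cut placed at -30
#' degrees (values reported in (-30, 330]) so that neither canonical helix
#' (tau around +52) nor canonical strand (tau around 180) sits near a bin
#' edge; bend angles are binned on \[0, 180\]. The default boundaries were
#' calibrated once against the ideal fixture generator so that ideal helix
#' and strand land in the interior of distinct pure cells and survive a
#' few degrees of torsional jitter; they are configuration, not constants.
#'
#' Every code belongs to one of six classes: `helix`, `alike-helix`,
#' `strand`, `alike-strand`, `irregular`, `undefined`. The pure helix cell
#' is written `A`, the pure strand cell `B`; the remaining geometric cells
#' take `C`-`Z` in fixed cell order.
#'
#' @param tau_breaks increasing numeric breakpoints of the wrapped
#'   pseudo-torsion axis, length 4, spanning 360 degrees. Bin 1 is the
#'   helix-like bin (must contain +52), bin 2 the strand-like bin (must
#'   contain 180), bin 3 the remainder.
#' @param theta_breaks increasing breakpoints of the bend-angle axis,
#'   length 4, from 0 to 180. Bin 1 must contain the canonical helix bend,
#'   bin 3 the canonical strand bend.
#' @return An object of class `pfsc_alphabet` with elements `codes` (27
#'   symbols), `class_of` (named character, code -> class), `cells`
#'   (data.frame mapping bin triples to codes), `tau_breaks`, `theta_breaks`.
#' @examples
#' ab <- pfsc_alphabet()
#' length(ab$codes)      # 27
#' classify_code("A", ab)
#' @export
pfsc_alphabet <- function(tau_breaks = c(-30, 120, 240, 330),
                          theta_breaks = c(0, 100, 145, 180)) {
  stopifnot(length(tau_breaks) == 4, length(theta_breaks) == 4,
            all(diff(tau_breaks) > 0), all(diff(theta_breaks) > 0))
  if (abs((tau_breaks[4] - tau_breaks[1]) - 360) > 1e-9)
    stop("tau_breaks must span the full 360-degree circle")
  if (theta_breaks[1] != 0 || theta_breaks[4] != 180)
    stop("theta_breaks must span [0, 180]")

  # cell roles in (tau1 bin, tau2 bin, theta bin) coordinates:
  #   helix cell (1,1,1); strand cell (2,2,3); degenerate cell (1,1,3)
  # (a collinear window has theta = 180 and torsions taken as 0 -> tau bin 1)
  cells <- expand.grid(i1 = 1:3, i2 = 1:3, i3 = 1:3,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$i1, cells$i2, cells$i3), ]
  key <- paste(cells$i1, cells$i2, cells$i3)
  code <- rep(NA_character_, 27)
  code[key == "1 1 1"] <- "A"
  code[key == "2 2 3"] <- "B"
  code[key == "1 1 3"] <- "$"
  code[is.na(code)] <- LETTERS[3:26]
  cells$code <- code

  tau_class <- c("H", "S", "O")   # bin 1 helix-like, 2 strand-like, 3 other
  cls <- character(27)
  for (r in seq_len(27)) {
    t1 <- tau_class[cells$i1[r]]; t2 <- tau_class[cells$i2[r]]
    th <- cells$i3[r]
    cls[r] <-
      if (cells$code[r] == "$") "undefined"
      else if (t1 == "H" && t2 == "H") {
        if (th == 1) "helix" else "alike-helix"
      } else if (t1 == "S" && t2 == "S") {
        if (th == 3) "strand" else "alike-strand"
      } else if ("H" %in% c(t1, t2) && "S" %in% c(t1, t2)) "irregular"
      else if ("H" %in% c(t1, t2)) "alike-helix"
      else if ("S" %in% c(t1, t2)) "alike-strand"
      else "irregular"
  }
  cells$class <- cls

  out <- list(codes = cells$code,
              class_of = setNames(cells$class, cells$code),
              cells = cells,
              tau_breaks = tau_breaks,
              theta_breaks = theta_breaks)
  class(out) <- "pfsc_alphabet"
  out
}

#' Default PFSC alphabet (cached)
#' @return The [pfsc_alphabet()] built with default boundaries.
#' @export
default_alphabet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pfsc_alphabet()
    cache
  }
})

#' Class label of a PFSC code
#'
#' @param code a single PFSC symbol.
#' @param alphabet a [pfsc_alphabet()].
#' @return One of `"helix"`, `"alike-helix"`, `"strand"`, `"alike-strand"`,
#'   `"irregular"`, `"undefined"`.
#' @examples
#' classify_code("B", pfsc_alphabet())  # "strand"
#' @export
classify_code <- function(code, alphabet = default_alphabet()) {
  stopifnot(inherits(alphabet, "pfsc_alphabet"))
  if (!is.character(code) || length(code) != 1L || is.na(code))
    stop("`code` must be a single symbol")
  if (!code %in% alphabet$codes)
    stop("unknown PFSC symbol: ", code)
  unname(alphabet$class_of[code])
}

#' @export
print.pfsc_alphabet <- function(x, ...) {
  cat("PFSC alphabet: 27 codes over a 3x3x3 descriptor cube\n")
  tab <- table(factor(x$class_of,
                      levels = c("helix", "alike-helix", "strand",
                                 "alike-strand", "irregular", "undefined")))
  for (cl in names(tab))
    cat(sprintf("  %-12s %2d  [%s]\n", cl, tab[[cl]],
                paste(names(x$class_of)[x$class_of == cl], collapse = "")))
  invisible(x)
}

# map raw tau (degrees, any branch) onto the wrapped axis (lo, lo+360]
wrap_tau <- function(tau, lo) {
  y <- (tau - lo) %% 360
  y[y == 0] <- 360
  y + lo
}

# descriptor triple -> bin triple under an alphabet; NA-safe
quantize_window <- function(tau1, tau2, theta, alphabet) {
  tb <- alphabet$tau_breaks; hb <- alphabet$theta_breaks
  i1 <- findInterval(wrap_tau(tau1, tb[1]), tb, left.open = TRUE,
                     rightmost.closed = TRUE)
  i2 <- findInterval(wrap_tau(tau2, tb[1]), tb, left.open = TRUE,
                     rightmost.closed = TRUE)
  i3 <- findInterval(theta, hb, rightmost.closed = TRUE)
  i3 <- pmin(pmax(i3, 1L), 3L)
  c(i1, i2, i3)
}

# bin triple -> code
cell_code <- function(bins, alphabet) {
  cells <- alphabet$cells
  cells$code[cells$i1 == bins[1] & cells$i2 == bins[2] & cells$i3 == bins[3]]
}
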