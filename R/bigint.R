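# Minimal exact non-negative big integer (base 1e4, little-endian digit
# vector). Only what the conformation counter needs: construction from a
# machine integer, multiplication by a small integer, decimal formatting
# and a mantissa/exponent view. Written here because no arbitrary-precision
# arithmetic package ships with the environment this package targets.

big_integer <- function(n = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == floor(n), n < 1e15)
  digits <- integer(0)
  n <- as.numeric(n)
  repeat {
    digits <- c(digits, as.integer(n %% 10000))
    n <- floor(n / 10000)
    if (n == 0) break
  }
  structure(list(d = digits), class = "big_integer")
}

# multiply by a small non-negative machine integer (< 2^31 / 1e4)
big_mul_small <- function(x, m) {
  stopifnot(inherits(x, "big_integer"), m >= 0, m == floor(m), m < 200000)
  if (m == 0) return(big_integer(0))
  d <- as.numeric(x$d) * m
  carry <- 0
  out <- numeric(0)
  i <- 1
  while (i <= length(d) || carry > 0) {
    v <- carry + if (i <= length(d)) d[i] else 0
    out <- c(out, v %% 10000)
    carry <- floor(v / 10000)
    i <- i + 1
  }
  structure(list(d = as.integer(out)), class = "big_integer")
}

#' @export
format.big_integer <- function(x, ...) {
  d <- rev(x$d)
  paste0(d[1], paste(sprintf("%04d", d[-1]), collapse = ""))
}

#' @export
print.big_integer <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.big_integer <- function(x, ...) format(x)

# scientific view: list(mantissa in [1,10), exponent); exact digits feed a
# floating mantissa from the leading 15 decimal digits
big_scientific <- function(x) {
  s <- format(x)
  exponent <- nchar(s) - 1L
  lead <- substr(s, 1, min(15, nchar(s)))
  mantissa <- as.numeric(lead) / 10^(nchar(lead) - 1L)
  list(mantissa = mantissa, exponent = exponent)
}

# base-10 logarithm of the exact integer
big_log10 <- function(x) {
  sc <- big_scientific(x)
  log10(sc$mantissa) + sc$exponent
}
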