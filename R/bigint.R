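# Exact non-negative integer arithmetic for configuration counts, which
# overflow doubles for realistic networks (the 14-node reprogramming network
# has ~2.6e25 operator configurations). Little-endian base-10000 digit
# vectors; schoolbook multiplication is ample at these sizes.

#' Exact big integer
#'
#' Minimal arbitrary-precision non-negative integers used for configuration
#' counting. Construct from a number or a digit string; combine with
#' [bigint_mul()] / [bigint_pow()]; render with `as.character()` or compare
#' with `==` against another `bigint` or a digit string.
#'
#' @param x Non-negative integer scalar, or a string of decimal digits.
#' @return An object of class `bigint`.
#' @examples
#' as.character(bigint_pow(bigint(16), 12))
#' @export
bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    s <- gsub("[ ,]", "", x)
    if (!grepl("^[0-9]+$", s)) stop("not a digit string: ", x)
    s <- sub("^0+(?=.)", "", s, perl = TRUE)
    n <- nchar(s)
    # groups of four decimal digits taken from the right: least significant first
    ends <- seq(n, 1, by = -4)
    d <- vapply(ends, function(i) as.integer(substr(s, max(i - 3, 1), i)), 0L)
    return(structure(list(d = d), class = "bigint"))
  }
  if (x < 0 || x != floor(x) || x > 2^53) stop("need a non-negative integer below 2^53")
  d <- integer(0)
  repeat {
    d <- c(d, as.integer(x %% 1e4))
    x <- floor(x / 1e4)
    if (x == 0) break
  }
  structure(list(d = d), class = "bigint")
}

#' Multiply two big integers
#' @param a,b `bigint` objects (or values accepted by [bigint()]).
#' @return A `bigint`.
#' @export
bigint_mul <- function(a, b) {
  a <- bigint(a); b <- bigint(b)
  la <- length(a$d); lb <- length(b$d)
  acc <- numeric(la + lb)
  for (i in seq_len(la)) {
    acc[i:(i + lb - 1)] <- acc[i:(i + lb - 1)] + a$d[i] * b$d
  }
  # carry propagation (doubles hold the partial sums exactly: < 1e8 * lb)
  carry <- 0
  d <- integer(length(acc))
  for (i in seq_along(acc)) {
    v <- acc[i] + carry
    d[i] <- as.integer(v %% 1e4)
    carry <- floor(v / 1e4)
  }
  while (carry > 0) {
    d <- c(d, as.integer(carry %% 1e4))
    carry <- floor(carry / 1e4)
  }
  while (length(d) > 1 && d[length(d)] == 0L) d <- d[-length(d)]
  structure(list(d = d), class = "bigint")
}

#' @rdname bigint_mul
#' @param n Non-negative integer exponent.
#' @export
bigint_pow <- function(a, n) {
  a <- bigint(a)
  out <- bigint(1)
  for (i in seq_len(n)) out <- bigint_mul(out, a)
  out
}

#' @export
as.character.bigint <- function(x, ...) {
  d <- rev(x$d)
  paste0(d[1], paste(sprintf("%04d", d[-1]), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
`==.bigint` <- function(e1, e2) {
  identical(bigint(e1)$d, bigint(e2)$d)
}
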