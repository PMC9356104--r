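# Exact multilinear (pseudo-Boolean) interpolation of the discrete landscape:
# the unique polynomial first-order in every gene that agrees with T at all
# binary corners, E(s) = sum_b omega_b prod_{i in b} s_i, plus the mixing
# entropy and the free energy F = E - T S.

#' Interpolation matrix M and its inverse
#'
#' `M` relates the multilinear coefficients to the corner energies via
#' `M %*% omega = T`: `M[a+1, b+1] = 1` iff the bit set of `b` is a subset
#' of the bit set of `a`. Both `M` and its inverse follow the recursive
#' block rule `M(n+1) = [[M(n), 0], [M(n), M(n)]]` (a Kronecker power of the
#' 2x2 base), the inverse carrying alternating signs. Exact in integer
#' arithmetic.
#'
#' @param n Number of genes (guarded at 14: the dense matrix is 2^n x 2^n;
#'   use [omega_from_T()], which never materializes M, for larger systems).
#' @return List with integer matrices `M` and `Minv`.
#' @examples
#' build_M(1)   # M = [[1,0],[1,1]], Minv = [[1,0],[-1,1]]
#' @export
build_M <- function(n) {
  if (n < 1 || n > 14) stop("n must be in 1..14")
  base <- matrix(c(1L, 1L, 0L, 1L), 2, 2)       # [[1,0],[1,1]]
  base_inv <- matrix(c(1L, -1L, 0L, 1L), 2, 2)  # [[1,0],[-1,1]]
  M <- base; Minv <- base_inv
  for (i in seq_len(n - 1)) {
    M <- base %x% M
    Minv <- base_inv %x% Minv
  }
  storage.mode(M) <- "integer"
  storage.mode(Minv) <- "integer"
  list(M = M, Minv = Minv)
}

#' Multilinear coefficients from a discrete landscape
#'
#' Computes `omega = Minv %*% T` by the fast subset Moebius transform in
#' O(n 2^n), without materializing M. Integer landscapes give integer
#' coefficients. `omega[b+1]` is the coefficient of the monomial
#' `prod_{i in bits(b)} s_i`.
#'
#' @param T An `energy_landscape`, or a numeric vector of length 2^n.
#' @return Numeric coefficient vector omega of length 2^n.
#' @examples
#' omega_from_T(c(0, 0, 1, -1))   # (0, 0, 1, -2): single-activator motif
#' @export
omega_from_T <- function(T) {
  if (inherits(T, "energy_landscape")) T <- T$T
  len <- length(T)
  n <- round(log2(len))
  if (2^n != len) stop("length of T must be a power of two")
  w <- as.numeric(T)
  for (i in seq_len(n) - 1L) {
    bit <- bitwShiftL(1L, i)
    hi <- which(bitwAnd(0:(len - 1L), bit) != 0L)
    w[hi] <- w[hi] - w[hi - bit]
  }
  w
}

#' Evaluate the continuous energy
#'
#' Evaluates the multilinear form at a point of the unit hypercube by
#' collapsing one gene at a time: `c <- c_without + s_i * c_with`, O(2^n)
#' total. At binary corners this reproduces the discrete energy exactly.
#'
#' @param omega Coefficient vector from [omega_from_T()].
#' @param s Numeric vector of expression levels in `[0, 1]`, one per gene.
#' @return The energy value.
#' @export
energy_continuous <- function(omega, s) {
  len <- length(omega)
  n <- round(log2(len))
  if (2^n != len) stop("length of omega must be a power of two")
  if (length(s) != n) stop("need one coordinate per gene")
  if (any(s < 0 | s > 1)) stop("coordinates must lie in [0, 1]")
  w <- as.numeric(omega)
  for (i in seq_len(n)) {
    half <- length(w) / 2
    # coefficients with gene i absent come first under little-endian masks
    w <- w[seq_len(half) * 2 - 1] + s[i] * w[seq_len(half) * 2]
  }
  w
}

#' Mixing entropy of a fuzzy expression state
#'
#' `S(s) = -sum_i [s_i log s_i + (1-s_i) log(1-s_i)]` (natural logarithm),
#' with the continuous extension 0 log 0 = 0 so corners have zero entropy.
#'
#' @param s Numeric vector in `[0, 1]`.
#' @return Entropy value (>= 0).
#' @export
entropy <- function(s) {
  if (any(s < 0 | s > 1)) stop("coordinates must lie in [0, 1]")
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  -sum(xlx(s) + xlx(1 - s))
}

#' Free energy of a fuzzy expression state
#'
#' `F(s) = E(s) - temperature * S(s)`. Stationary points satisfy
#' `s_i = logistic(-dE/ds_i / temperature)`, i.e. the model generates
#' sigmoid gain functions.
#'
#' @param omega Coefficient vector.
#' @param s Numeric vector in `[0, 1]`.
#' @param temperature Non-negative scalar.
#' @return Free energy value.
#' @export
free_energy <- function(omega, s, temperature) {
  if (temperature < 0) stop("temperature must be >= 0")
  energy_continuous(omega, s) - temperature * entropy(s)
}

#' Export multilinear coefficients as TSV
#'
#' Columns `subset_mask` (bit mask of the monomial's genes) and
#' `coefficient`.
#'
#' @param omega Coefficient vector.
#' @param path Output path.
#' @export
write_omega <- function(omega, path) {
  utils::write.table(
    data.frame(subset_mask = seq_along(omega) - 1L, coefficient = omega),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
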