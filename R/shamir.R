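# ---- prime-field arithmetic ---------------------------------------------
#
# Field modulus chosen so that products of two residues stay below 2^53 and
# remain exact in double-precision arithmetic.

SHAMIR_PRIME <- 94906249

fld_mul <- function(a, b, p = SHAMIR_PRIME) (a * b) %% p
fld_add <- function(a, b, p = SHAMIR_PRIME) (a + b) %% p
fld_sub <- function(a, b, p = SHAMIR_PRIME) ((a - b) %% p + p) %% p

# modular inverse via extended Euclid
fld_inv <- function(a, p = SHAMIR_PRIME) {
  a <- a %% p
  if (a == 0) stop("no inverse of 0 in the field")
  old_r <- a; r <- p
  old_s <- 1; s <- 0
  while (r != 0) {
    q <- old_r %/% r
    tmp <- old_r - q * r; old_r <- r; r <- tmp
    tmp <- old_s - q * s; old_s <- s; s <- tmp
  }
  ((old_s %% p) + p) %% p
}

fld_poly_eval <- function(coefs, x, p = SHAMIR_PRIME) {
  # Horner; coefs[1] is the constant term (the secret)
  acc <- 0
  for (c in rev(coefs)) acc <- fld_add(fld_mul(acc, x, p), c, p)
  acc
}

# ---- scheme and shares --------------------------------------------------

#' Define a Shamir threshold scheme
#'
#' `K` of `N` key keepers must cooperate to reconstruct a secret. Per the
#' marketplace's Byzantine fault-tolerance assumption the threshold must
#' satisfy `K > round(N/3)` (and `1 <= K <= N`).
#'
#' @param n_keepers Number of keepers N (>= 1).
#' @param threshold Threshold K; default the minimal admissible value
#'   `round(N/3) + 1`.
#' @param prime Field modulus (a prime whose square fits in a double).
#' @return A list of class `lp_shamir_scheme`.
#' @export
shamir_scheme <- function(n_keepers, threshold = NULL, prime = SHAMIR_PRIME) {
  n_keepers <- as.integer(n_keepers)
  if (is.na(n_keepers) || n_keepers < 1L) stop("n_keepers must be >= 1")
  if (is.null(threshold)) threshold <- as.integer(round(n_keepers / 3)) + 1L
  threshold <- as.integer(threshold)
  if (threshold < 1L || threshold > n_keepers) {
    stop("threshold K must satisfy 1 <= K <= N")
  }
  if (threshold <= round(n_keepers / 3)) {
    stop("threshold K = ", threshold, " violates the fault-tolerance bound ",
         "K > round(N/3) = ", round(n_keepers / 3))
  }
  structure(list(n_keepers = n_keepers, threshold = threshold, prime = prime),
            class = "lp_shamir_scheme")
}

#' Split a secret into N Shamir shares
#'
#' Samples a uniformly random polynomial of degree `K - 1` over the prime
#' field with the secret as constant term and evaluates it at
#' `x = 1, ..., N`. Any `K` shares reconstruct the secret exactly by
#' Lagrange interpolation at 0; fewer reveal nothing about it. Shares carry
#' a random split id so shares of different splits cannot be silently mixed.
#'
#' Uses R's RNG: seed the session (or pass a seeded state) for determinism.
#'
#' @param secret Integer in `[0, prime)`.
#' @param scheme An [shamir_scheme()].
#' @return List of `N` shares, each `list(x, y, split_id, threshold, prime)`.
#' @export
split_secret <- function(secret, scheme) {
  stopifnot(inherits(scheme, "lp_shamir_scheme"))
  p <- scheme$prime
  secret <- as.numeric(secret)
  if (is.na(secret) || secret < 0 || secret >= p || secret != floor(secret)) {
    stop("secret must be an integer in [0, ", p, ")")
  }
  k <- scheme$threshold
  coefs <- c(secret, if (k > 1L) floor(stats::runif(k - 1L, 0, p)))
  split_id <- sha256_hex(paste0("split:", paste(floor(stats::runif(4, 0, 2^31)),
                                                collapse = ":")))
  lapply(seq_len(scheme$n_keepers), function(x) {
    list(x = x, y = fld_poly_eval(coefs, x, p), split_id = split_id,
         threshold = k, prime = p)
  })
}

#' Reconstruct a Shamir secret from shares
#'
#' Lagrange interpolation at 0 over the prime field. Refuses with fewer than
#' `K` shares, on duplicated share points, or when shares from different
#' splits are mixed (detected via the embedded split id).
#'
#' @param shares A list of at least `K` shares from one [split_secret()] call.
#' @return The secret (numeric integer in `[0, prime)`).
#' @export
reconstruct_secret <- function(shares) {
  if (length(shares) == 0L) stop("no shares given")
  k <- shares[[1L]]$threshold
  p <- shares[[1L]]$prime
  ids <- vapply(shares, function(s) s$split_id, character(1))
  if (length(unique(ids)) != 1L) {
    stop("shares come from different splits (split id mismatch)")
  }
  if (length(shares) < k) {
    stop("threshold error: ", length(shares), " share(s) given but K = ", k,
         " required")
  }
  shares <- shares[seq_len(k)]
  xs <- vapply(shares, function(s) s$x, numeric(1))
  if (anyDuplicated(xs)) stop("duplicate share points")
  ys <- vapply(shares, function(s) s$y, numeric(1))
  acc <- 0
  for (i in seq_len(k)) {
    num <- 1; den <- 1
    for (j in seq_len(k)) {
      if (i == j) next
      num <- fld_mul(num, fld_sub(0, xs[j], p), p)
      den <- fld_mul(den, fld_sub(xs[i], xs[j], p), p)
    }
    li <- fld_mul(num, fld_inv(den, p), p)
    acc <- fld_add(acc, fld_mul(ys[i], li, p), p)
  }
  acc
}
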