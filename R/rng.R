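#' Derive a child seed from a master seed
#'
#' Every stochastic function in the package consumes exactly one integer
#' seed. Multi-stream computations (replicate panels, bootstrap draws,
#' optimizer restarts) derive their per-stream seeds with this splitter so
#' that stream `k` of a run is reproducible in isolation from the master
#' seed alone. The scheme is a Lehmer-style map on the Mersenne prime
#' modulus 2^31 - 1:
#' `child = (master * 48271 + k) mod (2^31 - 1)`, mapped away from 0.
#'
#' All arithmetic stays below 2^53 so the map is exact in double precision.
#'
#' @param master Integer master seed (any finite number; reduced mod 2^31-1).
#' @param k Non-negative integer stream index (vectorised).
#' @return Integer vector of child seeds in `[1, 2^31 - 2]`.
#' @examples
#' child_seed(42, 0:4)
#' @export
child_seed <- function(master, k) {
  m <- 2147483647
  if (!is.numeric(master) || length(master) != 1 || !is.finite(master)) {
    abort("`master` must be a single finite number", class = "rumidyn_invalid_seed")
  }
  s <- ((master %% m) * 48271 + (k %% m)) %% m
  as.integer(ifelse(s == 0, 1, s))
}
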