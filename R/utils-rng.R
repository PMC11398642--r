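# Counter-based seeding utilities.
#
# Every Gibbs block of every cycle of every chain reseeds R's RNG from a hash
# of (run seed, chain index, cycle, block id).  Chains therefore consume
# disjoint, reproducible random streams regardless of scheduling, so parallel
# and sequential execution of the same configuration are bit-identical.

# exact 32-bit modular arithmetic on doubles (doubles hold integers < 2^53)
.mod32 <- function(x) x %% 4294967296

.mul32 <- function(a, b) {
  # (a * b) mod 2^32, exact for 0 <= a, b < 2^32
  a1 <- a %/% 65536
  a0 <- a %% 65536
  .mod32(a0 * b + .mod32(a1 * b) %% 65536 * 65536)
}

.xor32 <- function(a, b) {
  # bitwXor on values possibly >= 2^31: split into 16-bit halves
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

.mix32 <- function(x) {
  # murmur3-style finalizer
  x <- .mod32(x)
  x <- .xor32(x, x %/% 65536)
  x <- .mul32(x, 2246822507)
  x <- .xor32(x, x %/% 8192)
  x <- .mul32(x, 3266489909)
  x <- .xor32(x, x %/% 65536)
  x
}

#' Deterministic per-block seed
#'
#' Hashes \code{(seed, chain, cycle, block)} into a positive 31-bit integer
#' suitable for \code{set.seed}.  Used internally so that every Gibbs block
#' draws from its own reproducible stream.
#'
#' @param seed integer run seed.
#' @param chain zero-based chain index.
#' @param cycle cycle counter (0 = initialization).
#' @param block integer block id within the cycle.
#' @return a single integer in \code{[1, 2^31 - 2]}.
#' @keywords internal
block_seed <- function(seed, chain, cycle, block) {
  h <- .mix32(.mod32(seed))
  h <- .mix32(.xor32(h, .mod32(chain * 2654435761)))
  h <- .mix32(.xor32(h, .mod32(cycle * 2246822519)))
  h <- .mix32(.xor32(h, .mod32(block * 3266489917)))
  as.integer(h %% 2147483645 + 1)
}

.seed_block <- function(state, block) {
  set.seed(block_seed(state$seed, state$chain_index, state$cycle, block))
}
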