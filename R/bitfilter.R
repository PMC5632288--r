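# Constant-time, constant-space probabilistic record of visited models.
#
# Every candidate variable gets a fixed 32-bit hash (MurmurHash3 of its
# index under a seed), precomputed at filter construction. A model's hash
# is the XOR of its members' hashes (empty model = 0), so moving from a
# model to a one-variable neighbour updates the hash with a single XOR.
# The hash plus the model size address one bit in a fixed 64 x 65,326 bit
# table (522,608 bytes): column = (hash mod 2^16) mod 65,326; row = hash
# bits 20-21 (0-based) as the high 2 bits joined with (size mod 16) as the
# low 4 bits. Mapping different sizes to different rows prevents the
# systematic collisions XOR folding would otherwise cause. Bits are never
# cleared, so a model once recorded is never reported unseen (no false
# negatives); aliased bits can report an unvisited model as seen, an error
# the windowed search tolerates by design.
#
# 32-bit arithmetic is done on doubles in [0, 2^32) — exact, since all
# intermediates stay below 2^53.

TWO32 <- 4294967296

mul32 <- function(a, b) {
  (((a %/% 65536 * b) %% 65536) * 65536 + (a %% 65536) * b) %% TWO32
}

xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

rotl32 <- function(x, r) {
  ((x * 2^r) %% TWO32) + x %/% 2^(32 - r)
}

# MurmurHash3 x86_32 of a single 4-byte block (the variable index).
murmur3_32 <- function(key, seed) {
  k <- mul32(key, 3432918353)           # 0xcc9e2d51
  k <- rotl32(k, 15)
  k <- mul32(k, 461845907)              # 0x1b873593
  h <- xor32(seed %% TWO32, k)
  h <- rotl32(h, 13)
  h <- (mul32(h, 5) + 3864292196) %% TWO32   # 0xe6546b64
  h <- xor32(h, 4)                      # length in bytes
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2246822507)             # 0x85ebca6b
  h <- xor32(h, h %/% 8192)             # >> 13
  h <- mul32(h, 3266489909)             # 0xc2b2ae35
  xor32(h, h %/% 65536)
}

FILTER_ROWS <- 64L
FILTER_COLS <- 65326L
FILTER_BYTES <- FILTER_ROWS * FILTER_COLS / 8L   # 522,608

#' Create a model bit filter
#'
#' Allocates the zeroed 64 x 65,326 bit table and precomputes the 32-bit
#' hash code of every candidate variable. The filter is a mutable
#' environment: [filter_test_and_set()] records models in place.
#'
#' @param num_vars Number of candidate variables (>= 1).
#' @param seed Integer hash seed; the variable hashes are a pure function
#'   of `(variable index, seed)`.
#' @return An object of class `bit_filter`.
#' @export
init_filter <- function(num_vars, seed) {
  stopifnot(num_vars >= 1L)
  f <- new.env(parent = emptyenv())
  f$table <- raw(FILTER_BYTES)
  f$var_hash <- murmur3_32(as.numeric(seq_len(num_vars)),
                           as.numeric(seed) %% TWO32)
  f$seed <- as.integer(seed)
  class(f) <- "bit_filter"
  f
}

#' Update a model hash by one variable
#'
#' XORs the variable's precomputed hash into the previous model hash; since
#' XOR is an involution the same call adds or removes the variable. The
#' empty model hashes to 0.
#'
#' @param prev_hash Previous model hash (32-bit value as a double).
#' @param var_hash_j The variable's hash code (`filter$var_hash[j]`).
#' @return The new 32-bit model hash.
#' @export
update_hash <- function(prev_hash, var_hash_j) {
  xor32(prev_hash, var_hash_j)
}

# XOR-fold a member set's hashes from the empty model.
model_hash <- function(filter, members) {
  h <- 0
  for (j in members) h <- xor32(h, filter$var_hash[j])
  h
}

#' Query and record a model in the bit filter
#'
#' Maps `(model_hash, model_size)` to one bit of the table, returns whether
#' that bit was already set, and sets it. A `TRUE` return means the model
#' is treated as already evaluated.
#'
#' @param filter A [init_filter()] object.
#' @param model_hash 32-bit model hash (see [update_hash()]).
#' @param model_size Number of variables in the model.
#' @return Logical: was the model's bit already set?
#' @export
filter_test_and_set <- function(filter, model_hash, model_size) {
  col <- (model_hash %% 65536) %% FILTER_COLS
  row <- ((model_hash %/% 1048576) %% 4) * 16 + (model_size %% 16)
  bit <- row * FILTER_COLS + col
  byte_i <- bit %/% 8 + 1
  mask <- 2^(bit %% 8)
  prev <- as.integer(filter$table[byte_i])
  seen <- (prev %/% mask) %% 2 == 1
  if (!seen) filter$table[byte_i] <- as.raw(prev + mask)
  seen
}

# Exact-set dedupe with the same surface as the bit filter, used for the
# oracle-equivalence mode of the search (dedupe = "exact").
init_exact_filter <- function(num_vars, seed) {
  f <- init_filter(num_vars, seed)
  f$keys <- new.env(parent = emptyenv())
  class(f) <- c("exact_filter", "bit_filter")
  f
}

exact_test_and_set <- function(filter, members) {
  key <- paste0("m:", paste(sort(members), collapse = ","))
  seen <- !is.null(filter$keys[[key]])
  if (!seen) filter$keys[[key]] <- TRUE
  seen
}
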