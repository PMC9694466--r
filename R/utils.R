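# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific seed from a master seed
#'
#' A counter-based splitting scheme: every stochastic stage draws its own
#' 31-bit seed from the master seed and a stage label, so stages can be
#' regenerated independently without consuming each other's random streams.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage (e.g. "hidden", "noise").
#' @return an integer seed in [1, 2^31 - 2].
#' @export
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 7919 + 12345) %% 2147483646 + 1)
}

# consistent error helper
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# squared-distance matrix between two coordinate matrices (rows = points)
.cross_dist <- function(a, b) {
  a2 <- rowSums(a * a); b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# frame accessor: n_atoms x 3 matrix for frame i
.frame <- function(traj, i) traj$coords[i, , , drop = TRUE]

# polynomial rolling hash of a character scalar, for run manifests
.text_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(paste(x, collapse = "\n")))
    h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}
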