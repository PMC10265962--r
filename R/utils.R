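## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible integer sub-seed from a master seed and labels
#'
#' A polynomial rolling hash over the master seed and an arbitrary sequence
#' of labels, reduced modulo a Mersenne-adjacent prime below 2^31.  Used to
#' give every independent source of randomness (participant, session, block,
#' simulation replicate) its own stream without consuming the global RNG.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return a positive integer strictly below 2^31.
#' @keywords internal
deriveSeed <- function(seed, ...) {
  s <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
             collapse = "\x1f")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483587
  as.integer(h + 1L)
}

## Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Moore-Penrose pseudoinverse by SVD; tolerance relative to the largest
## singular value (1e-10 by default, per the estimator's numerical contract).
pinv <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Projector onto the column space of contrast matrix C (conditions x q).
contrastProjector <- function(C) {
  C <- as.matrix(C)
  C %*% pinv(crossprod(C)) %*% t(C)
}

## Symmetric Hann window of length n (n >= 1), positive interior weights.
hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

## Short hexadecimal content hash for configs/reports (rolling polynomial).
contentHash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, give.attr = FALSE)),
             collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483587
  sprintf("%08x", as.integer(h))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
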