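#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed Integer seed (`NULL` leaves the RNG untouched).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a stage-specific 31-bit seed from a global seed
#'
#' Decouples the random streams of pipeline stages: each (seed, label, index)
#' triple maps to a fixed integer via an MD5 hash, so adding a stage never
#' shifts another stage's stream.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @param index Optional integer (e.g. repeat number).
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, label, index = 0L) {
  key <- sprintf("%d|%s|%d", as.integer(seed), label, as.integer(index))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(key, tmp)
  h <- substr(unname(tools::md5sum(tmp)), 1, 7)
  (strtoi(h, 16L) %% .Machine$integer.max) + 1L
}

#' @keywords internal
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' @keywords internal
assert_square_symmetric <- function(D, name = "D") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop(name, " must be square")
  if (max(abs(D - t(D))) > 1e-8) stop(name, " must be symmetric")
  D
}
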