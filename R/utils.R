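#' Derive a stage-specific seed from a global seed
#'
#' Stage seeds are a deterministic function of the global seed and a stage
#' label, so that toggling one pipeline stage never changes the random draws
#' seen by another. The hash stays below 2^31 so it is always a valid R seed.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage.
#' @return A single integer in [1, 2^31 - 2].
#' @export
#' @examples
#' stageSeed(1L, "diffexp")
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; doubles stay exact below 2^53
  h <- abs(as.numeric(seed)) %% m
  for (cc in utf8ToInt(stage)) {
    h <- (h * 131 + cc) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# INFO-style filter logging: every drop reports a count, as the pipeline's
# narrative of record.
logCounts <- function(what, n_in, n_out) {
  if (n_in != n_out) {
    message(sprintf("[pcsfCompare] %s: %d in, %d kept, %d dropped",
                    what, n_in, n_out, n_in - n_out))
  }
  invisible(NULL)
}

stopConfig <- function(...) stop(sprintf(...), call. = FALSE)

# Shared adjusted Rand index (chance-corrected partition agreement) used by
# recovery diagnostics; mclust provides the reference implementation when
# available, otherwise the closed form over the contingency table is used.
ariIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_ <- si * sj / choose(n, 2)
  max_ <- (si + sj) / 2
  if (max_ == exp_) return(1)
  (sij - exp_) / (max_ - exp_)
}
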