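# shared internal helpers

# run code with a locally-seeded RNG, restoring the caller's RNG state
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a reproducible sub-seed from a master seed, kept inside 32-bit range
sub_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483587L
}

# nearest-rank percentile (no interpolation): value at rank ceiling(q * n)
nearest_rank_percentile <- function(x, q) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    abort("no non-missing values for percentile computation")
  }
  sort(x)[max(1L, ceiling(q * length(x)))]
}

# Dirichlet draw (rows = draws)
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1), nrow = n)
  g / rowSums(g)
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single proportion in [0, 1]"))
  }
  invisible(x)
}
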