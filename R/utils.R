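# Internal helpers: error signalling, seed plumbing, small validators.

stop_wgseg <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "wgseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
validation_error <- function(msg, field = NULL) {
  stop_wgseg(msg, "wgseg_validation_error", field = field)
}

io_error <- function(msg, path = NULL) {
  stop_wgseg(msg, "wgseg_io_error", path = path)
}

format_error <- function(msg, path = NULL) {
  stop_wgseg(msg, "wgseg_format_error", path = path)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(sprintf("'%s' must be a single finite number", name),
                     field = name)
  if (integer && x != round(x))
    validation_error(sprintf("'%s' must be an integer", name), field = name)
  if (x < lower || (strict_lower && x == lower) || x > upper)
    validation_error(sprintf("'%s' = %g is outside the allowed range", name, x),
                     field = name)
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a global seed
#'
#' Every source of randomness in the package draws from its own stream whose
#' seed is a deterministic 31-bit hash of the global seed, a module tag, and
#' an index (FNV-1a over the tag bytes, folded with the seed and index).
#' This keeps independent stages (phantom rendering, dataset jitter,
#' augmentation, weight init, training batches, noise) decoupled: changing
#' how many draws one stage makes never shifts another stage's stream.
#'
#' @param seed Integer global seed.
#' @param tag Character scope tag, e.g. `"phantom"`.
#' @param index Integer stream index within the scope (default 0).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag, index = 0L) {
  check_number(seed, "seed", integer = TRUE)
  check_number(index, "index", integer = TRUE)
  # FNV-1a over the tag characters, in double arithmetic mod 2^31 - 1
  # (doubles hold integers exactly below 2^53, so no overflow here).
  m <- 2147483647 # 2^31 - 1, prime
  h <- 2166136261 %% m
  for (b in utf8ToInt(tag)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% m
  }
  # fold in seed and index, then two Lehmer rounds to mix; all products
  # stay below 2^53 so double arithmetic is exact
  h <- (h * 31 + (as.numeric(seed) %% m)) %% m
  h <- (h * 48271) %% m # mix the seed in before adding the index
  h <- (h + as.numeric(index) %% m + 1) %% m
  h <- (h * 48271) %% m
  h <- (h * 48271) %% m
  as.integer(h)
}

# clip to [0,1]
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 1
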