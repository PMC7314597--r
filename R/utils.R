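#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Streams of randomness inside the pipeline (per-rep CV splits, per-pair
#' bootstrap draws, per-rep retrains) each get their own seed derived
#' deterministically from the master seed and a label, so stages stay
#' reproducible and independent of evaluation order.
#'
#' @param seed integer master seed.
#' @param ... labels (strings or integers) identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double-integer range
  h <- as.double(seed) %% m
  for (part in list(...)) {
    for (tok in utf8ToInt(paste0("/", paste(as.character(part), collapse = ",")))) {
      h <- (h * 31 + tok) %% m
    }
  }
  as.integer(h)
}

# 32-bit polynomial rolling hash of a character scalar; used to fingerprint
# configs in pipeline manifests without external digest dependencies.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(x)) {
    h <- (h * 31 + b) %% 2147483647 # exact in doubles: 31 * h < 2^53
  }
  sprintf("%08x", as.integer(h))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Nearest-rank empirical percentile (type 1); reproducible across platforms.
nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1L, all(p >= 0 & p <= 1))
  s <- sort(x)
  idx <- pmax(1L, ceiling(p * length(s)))
  s[idx]
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
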