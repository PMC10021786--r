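# Shared numeric helpers: percentile convention, seed substreams, config hash.

#' Percentile with the package-wide convention
#'
#' All uncertainty ranges and distribution summaries in povbench use the
#' inclusive linear-interpolation percentile (R's `quantile()` type 7), so
#' reported bounds are bit-reproducible across modules.
#'
#' @param x Numeric vector.
#' @param probs Probabilities in \[0, 1\].
#' @return Numeric vector of percentiles, unnamed.
#' @export
pb_percentile <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

# Derive a deterministic substream seed from a master seed and a stream label,
# so that adding a stream (panel, spl, noise, draws...) never perturbs the
# others. Kept below 2^31 - 1 to stay a valid R integer seed.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- fnv1a32(paste0("povbench:", stream))
  as.integer((abs(seed) + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a hash of a character scalar, in double arithmetic split into
# 16-bit halves to avoid overflow. Used only as a provenance stamp in run
# manifests (not cryptographic).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor64(h, b)
    # multiply modulo 2^32 via 16-bit split
    hi <- floor(h / 65536)
    lo <- h - hi * 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  h
}

# xor for doubles holding 32-bit unsigned values
bitwXor64 <- function(a, b) {
  ah <- floor(a / 2147483648); al <- a - ah * 2147483648
  bh <- floor(b / 2147483648); bl <- b - bh * 2147483648
  xh <- if (ah == bh) 0 else 1
  xh * 2147483648 + bitwXor(as.integer(al), as.integer(bl))
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  h <- fnv1a32(as.character(json))
  paste0(format(as.hexmode(floor(h / 65536)), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
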