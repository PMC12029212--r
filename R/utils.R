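# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit sub-seed from a parent seed and a label, so that
# per-entity streams (replicate, nucleus, cell type) are stable under
# reordering. Plain polynomial string hash; not cryptographic.
sub_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647L
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# 0-based bin index (1-based R index) of the bin containing position `pos`
# for a given bin size; positions are 0-based.
pos_to_bin <- function(pos, bin_size) floor(pos / bin_size) + 1L

# midpoints (bp, 0-based) of bins 1..n
bin_midpoints <- function(n, bin_size) (seq_len(n) - 0.5) * bin_size

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(sprintf("`%s` must be a single finite number", name))
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop2(sprintf("`%s` = %g is out of range", name, x))
  invisible(x)
}
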