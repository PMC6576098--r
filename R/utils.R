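# Shared helpers: rounding, validation, seeded sub-streams.

#' Round half away from zero
#'
#' Base [round()] rounds half to even; genotyping reports conventionally
#' print percentages rounded half-up, so the accounting functions use this
#' variant throughout.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count pair, rounded as printed in genotyping reports
#'
#' @param num numerator count(s).
#' @param den denominator count(s); `NA` is returned where `den == 0`.
#' @param digits decimal places (default one, the usual report format).
#' @return numeric percentage vector.
#' @export
pct <- function(num, den, digits = 1) {
  n <- max(length(num), length(den))
  nm <- if (length(num) == n) names(num) else NULL
  num <- rep_len(num, n); den <- rep_len(den, n)
  names(num) <- nm
  out <- rep_len(NA_real_, n)
  ok <- !is.na(den) & den > 0
  out[ok] <- round_half_up(100 * num[ok] / den[ok], digits)
  names(out) <- names(num)
  out
}

# Validate a dosage matrix: loci in rows, samples in columns, calls coded
# 0/1/2 with NA for missing.
check_dosage <- function(g, arg = "genotypes") {
  if (!is.matrix(g)) {
    stop(sprintf("`%s` must be a matrix (loci x samples)", arg), call. = FALSE)
  }
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop(sprintf("`%s` must contain dosages 0, 1, 2 or NA", arg), call. = FALSE)
  }
  invisible(g)
}

# Deterministic 31-bit seed for a keyed random sub-stream.  Keying by
# (seed, run, sample id) means adding samples or runs never perturbs
# existing draws.
substream_seed <- function(seed, run, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647L
  as.integer((seed + 1299709 * run + h) %% 2147483647L)
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring
# the caller's stream afterwards.
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
  set.seed(seed)
  expr
}
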