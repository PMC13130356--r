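#' Weighted median
#'
#' Median of `x` under positive weights `w`, defined through the weighted
#' cumulative distribution: the smallest order statistic whose cumulative
#' weight reaches half the total.  When the cumulative weight hits exactly
#' half the total at an order statistic, the median is the midpoint of that
#' value and the next one, so with equal weights the usual even-n sample
#' median is recovered.
#'
#' @param x numeric vector.
#' @param w positive weights, recycled to `length(x)`; default equal weights.
#' @param na.rm drop missing values in `x` first.
#' @return scalar weighted median.
#' @examples
#' weighted_median(c(1, 2, 3, 4))            # 2.5
#' weighted_median(c(1, 10), w = c(3, 1))    # 1
#' @export
weighted_median <- function(x, w = NULL, na.rm = TRUE) {
  if (is.null(w)) w <- rep(1, length(x))
  w <- rep_len(w, length(x))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  if (length(x) == 0L) stop("no non-missing values")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  half <- cw[length(cw)] / 2
  i <- which(cw >= half - 1e-9 * half)[1]
  # cumulative weight exactly half (to relative tolerance): split the median
  if (abs(cw[i] - half) <= 1e-9 * half && i < length(x)) {
    (x[i] + x[i + 1]) / 2
  } else {
    x[i]
  }
}

# Deterministic sub-seed for a named pseudorandom stream, derived from the
# cohort seed.  Keeps column-level reproducibility when unrelated parts of a
# config change: each generation step re-seeds from its own stream.
substream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(seed) * 48271 + h * 1009) %% 2147483629)
}

# run `expr` under a purpose-keyed substream without disturbing the caller's
# RNG state
with_substream <- function(seed, purpose, expr) {
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
  set.seed(substream_seed(seed, purpose))
  expr
}

# shared validation helper
stop_if_missing_cols <- function(data, cols, what = "cohort") {
  absent <- setdiff(cols, names(data))
  if (length(absent)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(absent, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
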