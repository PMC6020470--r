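# Shared low-level helpers: alphabet encoding and log-space arithmetic.

DNA_BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integers
#'
#' A,C,G,T -> 1..4; '-' and '.' -> 0 (gap); 'N' (or any other IUPAC
#' ambiguity) -> 5. Input is uppercased first.
#'
#' @param x a single character string
#' @return integer vector, one element per character
#' @keywords internal
seq_to_int <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- match(ch, DNA_BASES)
  out[ch %in% c("-", ".")] <- 0L
  out[is.na(out)] <- 5L
  out
}

#' Decode an integer vector back to a DNA string
#' @param v integer vector over 0..5
#' @return character string
#' @keywords internal
int_to_seq <- function(v) {
  chr <- c("-", DNA_BASES, "N")[v + 1L]
  paste(chr, collapse = "")
}

#' Numerically safe log(sum(exp(x)))
#' @param x numeric vector (may contain -Inf)
#' @return scalar
#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise log-sum-exp of a matrix (returns a vector, one per column).
# Specialized for the ubiquitous 4-row (one per base) case.
col_log_sum_exp <- function(m) {
  mx <- if (nrow(m) == 4L) pmax(m[1L, ], m[2L, ], m[3L, ], m[4L, ])
        else apply(m, 2L, max)
  ok <- is.finite(mx)
  out <- mx
  if (all(ok)) {
    out <- mx + log(colSums(exp(m - rep(mx, each = nrow(m)))))
  } else if (any(ok)) {
    sw <- sweep(m[, ok, drop = FALSE], 2L, mx[ok], "-")
    out[ok] <- mx[ok] + log(colSums(exp(sw)))
  }
  out
}

# %||% as used throughout the tidyverse
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hp <- function(...) stop(sprintf(...), call. = FALSE)
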