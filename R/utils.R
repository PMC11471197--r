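`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of plain character sequences
#'
#' Vectorised reverse complement over `A/C/G/T/N` (case-insensitive,
#' `N` maps to `N`).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Apportion counts by largest-remainder rounding
#'
#' Splits `n` into integer parts proportional to `props` so the parts sum to
#' `n` exactly: floors first, then remaining units go to the largest
#' fractional remainders (ties broken by position).
#'
#' @param n total count.
#' @param props numeric vector of proportions summing to 1 (within 1e-9).
#' @return integer vector, same names as `props`, summing to `n`.
#' @export
largest_remainder <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0))
  if (abs(sum(props) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", sum(props), ")")
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    rem <- raw - base
    add <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# Percentage at one decimal, rounding half away from zero (so 11/12 -> 91.7).
pct_1dp <- function(x) {
  sign(x) * floor(abs(x) * 1000 + 0.5) / 10
}

#' Benjamini-Hochberg adjusted p-values (step-up)
#'
#' In-package step-up implementation of the Benjamini-Hochberg false
#' discovery rate adjustment (kept separate from [stats::p.adjust()] so the
#' two can be cross-checked).
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA` allowed.
#' @return numeric vector of adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pv[o] * m / (m - seq_len(m) + 1L)))[ro]
  out[ok] <- q
  out
}

# Deterministic condition classes used for the CLI exit-code contract.
cs_config_error <- function(msg) {
  structure(class = c("cs_config_error", "error", "condition"),
            list(message = msg, call = NULL))
}

cs_stop_config <- function(...) stop(cs_config_error(paste0(...)))
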