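# internal helpers shared across modules

geo_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# competition ("1224") ranking: ties share the smallest rank
competition_rank <- function(x) as.integer(rank(x, ties.method = "min"))

# sample SD with a switchable denominator; "n-1" is the package-wide default
ct_sd <- function(x, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  s2 <- stats::var(x)
  if (denom == "n") s2 <- s2 * (length(x) - 1) / length(x)
  sqrt(s2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# full-precision numeric rendering so TSV round-trips are bitwise exact
num_chr <- function(x) {
  vapply(x, function(v) formatC(v, digits = 17, format = "g"), character(1))
}
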