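## deterministic 32-bit stream id from a tuple of small integers (Lehmer-style
## Horner hash mod 2^31-1; exact in doubles since h*48271 < 2^53)
.mix <- function(...) {
  h <- 0
  for (x in c(...)) h <- (h * 48271 + as.numeric(x) + 1) %% 2147483647
  as.integer(h)
}

## separable Gaussian blur with edge renormalization; sigma in pixels
.gaussianBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  band <- function(n) {
    w <- outer(seq_len(n), seq_len(n),
               function(i, j) stats::dnorm(j - i, sd = sigma))
    w / rowSums(w)
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

## stable per-record key used for file names, colnames and ordering
.recordKey <- function(d) {
  sprintf("%s_%s_%s_v%d", d$subject_id, d$muscle_group, d$side,
          as.integer(d$view_index))
}

.entityKey <- function(d, grouping = c("muscle", "subject")) {
  grouping <- match.arg(grouping)
  if (grouping == "subject") as.character(d$subject_id)
  else paste(d$subject_id, d$muscle_group, d$side, sep = "|")
}
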