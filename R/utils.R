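# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

# complement of plus-strand bases, vectorized over character vectors
compBase <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

revComp <- function(x) {
  vapply(x, function(s) {
    paste(rev(compBase(strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# substitution type label, e.g. "A>G"
subType <- function(ref, alt) paste0(ref, ">", alt)

# seed derivation: keep all derived seeds valid 32-bit integers
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}
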