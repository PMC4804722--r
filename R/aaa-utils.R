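DNA_BASES <- c("A", "C", "G", "T")

# data.frame constructor without the validation overhead of data.frame();
# used on hot scanning paths where thousands of small frames are built
.fast_df <- function(...) {
  cols <- list(...)
  n <- if (length(cols)) length(cols[[1L]]) else 0L
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}

.EMPTY_HITS <- .fast_df(pwm_id = character(0), seq_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), score = numeric(0))
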