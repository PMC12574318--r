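## small shared helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

## deterministic sub-seed per generator name so adding generators never
## perturbs existing fixtures; kept below 2^31
.seedFor <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

.isGzFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}
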