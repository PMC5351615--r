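# shared internal helpers

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 31-bit string hash (djb2 variant); used for config hashes so
# reruns can prove "same inputs, same thresholds" without external deps
str_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

file_hash <- function(path) {
  if (!file.exists(path)) return("absent")
  str_hash(rawToChar(readBin(path, "raw", file.info(path)$size)))
}

#' @keywords internal
.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# TSV writer with '#'-prefixed metadata header lines
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
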