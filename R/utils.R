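# full-precision number formatting for reproducible plain-text serialization
format_full <- function(x) formatC(x, format = "g", digits = 17)

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tsv_file <- function(path, ...) {
  if (!file.exists(path)) stop("cannot read input file: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic short hash of a config list, for run logs
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

log_run <- function(cmd, config, seed = NULL, verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  message(sprintf("[supercoilr %s] %s seed=%s config=%s",
                  as.character(utils::packageVersion("supercoilr")),
                  cmd, seed %||% "none", config_hash(config)))
  invisible(NULL)
}
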