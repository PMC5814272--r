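# Internal helpers shared across modules.

#' @importFrom stats sd quantile rnorm rpois rexp runif rbinom pnorm pt
#'   pchisq dhyper complete.cases setNames
#' @importFrom utils read.delim write.table head
NULL

# Run code with a private RNG state; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# Open a text connection, transparently handling .gz paths (gzfile also
# reads plain text, so it is used for reading unconditionally).
open_read <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  gzfile(path, open = "rt", encoding = "UTF-8")
}

open_write <- function(path) {
  if (grepl("\\.gz$", path)) {
    gzfile(path, open = "wt", encoding = "UTF-8")
  } else {
    file(path, open = "wt", encoding = "UTF-8")
  }
}

read_lines_any <- function(path) {
  con <- open_read(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

write_lines_any <- function(lines, path) {
  con <- open_write(path)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Stop with a classed condition so callers/tests can discriminate error kinds.
stop_fmt <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "neoimmune_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

format_error <- function(fmt, ...) stop_fmt("neoimmune_format_error", fmt, ...)
record_error <- function(fmt, ...) stop_fmt("neoimmune_record_error", fmt, ...)
config_error <- function(fmt, ...) stop_fmt("neoimmune_config_error", fmt, ...)
data_error   <- function(fmt, ...) stop_fmt("neoimmune_data_error", fmt, ...)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Significance stars used as a presentation column in all tidy outputs.
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# Deterministic TSV writer (fixed col ordering, no quoting surprises).
write_tsv <- function(df, path) {
  con <- open_write(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  con <- open_read(path)
  on.exit(close(con))
  read.delim(con, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
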