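# Internal helpers: logging, atomic file output, RNG scoping.

.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' Messages below the chosen level are suppressed. All logging goes to
#' `stderr`; quantitative results are always written to files, never only
#' logged.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
gcan_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- .log_env$level
  .log_env$level <- level
  invisible(old)
}

gcan_log <- function(level, fmt, ...) {
  if (.log_levels[[level]] < .log_levels[[.log_env$level]]) return(invisible())
  msg <- sprintf(fmt, ...)
  message(sprintf("[gcan %s] %s", level, msg))
  invisible()
}

#' Write a file atomically
#'
#' Writes via a temporary file in the destination directory followed by a
#' rename, so an interrupted run never leaves a truncated artifact.
#'
#' @param writer function of one argument (a path) that writes the content.
#' @param path final destination path.
#' @return `path`, invisibly.
#' @keywords internal
atomic_write <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".gcan_tmp_", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    # cross-device fallback
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls do not perturb user sessions.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream label, staying inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) * 2654435761 + sum(utf8ToInt(as.character(stream)))) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
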