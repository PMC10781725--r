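#' @keywords internal
"_PACKAGE"

# p-values are clamped before any log so Fisher statistics stay finite
P_CLAMP_LO <- 1e-300

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp_p <- function(p) pmin(pmax(p, P_CLAMP_LO), 1)

#' Derive a reproducible child seed for an independent random stream
#'
#' Stream-split seeding: each (purpose, index) pair gets its own child seed so
#' that, for example, adding a study to a simulated database never shifts the
#' data of earlier studies.  The derivation is a small deterministic integer
#' hash kept below 2^31 - 1.
#'
#' @param seed parent integer seed.
#' @param ... integers or character scalars identifying the stream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    }
    h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Stable short hash of a configuration list, for output provenance headers.
config_hash <- function(cfg) {
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
               collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) {
    stopf("%s must be a single probability in %s, got %s",
          name, if (open) "(0,1)" else "[0,1]", format(x))
  }
  invisible(x)
}

# Gene identifiers: upper-cased symbols matched exactly after trimming.
normalize_gene <- function(x) toupper(trimws(as.character(x)))
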