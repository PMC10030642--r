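#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded operations do not
#' perturb the caller's RNG stream. All exported stochastic operations route
#' their draws through this helper.
#'
#' @param seed integer scalar, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

## Geometric mean of positive values; zeros/NA removed by callers as policy.
geom_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a child seed from a base seed and a stage label, deterministically
## and within 32-bit integer range (FNV-1a over the label, folded with seed).
derive_seed <- function(seed, label) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(label)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629 + 1)
}

## Short content hash (FNV-1a, hex) of a character scalar; used for
## provenance manifests, not cryptography.
fnv_hash <- function(x) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Read and write result tables as TSV
#'
#' All tabular outputs share one format: a `#`-prefixed provenance comment
#' line recording the package version (and optionally a seed), then a header
#' row and tab-separated values. `write.table` formats doubles
#' deterministically, which the pipeline relies on for byte-identical
#' reruns.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param comment extra text appended to the provenance comment.
#' @param ... passed on to [utils::read.delim()].
#' @return `path` invisibly (write); a data.frame (read).
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("coevocomm"))
  writeLines(sprintf("# coevocomm %s%s", ver,
                     if (is.null(comment)) "" else paste0(" ", comment)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
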