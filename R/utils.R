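#' @keywords internal
"_PACKAGE"

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
STOP_SYMBOL <- "*"

#' Variant identifier strings
#'
#' Builds the conventional `<wt><position><mut>` label (e.g. `"D1228N"`,
#' `"Y1230*"`) used to key variants across tables.
#'
#' @param df data frame with columns `wt_aa`, `position`, `mut_aa`.
#' @return character vector of variant ids.
#' @export
variant_id <- function(df) {
  paste0(df$wt_aa, df$position, df$mut_aa)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

#' Derive a stage seed from a global seed
#'
#' Expands one global seed into reproducible per-stage seeds by hashing the
#' stage name, so any stage of a run can be re-executed in isolation.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 1000003L
  as.integer((abs(as.numeric(seed)) * 1000003 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# TSV writers/readers shared by all stages: tab-separated, header row,
# no quoting, numerics at 6 significant digits.
met_write_tsv <- function(df, path, digits = 6) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

met_read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
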