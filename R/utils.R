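## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strand-resolved trinucleotide substitution classes
#'
#' Returns the 192 strand-resolved trinucleotide substitution classes used to
#' key mutational spectra and dN/dS opportunity tables. Each class is encoded
#' as \code{"XRY>XAY"}: the reference trinucleotide followed by the mutant
#' trinucleotide (middle base substituted). Unlike the familiar 96-class
#' scheme, the central base is not collapsed to pyrimidines, so transcription
#' strand information is retained.
#'
#' @return Character vector of length 192.
#' @examples
#' length(trinucContexts())
#' @export
trinucContexts <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (up in bases) for (ref in bases) for (down in bases) {
    for (alt in setdiff(bases, ref)) {
      out <- c(out, paste0(up, ref, down, ">", up, alt, down))
    }
  }
  out
}

.assertProb <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.assertCols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("schema error in '%s': missing column(s) %s",
                 table, paste(sQuote(miss), collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.proteinChanging <- function(consequence) {
  consequence %in% c("missense", "nonsense", "frameshift", "splice")
}

.isNeoantigen <- function(strong_binder_count) {
  strong_binder_count >= 1L
}

.emptyDF <- function() data.frame()

.hasTable <- function(df) is.data.frame(df) && nrow(df) > 0L

.hasMatrix <- function(m) is.matrix(m) && length(m) > 0L
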