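DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded package functions never perturb the global random stream. A `NULL`
#' seed evaluates `code` with the current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GGGTACCC")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""),
         character(1))
}

# split a string into single characters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

stop_input <- function(...) stop(..., call. = FALSE)

check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    chars <- unique(str_chars(gsub(if (allow_n) "[ACGTN]" else "[ACGT]", "",
                                   paste(x[bad], collapse = ""))))
    stop_input(sprintf("%s contains characters outside the expected alphabet: %s",
                       what, paste(chars, collapse = ", ")))
  }
  invisible(x)
}
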