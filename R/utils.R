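#' @useDynLib dualprot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom setNames sd
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom tools md5sum
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all reported percentages and
#' indices. Base [round()] uses banker's rounding and would map 92.5 to 92.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(28.82) # 29
#' @export
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Condition constructors: the CLI maps classes to exit codes
## (input/format -> 2, config -> 3, internal invariant -> 4).
dp_input_error <- function(msg, ...) {
  stop(structure(class = c("dp_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

dp_config_error <- function(msg, ...) {
  stop(structure(class = c("dp_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

dp_internal_error <- function(msg, ...) {
  stop(structure(class = c("dp_internal_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

## Split a string into single residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Collapse Ile to Leu so isobaric residues compare equal
collapse_il <- function(x) gsub("I", "L", x, fixed = TRUE)
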