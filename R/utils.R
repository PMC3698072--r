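# shared helpers

#' Round half away from zero
#'
#' Rounding used when comparing against printed 2-decimal tables, where 0.5
#' in the last place rounds upward (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.865)   # 0.87
#' round(0.865, 2)        # 0.86 under banker's rounding
round_half_up <- function(x, digits = 2) {
  # nudge by a relative epsilon first: 0.865 is stored just below 0.865
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

fmt2 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.2f", round_half_up(x, 2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a grouping vector to a two-level factor, preserving the order in
# which the levels were supplied (second level = "positive" group J)
as_two_groups <- function(y, groups = NULL) {
  if (is.factor(y)) {
    lv <- levels(y)
  } else {
    lv <- groups %||% unique(as.character(y))
  }
  if (!is.null(groups)) lv <- groups
  f <- factor(as.character(y), levels = lv)
  if (nlevels(f) != 2L || anyNA(f)) {
    stop("exactly two group labels are required (got: ",
         paste(unique(as.character(y)), collapse = ", "), ")")
  }
  f
}
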