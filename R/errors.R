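# Condition helpers. Validation/domain problems get the
# "reefnfix_validation_error" class so the command-line wrapper can map them to
# exit status 2; everything else surfaces as an ordinary error (status 1).

stop_validation <- function(fmt, ..., call. = FALSE) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("reefnfix_validation_error", "reefnfix_error", "error")))
}

stop_domain <- stop_validation

#' @noRd
check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop_domain("`%s` must be finite and nonnegative", name)
  invisible(x)
}
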