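# Internal helpers shared across modules.

# Devices are always a factor with the thigh (reference system) first so that
# the fixed device contrast in the agreement model is wrist - thigh.
.devices <- c("thigh", "wrist")

#' @noRd
as_device <- function(x) {
  x <- as.character(x)
  bad <- unique(x[!is.na(x) & !x %in% .devices])
  if (length(bad) > 0) {
    abort(sprintf("unknown device value(s): %s (expected 'thigh' or 'wrist')",
                  paste(bad, collapse = ", ")))
  }
  factor(x, levels = .devices)
}

# round() with the "largest component absorbs the residual" convention used by
# the pfSTEP biomarker; returns integer vector summing to round(sum(x)).
#' @noRd
round_preserving_sum <- function(x) {
  target <- round(sum(x))
  out <- round(x)
  resid <- target - sum(out)
  if (resid != 0) {
    i <- which.max(x)
    out[i] <- out[i] + resid
  }
  as.integer(out)
}

#' @noRd
check_scalar_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("invalid configuration: '%s' must be a single number in [%s, %s]",
                  field, format(min), format(max)),
          class = "pfstep_config_error")
  }
  invisible(x)
}

#' @noRd
check_count <- function(x, field, min = 0) {
  check_scalar_number(x, field, min = min)
  if (x != as.integer(x)) {
    abort(sprintf("invalid configuration: '%s' must be a whole number", field),
          class = "pfstep_config_error")
  }
  invisible(x)
}

#' @noRd
check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("invalid configuration: '%s' must be probabilities in [0, 1]", field),
          class = "pfstep_config_error")
  }
  invisible(x)
}

# Derive per-stream seeds from a master seed, keeping them in 32-bit range.
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483629L
}
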