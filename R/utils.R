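## Internal validation helpers. All user-facing errors are classed so the
## pipeline can distinguish validation problems from numerical failures.

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ecstrace_validation_error")
}

stop_domain <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ecstrace_domain_error")
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ecstrace_config_error")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("`%s` must be a single finite number", name)
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop_validation("`%s` = %g is outside its admissible range", name, x)
  }
  invisible(x)
}

## Deterministic 32-bit string hash (djb2 variant), used to spawn per-animal
## sub-seeds that are stable under reordering of groups in a config.
hash32 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

## Sub-seed for one animal: stable in (master seed, group label, index).
spawn_seed <- function(master_seed, group, index) {
  as.integer((as.numeric(master_seed) * 2654435761 + hash32(group) * 97 +
                index * 1000003) %% 2147483647)
}
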