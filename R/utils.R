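# internal helpers shared across modules

# Deterministic per-stage seed derivation from one root seed, so each pipeline
# stage is independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  seed <- as.integer(seed)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  (abs(seed) %% 1000003L) * 2017L + h * 31L + 7L
}

check_rate <- function(x, name, upper_open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (upper_open && x >= 1) || (!upper_open && x > 1)) {
    abort(sprintf("`%s` must be a rate in [0, 1%s), got %s",
                  name, if (upper_open) "" else "]", format(x)))
  }
  invisible(x)
}

check_positive_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer, got %s", name, format(x)))
  }
  invisible(as.integer(x))
}

# two-sided normal p-value for a z statistic
p_normal2 <- function(z) 2 * pnorm(-abs(z))

# 95% normal CI half-width constant used throughout (matches 2-sided 0.05)
Z95 <- 1.959964
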