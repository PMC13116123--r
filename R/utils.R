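#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pnorm rbinom rexp rgamma rlnorm rnorm runif sd
#'   setNames quantile
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

# Deterministic child seed for a named sub-stream of a master seed, so that
# adding one generator to a run never perturbs the draws of another.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 7919 + h + 1) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All exported stochastic functions route through this.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

abort_arg <- function(msg) stop(msg, call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min) {
    abort_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_arg(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  as.numeric(x)
}

# Column-presence check for tabular readers; errors name the missing column.
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort_arg(sprintf("%s is missing mandatory column(s): %s",
                      what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
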