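# Internal argument checks and seed plumbing.

abort_domain <- function(msg) {
  rlang::abort(msg, class = "micromotion_domain_error")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_domain(sprintf("`%s` must be a single finite positive number.", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (allow_inf || is.finite(x))
  if (!ok) {
    abort_domain(sprintf("`%s` must be a single non-negative number.", name))
  }
  invisible(x)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state;
# seed = NULL uses (and advances) the current stream.
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Derive a per-condition seed from a master seed and a condition label
#'
#' Conditions keep the same seed wherever they appear in a sweep: the label is
#' hashed with a polynomial rolling hash and folded into the master seed, so
#' reordering or subsetting the condition list never changes any condition's
#' random stream.
#'
#' @param master_seed Integer master seed for the whole sweep.
#' @param label Character scalar identifying the condition.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' condition_seed(1L, "urea 100 mM")
condition_seed <- function(master_seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps everything in integer range
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% m
  as.integer((as.numeric(master_seed) %% m + h) %% m)
}
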