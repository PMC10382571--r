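#' @keywords internal
"_PACKAGE"

# Typed conditions used across the package. Every error raised by dotmatch
# carries class c("dotmatch_<kind>", "dotmatch_error", "error") so callers can
# distinguish validation problems from pathological statistics.
dm_stop <- function(kind, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("dotmatch_", kind), "dotmatch_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

dm_warn <- function(message) {
  warning(warningCondition(message, class = "dotmatch_warning"))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded at `seed`, then restores
#' the caller's RNG state, so seeded helpers do not disturb the global stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    dm_stop("validation", "`seed` must be a single finite integer")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# scalar checks
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
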