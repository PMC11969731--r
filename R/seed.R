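#' Derive a reproducible substream seed from a global seed
#'
#' Every generator in the package draws from its own substream so that adding
#' a new generator (or reordering calls) never perturbs the random numbers
#' seen by existing ones. The splitting rule is documented and fixed: the
#' component name is hashed with a 31-radix polynomial rolling hash modulo
#' 2^31 - 1 and folded into the global seed.
#'
#' @param seed integer global seed.
#' @param component character scalar naming the consumer (e.g. "slam",
#'   "interactome").
#' @return an integer in [0, 2^31 - 1) usable with [set.seed()].
#' @export
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(component), length(component) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(component)) h <- (h * 31 + code) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", nm), call. = FALSE)
  x
}

.config_error <- function(...) {
  cond <- structure(class = c("nascentflow_config_error", "error", "condition"),
                    list(message = sprintf(...), call = sys.call(-1)))
  stop(cond)
}
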