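#' @useDynLib ventimap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor quantile rnorm runif aov TukeyHSD sd median ks.test
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Abort with a classed condition so callers/tests can distinguish error kinds.
vm_stop <- function(msg, class) {
  stop(structure(class = c(class, "ventimap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Derive a reproducible stage seed from a master seed
#'
#' Each pipeline stage draws its random numbers from a seed obtained by
#' hashing the stage name into the master seed, so that adding or reordering
#' stages never perturbs the random stream of another stage.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  p <- 2147483647 # 2^31 - 1, prime
  h <- as.double(master %% p)
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% p
  as.integer(h)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Linear-interpolation percentile (same convention as stats::quantile type 7).
vm_percentile <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}
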