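#' @keywords internal
"_PACKAGE"

# Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Otsu threshold of a numeric vector
#'
#' Maximises between-class variance over a 256-bin histogram of `x`.
#' Returns the bin-edge threshold; values strictly greater are "positive".
#'
#' @param x numeric vector.
#' @param n_bins number of histogram bins.
#' @return numeric threshold, or `NA` when `x` is degenerate (all equal).
#' @keywords internal
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(NA_real_)
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- hist(x, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(p))
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  br[k + 1L]
}

# Deterministic md5 of an R object via its canonical JSON serialisation;
# used for config/catalog hashes recorded in manifests.
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(f))
}

file_hash <- function(path) unname(tools::md5sum(path))

# Derive a stream of child seeds from one master seed; keeps every seed
# below 2^31 so it is a valid R integer.
derive_seeds <- function(seed, n, stream = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed((seed + 997L * stream) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

afmi_log <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [afmicell] ", ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
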