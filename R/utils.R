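# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generator internals never
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# One RNG stream per output family so regenerating one artifact does not
# perturb the others. Streams: annotation=1, methylome=2, graph=3, clinical=4.
stream_seed <- function(master_seed, stream) {
  offsets <- c(annotation = 1L, methylome = 2L, graph = 3L, clinical = 4L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((as.double(master_seed) * 48271 + offsets[[stream]] * 65537) %% 2147483629)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(name, " must be a single number in [", min, ", ", max, "]", call. = FALSE)
  invisible(x)
}

site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")
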