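#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim pchisq p.adjust rnorm rpois rnbinom runif rlnorm
#'   median sd setNames quantile lm.fit fisher.test kruskal.test
#'   pairwise.t.test uniroot complete.cases cor pt dnbinom var rgamma
#'   rmultinom model.matrix na.omit
#' @importFrom utils read.table write.table head tail
NULL

# Derive an independent RNG substream seed (< 2^31) from a master seed and a
# stream label, so regenerating one artifact never perturbs the others.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}

assert_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed))
    stop("a single integer 'seed' is required (reproducibility contract)",
         call. = FALSE)
  invisible(as.integer(seed))
}

junction_key <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = ":")
}
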