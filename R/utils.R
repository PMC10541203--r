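#' @importFrom methods new validObject is as slot
#' @importFrom stats median rnorm rnbinom runif prcomp p.adjust pnorm loess
#'   predict hclust dist kmeans var sd quantile cutree setNames aggregate
#' @importFrom utils head write.table read.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All generator/stage randomness flows through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stage-offset seeds keep stages reproducible independently of one another.
stageSeed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

msgLog <- function(..., logFile = NULL) {
  txt <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", paste0(...))
  message(txt)
  if (!is.null(logFile)) cat(txt, "\n", file = logFile, append = TRUE)
  invisible(txt)
}

stopCfg <- function(...) stop(paste0(...), call. = FALSE)

# counts accessor tolerant of plain matrices
.counts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else x
}

.logcounts <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
      stopCfg("no 'logcounts' assay: run normalizeCounts() first")
    SummarizedExperiment::assay(x, "logcounts")
  } else x
}
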