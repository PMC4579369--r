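# Internal helpers shared across modules.

# Evaluate `expr` under a RNG state derived deterministically from
# (seed, op). Each stochastic operation draws from its own stream so that
# reordering operations does not change their output. The previous RNG
# state is restored on exit.
with_op_seed <- function(seed, op, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  set.seed((abs(as.integer(seed)) %% 1000003L) * 2011L + h %% 65011L)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a `subset` argument against a genotype table: NULL (all rows),
# logical vector, integer indices, character ids, or a one-sided filter on
# the metadata columns given as a function.
resolve_subset <- function(g, subset) {
  n <- nrow(g$meta)
  if (is.null(subset)) return(seq_len(n))
  if (is.function(subset)) {
    keep <- subset(g$meta)
    stopifnot(is.logical(keep), length(keep) == n)
    return(which(keep))
  }
  if (is.logical(subset)) {
    stopifnot(length(subset) == n)
    return(which(subset))
  }
  if (is.character(subset)) {
    idx <- match(subset, g$meta$id)
    if (anyNA(idx)) stop("unknown ids in subset: ",
                         paste(subset[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(subset)
  stopifnot(all(idx >= 1L & idx <= n))
  idx
}

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
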