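# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All simulators route their randomness through this so that
# identical (spec, seed) pairs give bit-identical output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Scalar checks used by the validators; each error names the violated
# constraint so generator misconfiguration is caught early.
check_positive_scalar <- function(x, name, integer = FALSE, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (strict && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (!strict && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  if (integer && x != as.integer(x)) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

# Coerce a genes x cells container to a base dense matrix, preserving
# dimnames. Used where per-gene rank statistics need dense access.
as_dense <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(x)
}

# Column grouping indicator (cells x groups), used for fast grouped sums
# via sparse matrix multiplication.
group_indicator <- function(labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  ind <- Matrix::sparseMatrix(
    i = seq_along(labels),
    j = match(labels, groups),
    x = 1,
    dims = c(length(labels), length(groups)),
    dimnames = list(NULL, groups)
  )
  ind
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
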