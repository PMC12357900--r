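# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# extract a numeric value column from a vector or tibble-like input
.values <- function(x, col = "value") {
  v <- if (is.data.frame(x)) {
    if (!col %in% names(x)) {
      stop("expected a '", col, "' column", call. = FALSE)
    }
    x[[col]]
  } else {
    x
  }
  if (!is.numeric(v)) stop("values must be numeric", call. = FALSE)
  v[is.finite(v)]
}
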