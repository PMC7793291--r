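# internal helpers shared across modules

# run expr under a temporary RNG state so generators are deterministic per
# seed without clobbering the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# relative comparison of two objective vectors / rows
vec_close <- function(a, b, tol = 1e-9) {
  all(abs(a - b) <= tol * pmax(1, abs(a), abs(b)))
}

# index of a row of `mat` equal to `v` within tolerance, or 0L
match_row <- function(v, mat, tol = 1e-9) {
  if (is.null(mat) || nrow(mat) == 0L) return(0L)
  for (i in seq_len(nrow(mat))) if (vec_close(mat[i, ], v, tol)) return(i)
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pp <- function(msg, class) {
  stop(structure(class = c(class, "paretopaths_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
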