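# internal helpers

abort_ <- function(...) stop(..., call. = FALSE)

# run code under a temporary RNG seed, restoring any prior state
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  force(code)
}

# deterministic descending order by score, ascending lexicographic gene id on ties
order_ranked_ <- function(gene_id, score) {
  order(-score, gene_id, method = "radix")
}

# upper-triangle index pairs of an n x n matrix (i < j)
upper_pairs_ <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}
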