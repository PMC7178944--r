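#' @importFrom rlang abort warn
#' @importFrom stats rnorm runif rbinom setNames predict
#' @importFrom utils head
NULL

# Unordered pair key: encodes (i, j), i != j, 1-based, as a double.
# Safe for n up to ~9e7 (keys < 2^53).
pair_key <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * n + (hi - 1)
}

key_to_pair <- function(key, n) {
  lo <- key %/% n + 1
  hi <- key %% n + 1
  cbind(i = lo, j = hi)
}

# Index of unordered pair among all n*(n-1)/2 pairs in lexicographic order,
# and its inverse. Used for uniform pair sampling without enumeration.
pair_rank_to_ij <- function(r, n) {
  # r in 1..choose(n,2); row i satisfies cum(i) >= r where
  # cum(i) = (i-1)*n - i*(i-1)/2 counts pairs with first index < i... solve directly
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * r))
  offset <- (i - 1) * n - i * (i - 1) / 2
  j <- r - offset + i
  # guard against floating point at boundaries
  bad <- j > n | j <= i
  if (any(bad)) {
    for (k in which(bad)) {
      ii <- i[k]
      while (TRUE) {
        off <- (ii - 1) * n - ii * (ii - 1) / 2
        jj <- r[k] - off + ii
        if (jj > ii && jj <= n) { i[k] <- ii; j[k] <- jj; break }
        ii <- if (jj > n) ii + 1 else ii - 1
      }
    }
  }
  cbind(i = as.integer(i), j = as.integer(j))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax of a matrix (numerically shifted).
row_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Backward through row-wise softmax: a = softmax(z); returns dz given a, da.
row_softmax_bw <- function(a, da) {
  a * (da - rowSums(da * a))
}

relu_bw <- function(z, da) {
  da * (z > 0)
}

apply_act <- function(z, act) {
  switch(act,
    relu = relu(z),
    softmax = row_softmax(z),
    identity = z,
    abort(paste0("unknown activation '", act, "'"), class = "gognn_config_error")
  )
}

apply_act_bw <- function(z, a, da, act) {
  switch(act,
    relu = relu_bw(z, da),
    softmax = row_softmax_bw(a, da),
    identity = da,
    abort(paste0("unknown activation '", act, "'"), class = "gognn_config_error")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
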