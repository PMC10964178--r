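# Parameter initializers and small layer constructors. All initialization
# draws from the caller's RNG stream so model construction is reproducible
# under a single seed.

init_w <- function(dims, fan_in, gain = 2) {
  nd_param(array(stats::rnorm(prod(dims), sd = sqrt(gain / fan_in)), dims))
}

conv_layer <- function(k, cin, cout) {
  list(w = init_w(c(k, k, cin, cout), k * k * cin),
       b = nd_param(numeric(cout)))
}

# transposed conv kernel: dim (k, k, cout, cin)
convt_layer <- function(k, cout, cin) {
  list(w = init_w(c(k, k, cout, cin), k * k * cin / 4),
       b = nd_param(numeric(cout)))
}

dense_layer <- function(a, b) {
  list(w = init_w(c(a, b), a, gain = 1),
       b = nd_param(numeric(b)))
}

ln_layer <- function(d) {
  list(g = nd_param(rep(1, d)), b = nd_param(numeric(d)))
}

in_layer <- function(c) {
  list(g = nd_param(rep(1, c)), b = nd_param(numeric(c)))
}

# Multi-head attention parameters over channel dim C. `win` (window side)
# adds a learnable relative-position bias table of (2*win-1)^2 entries per
# head; NULL omits the table (plain full attention).
mha_layer <- function(C, n_heads, win = NULL) {
  p <- list(
    wq = init_w(c(C, C), C, gain = 1), wk = init_w(c(C, C), C, gain = 1),
    wv = init_w(c(C, C), C, gain = 1), wo = init_w(c(C, C), C, gain = 1),
    bq = nd_param(numeric(C)), bk = nd_param(numeric(C)),
    bv = nd_param(numeric(C)), bo = nd_param(numeric(C))
  )
  if (!is.null(win)) {
    p$bias <- nd_param(matrix(stats::rnorm((2 * win - 1)^2 * n_heads, sd = 0.02),
                              (2 * win - 1)^2, n_heads))
  }
  p
}

# ---- plain-array helpers (no autodiff) ----

softmax_rows <- function(m) {
  m <- m - m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m)
  e / rowSums(e)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# ensure an image has an explicit channel dimension
as_image <- function(x) {
  if (is.null(dim(x))) stop("image must be a matrix or H x W x C array")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}
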