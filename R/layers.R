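# Thin R wrappers around the C++ tensor kernels plus the layers kept in R
# (instance norm, ReLU, sigmoid, dropout). Activations are 4D arrays
# (X, Y, Z, C); weights are (k, k, k, Cin, Cout) arrays.

conv3d_fw <- function(x, w, b) {
  k <- dim(w)[1]
  cout <- dim(w)[5]
  y <- conv3d_fw_cpp(as.numeric(x), dim(x), as.numeric(w), k, cout,
                     as.numeric(b))
  array(y, dim = c(dim(x)[1:3], cout))
}

conv3d_bw <- function(x, w, gy) {
  k <- dim(w)[1]
  cout <- dim(w)[5]
  r <- conv3d_bw_cpp(as.numeric(x), dim(x), as.numeric(w), k, cout,
                     as.numeric(gy))
  list(gx = array(r$gx, dim = dim(x)),
       gw = array(r$gw, dim = dim(w)),
       gb = r$gb)
}

maxpool3d_fw <- function(x, size, stride, pad) {
  r <- maxpool3d_fw_cpp(as.numeric(x), dim(x), size, stride, pad)
  list(y = array(r$y, dim = r$ydim), idx = r$idx, xdim = dim(x))
}

maxpool3d_bw <- function(cache, gy) {
  array(maxpool3d_bw_cpp(cache$idx, as.numeric(gy), prod(cache$xdim)),
        dim = cache$xdim)
}

tconv3d_fw <- function(x, w, b) {
  cout <- dim(w)[5]
  y <- tconv3d_fw_cpp(as.numeric(x), dim(x), as.numeric(w), cout,
                      as.numeric(b))
  array(y, dim = c(2 * dim(x)[1:3], cout))
}

tconv3d_bw <- function(x, w, gy) {
  cout <- dim(w)[5]
  r <- tconv3d_bw_cpp(as.numeric(x), dim(x), as.numeric(w), cout,
                      as.numeric(gy))
  list(gx = array(r$gx, dim = dim(x)),
       gw = array(r$gw, dim = dim(w)),
       gb = r$gb)
}

relu_fw <- function(x) {
  x[x < 0] <- 0
  x
}

# gradient through ReLU given the post-activation values
relu_bw <- function(y, gy) gy * (y > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# instance normalization: per-channel mean/variance over the spatial grid
# of the (single) instance, with learnable per-channel gain and shift
instnorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  dims <- dim(x)
  n <- prod(dims[1:3])
  xm <- matrix(x, nrow = n)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, dim = dims),
       cache = list(xhat = xhat, istd = istd, dims = dims))
}

instnorm_bw <- function(cache, gamma, gy) {
  n <- prod(cache$dims[1:3])
  g <- matrix(gy, nrow = n)
  ggamma <- colSums(g * cache$xhat)
  gbeta <- colSums(g)
  gxhat <- sweep(g, 2, gamma, `*`)
  # d/dx of (x - mu)/sqrt(var + eps), both mu and var depend on x
  t1 <- sweep(gxhat, 2, colMeans(gxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(gxhat * cache$xhat), `*`)
  gx <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(gx = array(gx, dim = cache$dims), ggamma = ggamma, gbeta = gbeta)
}

dropout_fw <- function(x, rate) {
  if (rate <= 0) return(list(y = x, mask = NULL))
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  list(y = x * keep, mask = keep)
}

dropout_bw <- function(mask, gy) {
  if (is.null(mask)) gy else gy * mask
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

split_ch <- function(g, ca) {
  d <- dim(g)
  n <- prod(d[1:3])
  list(a = array(g[seq_len(n * ca)], dim = c(d[1:3], ca)),
       b = array(g[-seq_len(n * ca)], dim = c(d[1:3], d[4] - ca)))
}

he_init <- function(shape) {
  fan_in <- prod(shape[1:4])
  array(rnorm(prod(shape), sd = sqrt(2 / fan_in)), dim = shape)
}
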