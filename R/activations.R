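#' Numerically stable softplus
#'
#' Computes `log(1 + exp(x))` elementwise as `max(x, 0) + log1p(exp(-|x|))`,
#' which is exact in both tails (`softplus(x) -> x` for large positive `x`,
#' `-> exp(x)` for large negative `x`) without overflow.
#'
#' @param x numeric vector or array.
#' @return same shape as `x`.
#' @export
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Tanh-softplus (TS) activation
#'
#' The smooth activation `TS(x) = tanh(x) * softplus(x)` used in place of
#' SiLU inside detection heads. It is zero at the origin, approaches `x`
#' for large positive inputs and decays to zero for large negative inputs.
#'
#' @param x numeric vector or array.
#' @return same shape as `x`.
#' @examples
#' ts_activation(0)
#' ts_activation(c(-10, 10))
#' @export
ts_activation <- function(x) {
  out <- tanh(x) * softplus(x)
  dim(out) <- dim(x)
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

# Forward/backward dispatch used by the layer graph. `act_bwd` returns
# d(act)/dx evaluated at x (so dx = dy * act_bwd(x)).
act_fwd <- function(fun, x) {
  switch(fun,
    silu = silu(x),
    ts = ts_activation(x),
    sigmoid = sigmoid(x),
    identity = x,
    stop("unknown activation: ", fun)
  )
}

act_bwd <- function(fun, x) {
  switch(fun,
    silu = {
      s <- sigmoid(x)
      s * (1 + x * (1 - s))
    },
    ts = {
      th <- tanh(x)
      (1 - th^2) * softplus(x) + th * sigmoid(x)
    },
    sigmoid = {
      s <- sigmoid(x)
      s * (1 - s)
    },
    identity = 1 + 0 * x,
    stop("unknown activation: ", fun)
  )
}
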