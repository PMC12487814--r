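# Minimal dense-network engine: ReLU MLPs with manual backpropagation and
# Adam. Parameter collections are nested lists whose leaves are numeric
# arrays; the tree helpers below map over them generically.

.tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) .tree_map(f, e)) else f(x)
}

.tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- Map(function(a, b) .tree_map2(f, a, b), x, y)
    out
  } else f(x, y)
}

.tree_map3 <- function(f, x, y, z) {
  if (is.list(x)) Map(function(a, b, c) .tree_map3(f, a, b, c), x, y, z)
  else f(x, y, z)
}

# Xavier/Glorot initialization; consumes the caller's RNG stream.
.mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(i) {
    fi <- sizes[i]; fo <- sizes[i + 1]
    list(W = matrix(rnorm(fi * fo, sd = sqrt(2 / (fi + fo))), fi, fo),
         b = numeric(fo))
  })
}

# Forward pass, ReLU hidden layers, linear output. Returns the list of
# per-layer activations (A[[1]] = input, A[[nl + 1]] = output), which is
# all the cache backprop needs under ReLU.
.mlp_forward <- function(layers, X) {
  A <- vector("list", length(layers) + 1)
  A[[1]] <- X
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- A[[i]] %*% layers[[i]]$W
    Z <- Z + rep(layers[[i]]$b, each = nrow(Z))
    A[[i + 1]] <- if (i < nl) pmax(Z, 0) else Z
  }
  A
}

# dOut is dLoss/d(output); returns per-layer grads and dLoss/d(input).
.mlp_backward <- function(layers, A, dOut) {
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- dOut
  dA <- NULL
  for (i in nl:1) {
    grads[[i]] <- list(W = crossprod(A[[i]], delta), b = colSums(delta))
    dA <- delta %*% t(layers[[i]]$W)
    if (i > 1) delta <- dA * (A[[i]] > 0)
  }
  list(grads = grads, dX = dA)
}

.adam_new <- function(params) {
  list(m = .tree_map(function(p) p * 0, params),
       v = .tree_map(function(p) p * 0, params),
       t = 0)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  scale <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  params <- .tree_map3(function(p, m, v) p - scale * m / (sqrt(v) + eps),
                       params, state$m, state$v)
  list(params = params, state = state)
}

.tree_add <- function(x, y) .tree_map2(`+`, x, y)

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# geometric-mean hidden width, floored so tiny problems keep capacity
.hidden_dim <- function(inputDim, latentDim) {
  max(8L, as.integer(round(sqrt(inputDim * latentDim))))
}
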