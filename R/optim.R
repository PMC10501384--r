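# Minimal Adam optimizer over arbitrarily nested lists of numeric arrays.

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

adam_init <- function(pars) {
  list(m = zeros_like(pars), v = zeros_like(pars), t = 0L)
}

adam_update_node <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    out <- Map(adam_update_node, p, g, m, v,
               MoreArgs = list(lr = lr, b1 = b1, b2 = b2, eps = eps, t = t))
    list(p = lapply(out, `[[`, "p"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
}

adam_step <- function(pars, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  t <- state$t + 1L
  out <- adam_update_node(pars, grads, state$m, state$v, lr, b1, b2, eps, t)
  list(pars = out$p, state = list(m = out$m, v = out$v, t = t))
}
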