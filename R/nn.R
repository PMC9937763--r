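# Internal glue around the compiled conv-net core: weight initialisation,
# forward wrapper, and Adam. Weight lists use the names expected by nn.cpp.

nn_spec <- function(in_hw, in_ch, conv_filters, fc_units, n_out, dueling = FALSE) {
  stopifnot(length(conv_filters) >= 1L, all(conv_filters >= 1L),
            fc_units >= 1L, n_out >= 1L)
  # track spatial size through (3x3 valid conv, 2x2 floor pool) stages
  hw <- in_hw
  for (f in conv_filters) {
    hw <- (hw - 2L) %/% 2L
    if (hw < 1L) stop("input size ", in_hw, " too small for ",
                      length(conv_filters), " conv/pool stages")
  }
  list(in_hw = as.integer(in_hw), in_ch = as.integer(in_ch),
       conv_filters = as.integer(conv_filters),
       fc_units = as.integer(fc_units), n_out = as.integer(n_out),
       dueling = isTRUE(dueling),
       flat = as.integer(hw * hw * conv_filters[length(conv_filters)]))
}

# He-scaled Gaussian initialisation, driven by the session RNG so that a
# single set.seed() call upstream makes the whole model deterministic.
nn_init_weights <- function(spec) {
  w <- list()
  cin <- spec$in_ch
  for (l in seq_along(spec$conv_filters)) {
    nf <- spec$conv_filters[l]
    fan <- 9L * cin
    w[[paste0("Wc", l)]] <- matrix(rnorm(nf * fan, sd = sqrt(2 / fan)), nf, fan)
    w[[paste0("bc", l)]] <- numeric(nf)
    cin <- nf
  }
  w$Wf <- matrix(rnorm(spec$fc_units * spec$flat, sd = sqrt(2 / spec$flat)),
                 spec$fc_units, spec$flat)
  w$bf <- numeric(spec$fc_units)
  if (spec$dueling) {
    w$Wv <- matrix(rnorm(spec$fc_units, sd = sqrt(2 / spec$fc_units)), 1, spec$fc_units)
    w$bv <- 0
    w$Wa <- matrix(rnorm(spec$n_out * spec$fc_units, sd = sqrt(2 / spec$fc_units)),
                   spec$n_out, spec$fc_units)
    w$ba <- numeric(spec$n_out)
  } else {
    w$Wo <- matrix(rnorm(spec$n_out * spec$fc_units, sd = sqrt(2 / spec$fc_units)),
                   spec$n_out, spec$fc_units)
    w$bo <- numeric(spec$n_out)
  }
  w
}

nn_forward <- function(weights, spec, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  nn_forward_cpp(weights, spec, x)
}

nn_grad <- function(weights, spec, x, grad_out) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  nn_grad_cpp(weights, spec, x, grad_out)
}

adam_state <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    # arma vectors surface as n x 1 matrices; keep weight shapes stable
    if (is.null(dim(weights[[nm]]))) g <- as.numeric(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(weights = weights, state = state)
}
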