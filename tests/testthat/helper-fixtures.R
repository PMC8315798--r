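# Shared synthetic fixtures, built once per test run. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

sc5 <- function() fixture("sc5", function() make_connectome(5, seed = 11))
sc10 <- function() fixture("sc10", function() make_connectome(10, seed = 2))
sc30 <- function() fixture("sc30", function() make_connectome(30, seed = 0))

model30 <- function() fixture("model30", function()
  dmf_model(sc30(), dmf_params(G = 0.5)))

model10 <- function() fixture("model10", function()
  dmf_model(sc10(), dmf_params(G = 0.5)))

# strongly autocorrelated expression-like map on the 30-node connectome
h30 <- function() fixture("h30", function()
  make_expression_map(sc30(), autocorr_length = 60, seed = 3))

# reference scalar-loop evaluation of the synaptic drift (independent of the
# vectorized implementation)
drift_loop <- function(S_E, S_I, C, p, a_E, a_I, w_EI) {
  n <- length(S_E)
  dS_E <- dS_I <- numeric(n)
  for (i in seq_len(n)) {
    lr <- 0
    for (j in seq_len(n)) lr <- lr + C[i, j] * S_E[j]
    I_E <- p$W_E * p$Ib + p$w_EE * S_E[i] + p$G * p$J * lr - w_EI[i] * S_I[i]
    I_I <- p$W_I * p$Ib + p$w_IE * S_E[i] - S_I[i]
    phi <- function(I, a, b, d) {
      x <- a * I - b
      if (abs(d * x) < 1e-12) return(1 / d)
      x / (1 - exp(-d * x))
    }
    r_E <- phi(I_E, a_E[i], p$b_E, p$d_E)
    r_I <- phi(I_I, a_I[i], p$b_I, p$d_I)
    dS_E[i] <- -S_E[i] / p$tau_E + (1 - S_E[i]) * p$gamma_kin * r_E
    dS_I[i] <- -S_I[i] / p$tau_I + r_I
  }
  list(dS_E = dS_E, dS_I = dS_I)
}
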