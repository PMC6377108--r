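# internal helpers shared across modules

# clip probabilities for likelihood work only; predictions are never clipped
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation helpers do not perturb
# the global stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

# Frechet kernel on the scaled effective dose: exp(-d'^-eta), with the
# convention that a non-positive effective dose gives response exactly 0
# (the limit of the closed form; 0^-eta overflows to Inf and exp(-Inf)
# underflows to 0, but we make the convention explicit and overflow-free).
frechet_kernel <- function(d_prime, eta) {
  eta <- rep_len(eta, length(d_prime))
  out <- numeric(length(d_prime))
  pos <- is.finite(d_prime) & d_prime > 0
  out[pos] <- exp(-d_prime[pos]^(-eta[pos]))
  out[is.infinite(d_prime) & d_prime > 0] <- 1
  out
}
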