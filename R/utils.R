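# internal helpers shared across modules

# Run code with a private RNG stream: seeds locally, restores the caller's
# .Random.seed afterwards so package functions never perturb user RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# deterministic child seed, kept inside 32-bit integer range
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147480000 + index * 9973) %% 2147483646) + 1L
}

# Euclidean projection of v onto the probability simplex (Duchi et al. 2008)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("gpsdr_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_fit <- function(msg, diagnostics = NULL) {
  stop(structure(class = c("gpsdr_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      diagnostics = diagnostics)))
}
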