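# internal helpers shared across the package

# wrap angles to [0, 2*pi)
wrap_angle <- function(theta) {
  out <- theta %% (2 * pi)
  out[out < 0] <- out[out < 0] + 2 * pi
  out
}

# wrap angle differences to (-pi, pi]
wrap_diff <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

stop_invalid_param <- function(msg) {
  stop(structure(class = c("circptr_invalid_parameter", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_no_convergence <- function(msg, last) {
  stop(structure(class = c("circptr_no_convergence", "error", "condition"),
                 list(message = msg, call = sys.call(-1), last = last)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
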