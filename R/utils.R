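# internal helpers shared across modules

fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# TRUE when x is a whole number within floating tolerance
is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# deterministic small-integer seed derived from a master seed and a stage
# name, so adding a stage never perturbs another stage's stream
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((abs(as.numeric(master)) %% 1000003) * 1009 + h) %% 2147483587L
}
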