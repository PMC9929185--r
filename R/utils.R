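# Internal helpers: classed conditions and deterministic seed derivation.

scStop <- function(msg, class) {
  stop(errorCondition(msg,
    class = c(paste0("SynapseColoc_", class), "SynapseColoc_error", "error")))
}

scWarn <- function(msg, class = "warning") {
  warning(warningCondition(msg,
    class = c(paste0("SynapseColoc_", class), "SynapseColoc_warning", "warning")))
}

# Child seed for cell `idx` under a master seed; fixed counter scheme so that
# cohorts are reproducible. Kept strictly below 2^31 (R integers are 32-bit).
deriveSeed <- function(master, idx) {
  m <- as.numeric(master) %% 2147483629
  as.integer((m * 10007 + as.numeric(idx) * 7919 + 13) %% 2147483629)
}

# Jitter seed depends on the cell index only, never on the master seed:
# the master seed selects the noise realization while the per-cell biological
# parameters (radius, enrichment) form a fixed sequence across cohorts.
jitterSeed <- function(idx) {
  as.integer((104729 * as.numeric(idx) + 97) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
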