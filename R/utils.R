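#' @keywords internal
"_PACKAGE"

# Stage logging: every pipeline stage reports input dimensions, thresholds and
# counts of filtered items so synthetic runs are auditable like the real study.
ps_log <- function(..., verbose = getOption("pesignal.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[pesignal] ", ...)
  invisible(NULL)
}

ps_stop <- function(...) stop(..., call. = FALSE)

ps_assert <- function(cond, ...) {
  if (!isTRUE(cond)) ps_stop(...)
  invisible(TRUE)
}

# Deterministic seed derivation: one global integer seed, sub-streams per
# stage keyed by name. Kept below 2^31 - 1.
derive_seed <- function(seed, key) {
  ps_assert(is.numeric(seed) && length(seed) == 1, "seed must be a single integer")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Benjamini-Hochberg wrapper; NA-safe, preserves order.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
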