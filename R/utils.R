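# Internal utilities: seeding, exact CSV I/O, logging.

# Named substreams derived from one top-level seed, so that every stage
# (truth sampling, day jitter, noise, screening, sweep, external series)
# has its own reproducible stream and no stage perturbs another.
tct_substream <- function(seed, stream) {
  streams <- c("truth", "jitter", "noise", "screening", "sweep",
               "external", "compositions")
  idx <- match(stream, streams)
  if (is.na(idx)) stop("unknown random substream: ", stream, call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, length(streams))[idx]
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate expr with a local RNG seeded at `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

# CSV writer with full-precision ("%.17g") numeric formatting: output is
# byte-deterministic and numeric columns round-trip losslessly through
# read.csv.
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

tct_log <- function(..., quiet = FALSE) {
  if (!quiet) message("[tcelltwin] ", ...)
  invisible(NULL)
}
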