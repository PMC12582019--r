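# Internal helpers shared across modules.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so seeded generators never disturb the session stream.
# seed = NULL means "use the current stream".
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single finite number")
  }
  invisible(x)
}

# Robust per-frame noise SD of a channel, from first differences
# (sd of diff of iid noise is sqrt(2) * sigma).
robust_step_sd <- function(x) {
  d <- diff(x)
  s <- stats::mad(d) / sqrt(2)
  if (!is.finite(s) || s == 0) s <- stats::sd(d) / sqrt(2)
  if (!is.finite(s)) s <- 0
  s
}

# Order-preserving split of a long-format table by molecule_id.
split_by_molecule <- function(df) {
  split(df, factor(df$molecule_id, levels = unique(df$molecule_id)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
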