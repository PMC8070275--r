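# Internal helpers shared across modules.

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# independent RNG seeds for stages/subjects/channels from one master seed, so
# any stage can be regenerated without replaying the others.
hash_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's RNG
# state afterwards. Keeps seeded generators from perturbing user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# log with a fixed floor; keeps degenerate (all-zero) inputs finite.
LOG_FLOOR <- 1e-12
safe_log <- function(x) log(pmax(x, LOG_FLOOR))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pleura <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop_pleura(msg)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x > 0 && x == round(x)
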