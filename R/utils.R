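#' Derive a deterministic child seed from a parent seed and a stage name
#'
#' All stochastic stages of the pipeline draw their randomness from one global
#' integer seed; each stage derives its own stream with a polynomial string
#' hash of the stage name so that adding or reordering stages never perturbs
#' another stage's draws.
#'
#' @param seed integer parent seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- abs(as.double(seed)) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# Evaluate `code` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

# Mann-Whitney AUC of `scores` for the binary indicator `positive`.
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stop_input <- function(...) stop(..., call. = FALSE)
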