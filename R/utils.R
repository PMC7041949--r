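#' Derive a child seed from a master seed and an operation label
#'
#' Stochastic stages derive their own seed from a single master seed plus a
#' stable text label, so that adding a stage to a pipeline never perturbs the
#' random stream of the existing ones.
#'
#' @param master_seed integer master seed.
#' @param label character label naming the operation.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(label), length(label) == 1L)
  mod <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master_seed) %% mod
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% mod
  }
  as.integer(h)
}

# Run a block with a local RNG state restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Mean and standard error of the mean
#'
#' Summary convention used throughout: per-patch estimates are averaged and
#' reported as mean +/- SEM with n = number of patches. With a single value
#' the SEM is undefined and is reported as 0 with `sem_defined = FALSE`.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `mean`, `sem`, `n`, `sem_defined`.
#' @export
mean_sem <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(is.finite(values)))
  n <- length(values)
  if (n == 1L) {
    return(list(mean = values[[1L]], sem = 0, n = 1L, sem_defined = FALSE))
  }
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n,
       sem_defined = TRUE)
}

# is x a single finite number?
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
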