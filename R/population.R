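#' Define a simulation condition
#'
#' One cell of the study grid: sample size `n`, item count `J`, category
#' count `K`, number of replications `R`, and the base seed from which all of
#' the cell's random streams are derived.
#'
#' @param n Sample size drawn per replication.
#' @param J Number of items (>= 2).
#' @param K Number of response categories per item (>= 2).
#' @param R Number of replications (>= 1).
#' @param base_seed Integer base seed; defaults to 123.
#' @return A list of class `grm_condition`.
#' @examples
#' grm_condition(n = 500, J = 10, K = 5, R = 20)
#' @export
grm_condition <- function(n, J, K, R = 100L, base_seed = 123L) {
  if (n < 1) abort("`n` must be at least 1.", class = "grmsim_invalid_design")
  if (J < 2) abort("`J` must be at least 2.", class = "grmsim_invalid_design")
  if (K < 2) abort("`K` must be at least 2.", class = "grmsim_invalid_design")
  if (R < 1) abort("`R` must be at least 1.", class = "grmsim_invalid_design")
  structure(
    list(n = as.integer(n), J = as.integer(J), K = as.integer(K),
         R = as.integer(R), base_seed = as.integer(base_seed)),
    class = "grm_condition"
  )
}

# Hierarchical seed derivation: a polynomial hash of the condition coordinates
# and replication index modulo 2^31 - 1, so child streams are reproducible
# regardless of execution order and stay in set.seed() range. rep = 0 is
# reserved for the condition-level truth (item bank + population).
derive_seed <- function(base_seed, n, J, K, rep = 0L) {
  m <- 2147483647
  h <- 17
  for (x in c(base_seed, n, J, K, rep)) {
    h <- (h * 69069 + (as.numeric(x) %% m)) %% m
  }
  as.integer(h)
}

#' Generate a random item bank from the study's generating distributions
#'
#' Discriminations are drawn `U(0.5, 2.5)`; each item's `K - 1` category
#' locations are drawn `U(-2, 2)` and sorted ascending; intercepts follow
#' `d = -D * a * b`. Uses the current R random stream.
#'
#' @param J Number of items (>= 2).
#' @param K Number of categories (>= 2).
#' @param D Scaling constant.
#' @return An [item_bank()].
#' @examples
#' set.seed(42)
#' generate_item_bank(J = 5, K = 4)
#' @export
generate_item_bank <- function(J, K, D = 1.701) {
  if (J < 2 || K < 2) {
    abort("Invalid design: need J >= 2 and K >= 2.", class = "grmsim_invalid_design")
  }
  a <- runif(J, 0.5, 2.5)
  b <- t(apply(matrix(runif(J * (K - 1L), -2, 2), J, K - 1L), 1, sort))
  if (K == 2L) b <- matrix(b, ncol = 1L)
  item_bank(a = a, b = b, D = D)
}

#' Generate the fixed population of one condition cell
#'
#' Builds the condition-level truth shared by all replications: one item bank
#' and a finite pool of `N_pop = ceiling(n / 0.001)` latent traits drawn
#' i.i.d. from `N(0, 1)` (a 0.1% sampling fraction). The random stream is
#' derived from the condition's base seed, so the same condition always
#' regenerates the identical population.
#'
#' @param condition A [grm_condition()].
#' @param D Scaling constant passed to the item bank.
#' @return A list of class `grm_population` with elements `condition`,
#'   `bank`, `theta` (length `N_pop`) and `N_pop`. Only the latent traits are
#'   materialized; responses are simulated per drawn sample.
#' @examples
#' pop <- generate_population(grm_condition(n = 100, J = 5, K = 4, R = 2))
#' pop$N_pop
#' @export
generate_population <- function(condition, D = 1.701) {
  stopifnot(inherits(condition, "grm_condition"))
  set.seed(derive_seed(condition$base_seed, condition$n, condition$J,
                       condition$K, 0L))
  bank <- generate_item_bank(condition$J, condition$K, D = D)
  N_pop <- as.integer(ceiling(condition$n / 0.001))
  theta <- rnorm(N_pop)
  structure(list(condition = condition, bank = bank, theta = theta,
                 N_pop = N_pop),
            class = "grm_population")
}

#' Draw one replication sample from a population
#'
#' Samples `n` respondents uniformly without replacement from the finite
#' latent-trait pool and simulates their responses from the population's item
#' bank. Responses are realized at draw time: the population fixes the latent
#' traits, not the response noise.
#'
#' @param pop A [grm_population()].
#' @param rep_index Optional replication index; when supplied the random
#'   stream is re-derived from `(base_seed, n, J, K, rep_index)` so the draw
#'   is reproducible in isolation. When `NULL` the current stream is used.
#' @return A list of class `grm_sample` with `indices`, `theta_true` and the
#'   `n x J` integer `responses` matrix.
#' @examples
#' pop <- generate_population(grm_condition(n = 100, J = 5, K = 4, R = 2))
#' s <- draw_sample(pop, rep_index = 1)
#' dim(s$responses)
#' @export
draw_sample <- function(pop, rep_index = NULL) {
  stopifnot(inherits(pop, "grm_population"))
  cond <- pop$condition
  if (cond$n > pop$N_pop) {
    abort("Sample size exceeds population size.", class = "grmsim_invalid_design")
  }
  if (!is.null(rep_index)) {
    set.seed(derive_seed(cond$base_seed, cond$n, cond$J, cond$K,
                         as.integer(rep_index)))
  }
  idx <- sample.int(pop$N_pop, cond$n)
  theta_true <- pop$theta[idx]
  structure(
    list(indices = idx, theta_true = theta_true,
         responses = simulate_responses(theta_true, pop$bank),
         rep_index = rep_index, condition = cond),
    class = "grm_sample"
  )
}

#' Write and read replication samples as CSV
#'
#' The file starts with a `#`-prefixed comment line recording the seed
#' lineage `(n, J, K, rep, base_seed)`, followed by a header and one row per
#' respondent: the true latent trait and the integer responses (0-based).
#'
#' @param sample A `grm_sample`.
#' @param path File path.
#' @return `write_sample()` returns `path` invisibly; `read_sample()` a list
#'   with `theta_true`, `responses`, and the parsed lineage.
#' @export
write_sample <- function(sample, path) {
  cond <- sample$condition
  hdr <- sprintf("# n=%d J=%d K=%d rep=%s base_seed=%d", cond$n, cond$J,
                 cond$K, ifelse(is.null(sample$rep_index), "NA",
                                as.character(sample$rep_index)),
                 cond$base_seed)
  df <- data.frame(theta_true = sample$theta_true, sample$responses)
  names(df) <- c("theta_true", paste0("item_", seq_len(ncol(sample$responses))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample
#' @export
read_sample <- function(path) {
  hdr <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#")
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  lineage <- as.list(stats::setNames(
    suppressWarnings(as.integer(sub(".*=", "", kv))), sub("=.*", "", kv)))
  list(theta_true = df$theta_true,
       responses = as.matrix(df[grep("^item_", names(df))]),
       lineage = lineage)
}
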