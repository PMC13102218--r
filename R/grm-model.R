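#' Construct an item bank for the graded response model
#'
#' An item bank holds the generating truth of a simulation condition: one
#' discrimination `a_j` per item and `K - 1` ascending category locations
#' `b_jk` (the theta values at which the probability of responding in category
#' `k` or above is one half). The slope-intercept parametrization is stored
#' alongside: `d_jk = -D * a_j * b_jk`, so the logit of the boundary
#' probability is `D * a_j * theta + d_jk`.
#'
#' @param a Numeric vector of `J` discriminations on the classic IRT scale
#'   (non-negative).
#' @param b Numeric matrix of category locations with `J` rows and `K - 1`
#'   columns, each row weakly ascending. A vector is taken as a single-column
#'   matrix (`K = 2`).
#' @param D Positive scaling constant aligning the logistic with the normal
#'   ogive; defaults to 1.701.
#'
#' @return A tibble of class `item_bank` with columns `item`, `a`,
#'   `b_1 ... b_{K-1}`, `d_1 ... d_{K-1}`, and attributes `K` and `D`.
#' @examples
#' item_bank(a = c(1, 2), b = rbind(c(-1, 0, 1), c(-0.5, 0.2, 1.3)))
#' @export
item_bank <- function(a, b, D = 1.701) {
  if (!is.matrix(b)) b <- matrix(b, ncol = length(b))
  J <- length(a)
  if (nrow(b) != J) {
    abort("`b` must have one row per element of `a`.", class = "grmsim_invalid_item")
  }
  if (!all(is.finite(a)) || !all(is.finite(b)) || !is.finite(D)) {
    abort("Item parameters must be finite.", class = "grmsim_invalid_argument")
  }
  if (any(a < 0)) {
    abort("Discriminations `a` must be non-negative.", class = "grmsim_invalid_item")
  }
  if (D <= 0) abort("`D` must be positive.", class = "grmsim_invalid_argument")
  if (ncol(b) > 1 && any(t(apply(b, 1, diff)) < 0)) {
    abort("Each row of `b` must be ascending.", class = "grmsim_invalid_item")
  }
  d <- -D * a * b
  K <- ncol(b) + 1L
  out <- tibble::tibble(item = seq_len(J), a = as.numeric(a))
  bt <- as.data.frame(b)
  names(bt) <- paste0("b_", seq_len(K - 1L))
  dt <- as.data.frame(d)
  names(dt) <- paste0("d_", seq_len(K - 1L))
  out <- dplyr::bind_cols(out, tibble::as_tibble(bt), tibble::as_tibble(dt))
  attr(out, "K") <- K
  attr(out, "D") <- D
  class(out) <- c("item_bank", class(out))
  out
}

bank_b <- function(bank) {
  K <- attr(bank, "K")
  as.matrix(bank[paste0("b_", seq_len(K - 1L))])
}

bank_d <- function(bank) {
  K <- attr(bank, "K")
  as.matrix(bank[paste0("d_", seq_len(K - 1L))])
}

#' Boundary (cumulative) response probability of the GRM
#'
#' Probability of responding in category `k` or above for one boundary:
#' `plogis(D * a * (theta - b_k))`. Strictly increasing in `theta` and
#' strictly decreasing in `b_k`.
#'
#' @param theta Latent trait value(s).
#' @param a Item discrimination, positive.
#' @param b_k Category location for this boundary.
#' @param D Scaling constant, positive.
#' @return Probabilities in (0, 1), vectorized over the inputs.
#' @examples
#' boundary_prob(theta = 1, a = 1, b_k = 0) # plogis(1.701)
#' @export
boundary_prob <- function(theta, a, b_k, D = 1.701) {
  if (!all(is.finite(theta)) || !all(is.finite(a)) || !all(is.finite(b_k)) ||
      !all(is.finite(D))) {
    abort("All arguments must be finite.", class = "grmsim_invalid_argument")
  }
  if (any(a <= 0) || any(D <= 0)) {
    abort("`a` and `D` must be positive.", class = "grmsim_invalid_argument")
  }
  plogis(D * a * (theta - b_k))
}

#' Category response probabilities of the GRM for one item
#'
#' Samejima's difference form: the probability of category `k` (0-based) is
#' the difference of adjacent boundary probabilities, with the conventions
#' that the zeroth boundary probability is 1 and the `K`-th is 0.
#'
#' @param theta Vector of latent trait values.
#' @param a Item discrimination.
#' @param b Ascending vector of `K - 1` category locations.
#' @param D Scaling constant.
#' @return A `length(theta) x K` matrix of probabilities; rows sum to 1.
#' @examples
#' category_prob(theta = 0, a = 1, b = c(-1, 0, 1))
#' @export
category_prob <- function(theta, a, b, D = 1.701) {
  if (is.unsorted(b)) {
    abort("Category locations `b` must be ascending.", class = "grmsim_invalid_item")
  }
  pstar <- plogis(D * a * outer(theta, b, "-"))
  if (!is.matrix(pstar)) pstar <- matrix(pstar, nrow = length(theta))
  cbind(1, pstar) - cbind(pstar, 0)
}

# Category probabilities on the internal slope-intercept scale: logit of the
# boundary t is a1 * theta + d_t with d descending. Used by the EM machinery.
category_prob_internal <- function(theta, a1, d) {
  psi <- plogis(outer(a1 * theta, d, "+"))
  cbind(1, psi) - cbind(psi, 0)
}

#' Simulate GRM response matrices
#'
#' Draws one integer response (0-based category) per respondent and item from
#' the category probabilities at that respondent's latent trait. Uses the
#' current R random stream; seed with [set.seed()] for reproducibility.
#'
#' @param theta Vector of latent trait values, one per respondent.
#' @param bank An [item_bank()].
#' @return An integer matrix of dimension `length(theta) x J` with entries in
#'   `0 .. K-1`.
#' @examples
#' bank <- item_bank(a = c(1, 1.5), b = rbind(c(-1, 1), c(0, 0.5)))
#' set.seed(1)
#' simulate_responses(c(-1, 0, 1), bank)
#' @export
simulate_responses <- function(theta, bank) {
  if (length(theta) == 0) {
    abort("`theta` must be non-empty.", class = "grmsim_invalid_argument")
  }
  J <- nrow(bank)
  D <- attr(bank, "D")
  b <- bank_b(bank)
  n <- length(theta)
  out <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    pstar <- plogis(D * bank$a[j] * outer(theta, b[j, ], "-"))
    u <- runif(n)
    # boundary events {u < P*_k} are nested, so the count is the category
    out[, j] <- as.integer(rowSums(u < pstar))
  }
  out
}

#' Read and write item banks as CSV
#'
#' The on-disk schema is `item, a, b_1..b_{K-1}, d_1..d_{K-1}` with a
#' mandatory header row. The scaling constant is not stored; supply it on
#' read (it is only needed to re-derive one parametrization from the other).
#'
#' @param bank An [item_bank()].
#' @param path File path.
#' @param D Scaling constant assumed when reading.
#' @return `write_item_bank()` returns `path` invisibly; `read_item_bank()`
#'   returns an [item_bank()].
#' @export
write_item_bank <- function(bank, path) {
  write.csv(as.data.frame(bank), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path, D = 1.701) {
  df <- read.csv(path)
  bcols <- grep("^b_", names(df), value = TRUE)
  item_bank(a = df$a, b = as.matrix(df[bcols]), D = D)
}
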