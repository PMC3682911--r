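#' General time-reversible model with gamma rate heterogeneity
#'
#' Constructs a GTR+Gamma nucleotide substitution model: base frequencies
#' `pi` (A, C, G, T), six exchangeabilities in the order AC, AG, AT, CG, CT,
#' GT (GT fixed to 1 by convention), a gamma shape `alpha` discretized into
#' `k` equal-weight categories (category means), and a per-partition rate
#' multiplier used in partitioned analyses.
#'
#' @param pi base frequencies, positive, summing to 1.
#' @param rates six positive exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param alpha gamma shape (> 0); `Inf` disables rate heterogeneity.
#' @param k number of discrete gamma categories (default 4).
#' @param rate_mult partition rate multiplier (default 1).
#' @return an object of class `gtr_model`.
#' @export
gtr_model <- function(pi = rep(0.25, 4),
                      rates = rep(1, 6),
                      alpha = 1, k = 4, rate_mult = 1) {
  pi <- as.numeric(pi); rates <- as.numeric(rates)
  if (length(pi) != 4 || any(pi <= 0)) stop("pi must be 4 positive frequencies")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (length(rates) != 6 || any(rates <= 0)) stop("rates must be 6 positive values")
  if (!is.infinite(alpha) && alpha <= 0) stop("alpha must be > 0")
  if (k < 1) stop("k must be >= 1")
  if (rate_mult <= 0) stop("rate_mult must be > 0")
  rates <- rates / rates[6] # GT = 1
  structure(list(pi = setNames(pi, c("A", "C", "G", "T")),
                 rates = setNames(rates, c("AC", "AG", "AT", "CG", "CT", "GT")),
                 alpha = alpha, k = as.integer(k), rate_mult = rate_mult),
            class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+Gamma model\n  pi:", sprintf("%.3f", x$pi), "\n  rates:",
      sprintf("%.3f", x$rates), "\n  alpha:", format(x$alpha),
      " k:", x$k, " rate multiplier:", format(x$rate_mult), "\n")
  invisible(x)
}

#' Build the normalized GTR rate matrix
#'
#' Off-diagonals are `Q[i, j] = r_ij * pi[j] * scale`, diagonals make rows sum
#' to zero, and the scale is chosen so the expected substitution rate at
#' stationarity is one (`-sum(pi * diag(Q)) == 1`), making branch lengths
#' expected substitutions per site.
#'
#' @param model a [gtr_model()].
#' @return a 4x4 rate matrix with A, C, G, T dimnames.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "gtr_model"))
  pi <- model$pi; r <- model$rates
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (e in seq_len(6)) {
    i <- idx[e, 1]; j <- idx[e, 2]
    Q[i, j] <- r[e] * pi[j]
    Q[j, i] <- r[e] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

# Eigensystem of the reversible Q via the symmetrized form
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)); returns V, Vinv, lambda with
# Q = V diag(lambda) Vinv, all real.
gtr_eigen <- function(model) {
  Q <- build_rate_matrix(model)
  sp <- sqrt(model$pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(V = diag(1 / sp) %*% es$vectors,
       Vinv = t(es$vectors) %*% diag(sp),
       lambda = es$values)
}

#' Discrete gamma category rates
#'
#' Mean rates of `k` equal-probability categories of a Gamma(alpha, alpha)
#' distribution (mean 1), the standard discretization for among-site rate
#' variation.
#'
#' @param alpha gamma shape; `Inf` gives a single rate of 1.
#' @param k number of categories.
#' @return numeric vector of `k` rates with mean 1.
#' @export
gamma_rates <- function(alpha, k = 4) {
  if (k == 1 || is.infinite(alpha)) return(rep(1, k))
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- pgamma(q, shape = alpha + 1, rate = alpha)
  r <- k * diff(p)
  r / mean(r) # guard against tail round-off
}

#' Transition probability matrix P(t)
#'
#' `P = exp(Q * rate * t)` computed from the eigendecomposition of the
#' reversible rate matrix (real spectrum), so `P(0) = I` and rows sum to 1.
#'
#' @param model a [gtr_model()].
#' @param t branch length (>= 0), expected substitutions per site.
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return 4x4 stochastic matrix.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be >= 0")
  es <- gtr_eigen(model)
  P <- es$V %*% diag(exp(es$lambda * rate * t)) %*% es$Vinv
  P[P < 0] <- 0
  dimnames(P) <- list(names(model$pi), names(model$pi))
  P
}

#' Pair substitution models with partitions
#'
#' A partitioned model shares one set of branch lengths across partitions and
#' gives each partition its own GTR+Gamma model plus a rate multiplier; the
#' multipliers are rescaled to mean 1 so the branch-length scale stays
#' identified.
#'
#' @param models a single [gtr_model()] (recycled) or a named list, one per
#'   partition.
#' @param genes character vector of partition names.
#' @return an object of class `partitioned_model` (named list of models).
#' @export
partitioned_model <- function(models, genes) {
  if (inherits(models, "gtr_model")) {
    models <- setNames(rep(list(models), length(genes)), genes)
  }
  stopifnot(length(models) == length(genes))
  names(models) <- genes
  mult <- vapply(models, function(m) m$rate_mult, 0)
  if (any(mult <= 0)) stop("rate multipliers must be positive")
  mult <- mult / mean(mult)
  for (i in seq_along(models)) models[[i]]$rate_mult <- mult[i]
  structure(models, class = "partitioned_model")
}

#' @export
print.partitioned_model <- function(x, ...) {
  cat("partitioned model over", length(x), "partitions:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
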