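#' Optimize branch lengths by iterated Brent sweeps
#'
#' One-dimensional (Brent) optimization of each branch in turn, holding the
#' others fixed, sweeping until the total log-likelihood improves by less
#' than `tol`. Lengths are bounded to `[1e-8, 10]` expected substitutions per
#' site. The log-likelihood never decreases across sweeps.
#'
#' @param tree a `phylo` with branch lengths (used as the starting point).
#' @param m a `supermatrix` or [compile_matrix()] object.
#' @param pm a [partitioned_model()] (or single [gtr_model()]).
#' @param tol stop when a full sweep improves lnL by less than this
#'   (default 0.01).
#' @param max_sweeps maximum sweeps (default 50); warns on non-convergence.
#' @param brent_tol x-tolerance of each univariate search.
#' @return the tree with optimized `edge.length` and the final lnL in
#'   `attr(, "lnL")`.
#' @export
optimize_branch_lengths <- function(tree, m, pm, tol = 0.01, max_sweeps = 50,
                                    brent_tol = 1e-4) {
  lld <- compile_matrix(m)
  pm <- as_partitioned(pm, names(lld$parts))
  prep <- prepare_models(pm)
  tr <- ape::reorder.phylo(tree, "postorder")
  info <- postorder_info(tr)
  res <- brlen_sweeps(info, lld, prep, tol, max_sweeps, brent_tol)
  tr$edge.length <- res$brlen
  attr(tr, "lnL") <- res$lnL
  tr
}

# In-place sweeps over a postorder info structure; returns brlen + lnL.
# The univariate search first looks in a window around the current length
# and widens to the full [1e-8, 10] range only when the optimum presses
# against the window edge.
brlen_sweeps <- function(info, lld, prep, tol, max_sweeps, brent_tol,
                         edges = seq_len(nrow(info$edge)), warn = TRUE) {
  cur <- lnl_eval(info, lld, prep)$lnL
  row_idx <- match(info$tips, lld$taxa)
  genes <- names(lld$parts)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    before <- cur
    for (e in edges) {
      old <- info$brlen[e]
      # one pruning pass per partition gives the exact 1-D likelihood
      # profile along this edge; each Brent evaluation is then cheap
      profs <- lapply(genes, function(g) {
        p <- lld$parts[[g]]
        mp <- prep[[g]]
        .cpp_edge_profile(info$edge, info$brlen, info$ntip, info$nnode,
                          p$states[row_idx, , drop = FALSE], mp$pi, mp$V,
                          mp$Vinv, mp$lambda, mp$rates, e)
      })
      f <- function(x) {
        tot <- 0
        for (gi in seq_along(genes)) {
          mp <- prep[[genes[gi]]]
          tot <- tot + .cpp_profile_lnl(profs[[gi]]$F, profs[[gi]]$G,
                                        profs[[gi]]$scale,
                                        lld$parts[[genes[gi]]]$weights,
                                        mp$V, mp$Vinv, mp$lambda, mp$rates, x)
        }
        tot
      }
      lo <- max(1e-8, old / 8); hi <- min(10, old * 8 + 1e-3)
      opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = brent_tol)
      if (opt$maximum < lo * 1.2 && lo > 1.5e-8) {
        opt <- optimize(f, c(1e-8, lo * 1.2), maximum = TRUE, tol = brent_tol)
      } else if (opt$maximum > hi * 0.9 && hi < 10) {
        opt <- optimize(f, c(hi * 0.9, 10), maximum = TRUE, tol = brent_tol)
      }
      if (opt$objective > cur) {
        info$brlen[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - before < tol) { converged <- TRUE; break }
  }
  if (!converged && warn) {
    warning("branch-length optimization did not converge in ", max_sweeps,
            " sweeps; returning best found")
  }
  list(brlen = info$brlen, lnL = cur, info = info)
}

#' Optimize substitution-model parameters on a fixed topology
#'
#' Coordinate ascent over, per partition: base frequencies (empirical by
#' default), the five free GTR exchangeabilities, the gamma shape, and the
#' partition rate multiplier. Multipliers are kept at mean one by absorbing
#' their scale into the shared branch lengths, so the reported
#' log-likelihood is never decreased by the renormalization. Degenerate
#' partitions (a single site pattern) keep their current model with a
#' warning; uniform data drive `alpha` to its upper bound (flagged with a
#' warning).
#'
#' @inheritParams optimize_branch_lengths
#' @param rounds coordinate-ascent rounds (default 2).
#' @param empirical_freq use empirical base frequencies (default `TRUE`);
#'   otherwise frequencies are kept as given.
#' @param alpha_bounds search interval for the gamma shape.
#' @return a list: `model` (the optimized `partitioned_model`), `tree` (with
#'   rescaled branch lengths), `lnL`.
#' @export
optimize_model <- function(tree, m, pm, rounds = 2, empirical_freq = TRUE,
                           alpha_bounds = c(0.02, 100)) {
  lld <- compile_matrix(m)
  pm <- as_partitioned(pm, names(lld$parts))
  tr <- ape::reorder.phylo(tree, "postorder")
  info <- postorder_info(tr)

  if (empirical_freq) {
    for (g in names(lld$parts)) {
      st <- lld$parts[[g]]$states
      w <- rep(lld$parts[[g]]$weights, each = nrow(st))
      counts <- vapply(0:3, function(s) sum(w[st == s]), 0)
      if (all(counts > 0)) {
        pm[[g]]$pi <- setNames(counts / sum(counts), c("A", "C", "G", "T"))
      }
    }
  }

  # coordinate ascent touches one partition at a time, so only that
  # partition's likelihood is re-evaluated
  part_lnl <- function(g, mod) {
    es <- gtr_eigen(mod)
    p <- lld$parts[[g]]
    row_idx <- match(info$tips, lld$taxa)
    .cpp_pruning_lnl(info$edge, info$brlen, info$ntip, info$nnode,
                     p$states[row_idx, , drop = FALSE], p$weights,
                     as.numeric(mod$pi), es$V, es$Vinv, es$lambda,
                     gamma_rates(mod$alpha, mod$k) * mod$rate_mult)$lnL
  }
  lnls <- vapply(names(pm), function(g) part_lnl(g, pm[[g]]), 0)
  for (round in seq_len(rounds)) {
    for (g in names(pm)) {
      p <- lld$parts[[g]]
      if (length(p$weights) < 2) {
        warning("partition ", g, " has a single site pattern; model fixed")
        next
      }
      # exchangeabilities (log scale, GT fixed at 1)
      fr <- function(lr) {
        mod <- pm[[g]]
        mod$rates <- setNames(c(exp(lr), 1), names(mod$rates))
        part_lnl(g, mod)
      }
      o <- optim(log(pm[[g]]$rates[1:5]), fr, method = "L-BFGS-B",
                 lower = log(1e-4), upper = log(1e4),
                 control = list(fnscale = -1, maxit = 25, factr = 1e10))
      if (o$value > lnls[g]) {
        pm[[g]]$rates <- setNames(c(exp(o$par), 1), names(pm[[g]]$rates))
        lnls[g] <- o$value
      }
      # gamma shape
      fa <- function(la) {
        mod <- pm[[g]]
        mod$alpha <- exp(la)
        part_lnl(g, mod)
      }
      oa <- optimize(fa, log(alpha_bounds), maximum = TRUE, tol = 1e-3)
      if (oa$objective > lnls[g]) {
        pm[[g]]$alpha <- exp(oa$maximum)
        lnls[g] <- oa$objective
      }
      if (pm[[g]]$alpha > 0.98 * alpha_bounds[2]) {
        warning("gamma shape for partition ", g,
                " pinned at its upper bound (no detectable rate variation)")
      }
      # partition rate multiplier
      if (length(pm) > 1) {
        fm <- function(lm) {
          mod <- pm[[g]]
          mod$rate_mult <- exp(lm)
          part_lnl(g, mod)
        }
        om <- optimize(fm, log(c(0.02, 50)), maximum = TRUE, tol = 1e-3)
        if (om$objective > lnls[g]) {
          pm[[g]]$rate_mult <- exp(om$maximum)
          lnls[g] <- om$objective
        }
      }
    }
  }
  cur <- sum(lnls)
  # renormalize multipliers to mean 1, absorbing the scale into branch lengths
  mult <- vapply(pm, function(x) x$rate_mult, 0)
  scale <- mean(mult)
  for (g in names(pm)) pm[[g]]$rate_mult <- mult[g] / scale
  tr$edge.length <- pmin(pmax(tr$edge.length * scale, 1e-8), 10)
  list(model = pm, tree = tr, lnL = cur)
}
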