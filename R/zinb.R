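#' @title Zero-inflated negative binomial assessment and observation weights
#' @name zinb
#' @description Plate screens with limited input material often show more
#'   zeros than a negative binomial (NB) predicts. This module fits per-gene
#'   NB models, quantifies excess zeros, and estimates observation-level
#'   weights under a per-gene zero-inflated NB (ZINB) mixture by EM. The
#'   weights (1 for every positive count, the posterior probability of the
#'   NB component for zeros) plug into the weighted differential-expression
#'   engines.
NULL

THETA_FLOOR <- 1e-3
THETA_CAP <- 1e6

# Vectorised Newton update of per-group means on the log scale.
# counts: genes x wells; sf: per-well size factors; grp: factor over wells;
# w: weight matrix; theta: per-gene vector. Returns genes x nlevels matrix m
# with fitted mean mu[g, j] = sf[j] * m[g, grp[j]].
update_group_means <- function(counts, sf, grp, w, theta, m = NULL,
                               iter = 8L) {
  G <- nrow(counts); lev <- levels(grp)
  if (is.null(m)) {
    m <- vapply(lev, function(g) {
      j <- which(grp == g)
      num <- (w[, j, drop = FALSE] * sweep(counts[, j, drop = FALSE], 2, sf[j], "/")) |> rowSums()
      den <- rowSums(w[, j, drop = FALSE])
      pmax(num / pmax(den, 1e-12), 1e-8)
    }, numeric(G))
    m <- matrix(m, nrow = G, dimnames = list(NULL, lev))
  }
  for (g in seq_along(lev)) {
    j <- which(grp == lev[g])
    yj <- counts[, j, drop = FALSE]
    wj <- w[, j, drop = FALSE]
    for (it in seq_len(iter)) {
      mu <- m[, g] %o% sf[j]
      r <- theta / (theta + mu)
      score <- rowSums(wj * (yj - mu) * r)           # d loglik / d log m
      info <- rowSums(wj * mu * r)                   # expected information
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -2), 2)
      m[, g] <- pmax(m[, g] * exp(step), 1e-10)
      if (max(abs(step)) < 1e-10) break
    }
  }
  m
}

# Weighted NB log-likelihood per gene; mu genes x wells.
nb_loglik_rows <- function(counts, mu, theta, w) {
  ll <- dnbinom(counts, size = theta, mu = pmax(mu, 1e-12), log = TRUE)
  rowSums(w * ll)
}

# Damped vectorised Newton steps for per-gene theta on the log scale.
update_theta <- function(counts, mu, theta, w, iter = 8L) {
  u <- log(theta)
  for (it in seq_len(iter)) {
    th <- exp(u)
    mus <- pmax(mu, 1e-12)
    # d loglik / d theta, summed with weights
    dth <- digamma(counts + th) - digamma(th) + log(th) + 1 -
      log(th + mus) - (th + counts) / (th + mus)
    score <- rowSums(w * dth) * th                  # chain rule to log scale
    d2 <- trigamma(counts + th) - trigamma(th) + 1 / th -
      2 / (th + mus) + (th + counts) / (th + mus)^2
    hess <- rowSums(w * d2) * th^2 + score
    step <- score / pmax(abs(hess), 1e-8)
    step <- pmin(pmax(step, -1), 1)
    # damped ascent: fall back to a scaled step when the likelihood drops
    ll_old <- nb_loglik_rows(counts, mu, exp(u), w)
    u_new <- pmin(pmax(u + step, log(THETA_FLOOR)), log(THETA_CAP))
    ll_new <- nb_loglik_rows(counts, mu, exp(u_new), w)
    bad <- which(ll_new < ll_old - 1e-10)
    if (length(bad)) {
      u_half <- u
      u_half[bad] <- pmin(pmax(u[bad] + step[bad] / 4, log(THETA_FLOOR)),
                          log(THETA_CAP))
      ll_half <- nb_loglik_rows(counts[bad, , drop = FALSE],
                                mu[bad, , drop = FALSE],
                                exp(u_half[bad]), w[bad, , drop = FALSE])
      worse <- ll_half < ll_old[bad]
      u_new[bad] <- ifelse(worse, u[bad], u_half[bad])
    }
    if (max(abs(u_new - u)) < 1e-10) { u <- u_new; break }
    u <- u_new
  }
  exp(u)
}

#' Fit per-gene negative binomial models
#'
#' Group means are maximum-likelihood estimates of size-factor-scaled
#' counts; the per-gene NB size `theta` (dispersion = 1/theta) is estimated
#' by Newton ascent of the profile log-likelihood, floored at 1e-3 and
#' capped at 1e6. All-zero genes are flagged and excluded from downstream
#' weighting.
#'
#' @param counts Count matrix (genes x wells), `count_matrix` or `Screen`.
#' @param size_factors Per-well size factors (default: library size scaled
#'   to mean 1).
#' @param grouping Factor over wells (default: one group).
#' @return An `nb_fit`: `mu` (genes x wells fitted means), `group_means`,
#'   `theta`, `loglik`, `all_zero` flags, `grouping`, `size_factors`.
#' @export
fit_nb <- function(counts, size_factors = NULL, grouping = NULL) {
  y <- as_count_values(counts)
  n <- ncol(y)
  if (is.null(size_factors)) {
    ls <- colSums(y)
    size_factors <- if (all(ls > 0)) ls / mean(ls) else rep(1, n)
  }
  grp <- if (is.null(grouping)) factor(rep("all", n)) else factor(grouping)
  if (any(table(grp) < 2)) stop("each group needs at least 2 wells")
  all_zero <- rowSums(y) == 0
  w <- matrix(1, nrow(y), n)
  theta <- rep(10, nrow(y))
  m <- update_group_means(y, size_factors, grp, w, theta)
  for (round in 1:3) {
    mu <- m[, as.integer(grp), drop = FALSE] * rep(size_factors, each = nrow(y))
    theta <- update_theta(y, mu, theta, w)
    m <- update_group_means(y, size_factors, grp, w, theta, m = m)
  }
  mu <- m[, as.integer(grp), drop = FALSE] * rep(size_factors, each = nrow(y))
  theta[all_zero] <- NA_real_
  structure(list(mu = mu, group_means = m, theta = theta,
                 loglik = nb_loglik_rows(y, mu, ifelse(is.na(theta), 1, theta), w),
                 all_zero = all_zero, grouping = grp,
                 size_factors = size_factors, gene_ids = rownames(y)),
            class = "nb_fit")
}

#' Assess zero inflation against a fitted NB
#'
#' Per gene: the observed zero fraction, the expected zero fraction under
#' the fitted NB (`mean_j (theta/(theta+mu_j))^theta`), and their
#' difference (excess zeros). The screen-level summary is the mean excess
#' over genes; values near zero indicate the NB is adequate.
#'
#' @param counts Count matrix used for the fit.
#' @param nbfit An [fit_nb()] result.
#' @return `data.frame` per gene plus attribute `mean_excess`.
#' @export
zero_inflation_assessment <- function(counts, nbfit) {
  y <- as_count_values(counts)
  obs <- rowMeans(y == 0)
  th <- nbfit$theta
  p0 <- matrix(NA_real_, nrow(y), ncol(y))
  ok <- !is.na(th)
  p0[ok, ] <- (th[ok] / (th[ok] + nbfit$mu[ok, , drop = FALSE]))^th[ok]
  expd <- rowMeans(p0)
  expd[nbfit$all_zero] <- 1
  excess <- obs - expd
  out <- data.frame(gene_id = nbfit$gene_ids %||% seq_len(nrow(y)),
                    observed_zero_fraction = obs,
                    expected_zero_fraction = expd,
                    excess_zero_fraction = excess, row.names = NULL)
  attr(out, "mean_excess") <- mean(excess, na.rm = TRUE)
  out
}

#' Posterior NB weight of a zero observation
#'
#' Under the ZINB mixture, a zero observation belongs to the NB component
#' with posterior probability `w = (1 - pi) * NB0 / (pi + (1 - pi) * NB0)`
#' where `NB0 = (theta / (theta + mu))^theta` is the NB probability of a
#' zero; `1 - w` is the dropout responsibility. As `mu -> 0`, `NB0 -> 1`
#' and `w -> 1 - pi` (an uninformative zero); for large `mu`, `w -> 0`
#' (near-certain dropout).
#'
#' @param mu NB mean(s).
#' @param theta NB size(s).
#' @param pi Zero-inflation probability.
#' @return Weight(s) in [0, 1].
#' @export
zinb_zero_weight <- function(mu, theta, pi) {
  nb0 <- (theta / (theta + pmax(mu, 0)))^theta
  (1 - pi) * nb0 / (pi + (1 - pi) * nb0)
}

#' Estimate ZINB observation weights by per-gene EM
#'
#' Per gene, a two-component mixture of a point mass at zero (probability
#' `pi`) and an NB with group means and size `theta` is fitted by EM:
#' the E-step assigns every zero its dropout responsibility
#' `z = pi / (pi + (1 - pi) * NB0)` with `NB0 = (theta/(theta+mu))^theta`;
#' the M-step updates `pi` as the mean of `z` (zero for positive counts)
#' and re-estimates means and `theta` on `1 - z` weighted data. The
#' returned weights are `1 - z` for zero observations and exactly 1 for
#' positive ones. Iterations whose observed-data log-likelihood would
#' decrease are reverted and the gene frozen, so the reported
#' log-likelihood path is non-decreasing.
#'
#' @param counts Count matrix (genes x wells), `count_matrix` or `Screen`.
#' @param size_factors Per-well size factors (default library size, mean 1).
#' @param grouping Factor over wells (default one group).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the per-gene log-likelihood change.
#' @return A `zinb_fit`: `pi`, `theta`, `group_means`, `mu`, `loglik`,
#'   `loglik_trace`, `converged`, `iterations`, plus `weights`
#'   (genes x wells in [0, 1], 1 wherever the count is positive).
#' @export
estimate_zinb_weights <- function(counts, size_factors = NULL, grouping = NULL,
                                  max_iter = 100L, tol = 1e-4) {
  y <- as_count_values(counts)
  G <- nrow(y); n <- ncol(y)
  if (is.null(size_factors)) {
    ls <- colSums(y)
    size_factors <- if (all(ls > 0)) ls / mean(ls) else rep(1, n)
  }
  grp <- if (is.null(grouping)) factor(rep("all", n)) else factor(grouping)
  all_zero <- rowSums(y) == 0
  is0 <- y == 0

  nb0fit <- fit_nb(y, size_factors, grp)
  m <- nb0fit$group_means
  theta <- ifelse(is.na(nb0fit$theta), 10, nb0fit$theta)
  pi_g <- pmin(pmax(rowMeans(is0) * 0.5, 1e-4), 0.9)

  obs_loglik <- function(m, theta, pi_g) {
    mu <- m[, as.integer(grp), drop = FALSE] * rep(size_factors, each = G)
    nb <- dnbinom(y, size = theta, mu = pmax(mu, 1e-12), log = TRUE)
    ll <- log(1 - pi_g) + nb
    nb0 <- (theta / (theta + pmax(mu, 1e-12)))^theta
    llz <- log(pi_g + (1 - pi_g) * nb0)
    rowSums(ifelse(is0, llz, ll))
  }

  ll <- obs_loglik(m, theta, pi_g)
  trace <- matrix(NA_real_, G, max_iter + 1); trace[, 1] <- ll
  active <- !all_zero
  iters <- rep(0L, G); converged <- all_zero  # all-zero genes trivially done
  z <- matrix(0, G, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    mu <- m[, as.integer(grp), drop = FALSE] * rep(size_factors, each = G)
    z_new <- matrix(0, G, n)
    z_new[is0] <- (1 - zinb_zero_weight(pmax(mu, 1e-12), theta, pi_g))[is0]
    pi_new <- rowMeans(z_new)
    w <- 1 - z_new
    m_new <- update_group_means(y, size_factors, grp, w, theta, m = m, iter = 4L)
    mu_new <- m_new[, as.integer(grp), drop = FALSE] * rep(size_factors, each = G)
    theta_new <- update_theta(y, mu_new, theta, w, iter = 4L)
    ll_new <- obs_loglik(m_new, theta_new, pi_new)
    improved <- active & (ll_new >= ll - 1e-8)
    # revert genes whose likelihood would drop; they are converged
    frozen <- active & !improved
    upd <- improved
    pi_g[upd] <- pi_new[upd]; m[upd, ] <- m_new[upd, , drop = FALSE]
    theta[upd] <- theta_new[upd]
    z[upd, ] <- z_new[upd, , drop = FALSE]
    delta <- abs(ll_new - ll)
    ll[upd] <- ll_new[upd]
    trace[, it + 1] <- ll
    iters[active] <- it
    done <- active & (frozen | delta < tol)
    converged <- converged | done
    active <- active & !done
  }
  if (any(!converged & !all_zero))
    warning(sprintf("%d gene(s) did not converge in %d EM iterations",
                    sum(!converged & !all_zero), max_iter))
  weights <- 1 - z
  weights[y > 0] <- 1
  weights[all_zero, ] <- 1
  pi_g[all_zero] <- NA_real_; theta[all_zero] <- NA_real_
  mu <- m[, as.integer(grp), drop = FALSE] * rep(size_factors, each = G)
  dimnames(weights) <- dimnames(y)
  structure(list(pi = pi_g, theta = theta, group_means = m, mu = mu,
                 loglik = ll, loglik_trace = trace[, seq_len(min(max_iter, max(iters)) + 1), drop = FALSE],
                 converged = converged, iterations = iters,
                 all_zero = all_zero, weights = weights,
                 grouping = grp, size_factors = size_factors),
            class = "zinb_fit")
}
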