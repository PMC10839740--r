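# Metropolis-within-Gibbs sampler for the per-region hierarchical linear
# model with batch-specific intercepts, slopes and residual log-SDs:
#
#   y_i = alpha_b(i) + beta_b(i) * x_i + eps_i,   eps_i ~ N(0, sigma_b(i)^2)
#   alpha_b ~ N(mu_alpha, tau_alpha^2)
#   beta_b  ~ N(mu_beta,  tau_beta^2)
#   log sigma_b ~ N(mu_logsigma, tau_logsigma^2)
#
# with Normal hyperpriors on the mu's and half-normal or zero-truncated
# Normal hyperpriors on the tau's. All batch updates operate on per-batch
# sufficient statistics, so iteration cost is O(#batches), not O(#rows):
# (alpha_b, beta_b) jointly conjugate bivariate normal (vectorized across
# batches); log sigma_b by vectorized random-walk Metropolis with step-size
# adaptation during warmup; mu's conjugate; tau's by slice sampling on the
# log scale. Empty batches are legal and then sampled from the hierarchy
# (prior-only posterior).

hyper_names <- c("mu_alpha", "tau_alpha", "mu_beta", "tau_beta",
                 "mu_logsigma", "tau_logsigma")

# log prior density for a tau-type hyperparameter, up to a constant
tau_logprior <- function(t, pr) {
  switch(pr$dist,
    halfnormal = -t^2 / (2 * pr$scale^2),
    truncnormal = -(t - pr$location)^2 / (2 * pr$scale^2),
    stop("unsupported tau prior: ", pr$dist)
  )
}

# univariate slice sampler (stepping out + shrinkage), Neal (2003)
slice_sample1 <- function(x0, logf, w = 1, m = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(m * stats::runif(1))
  k <- m - 1 - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

batch_suffstats <- function(x, y, batch_idx, B) {
  n <- tabulate(batch_idx, B)
  full <- matrix(0, B, 5)
  if (length(x) > 0) {
    M <- rowsum(cbind(x, x^2, y, x * y, y^2), batch_idx)
    full[as.integer(rownames(M)), ] <- M
  }
  list(n = as.numeric(n), Sx = full[, 1], Sxx = full[, 2],
       Sy = full[, 3], Sxy = full[, 4], Syy = full[, 5])
}

# residual sum of squares per batch from sufficient statistics
batch_sse <- function(ss, a, b) {
  pmax(ss$Syy - 2 * a * ss$Sy - 2 * b * ss$Sxy + 2 * a * b * ss$Sx +
         a^2 * ss$n + b^2 * ss$Sxx, 0)
}

run_hbr_chain <- function(ss, B, priors, control, chain_seed,
                          freeze_hypers = FALSE) {
  set.seed(chain_seed)
  warmup <- control$warmup
  iter <- control$iter
  n_tot <- warmup + iter

  # --- initialization -------------------------------------------------------
  a <- numeric(B); b <- numeric(B); ls <- numeric(B)
  mu_a <- priors$mu_alpha$location
  mu_b <- priors$mu_beta$location
  mu_ls <- priors$mu_logsigma$location
  t_a <- tau_init(priors$tau_alpha)
  t_b <- tau_init(priors$tau_beta)
  t_ls <- tau_init(priors$tau_logsigma)
  for (bb in seq_len(B)) {
    if (ss$n[bb] >= 3) {
      d <- ss$n[bb] * ss$Sxx[bb] - ss$Sx[bb]^2
      if (d > 1e-10) {
        b[bb] <- (ss$n[bb] * ss$Sxy[bb] - ss$Sx[bb] * ss$Sy[bb]) / d
        a[bb] <- (ss$Sy[bb] - b[bb] * ss$Sx[bb]) / ss$n[bb]
      } else {
        b[bb] <- mu_b; a[bb] <- ss$Sy[bb] / ss$n[bb]
      }
      sse <- batch_sse(ss, a, b)[bb]
      ls[bb] <- 0.5 * log(max(sse / max(ss$n[bb] - 2, 1), 1e-8))
    } else {
      a[bb] <- mu_a; b[bb] <- mu_b; ls[bb] <- mu_ls
    }
  }
  if (!freeze_hypers && B > 1) {
    mu_a <- mean(a); mu_b <- mean(b); mu_ls <- mean(ls)
    t_a <- max(stats::sd(a), 1e-3)
    t_b <- max(stats::sd(b), 1e-3)
    t_ls <- max(stats::sd(ls), 1e-3)
  }

  step_ls <- rep(0.3, B)
  acc_ls <- rep(0, B)

  P <- 3 * B + 6
  draws <- matrix(NA_real_, iter, P)

  for (it in seq_len(n_tot)) {
    s2 <- exp(2 * ls)

    # (alpha_b, beta_b) joint conjugate update, vectorized over batches
    P11 <- ss$n / s2 + 1 / t_a^2
    P12 <- ss$Sx / s2
    P22 <- ss$Sxx / s2 + 1 / t_b^2
    r1 <- ss$Sy / s2 + mu_a / t_a^2
    r2 <- ss$Sxy / s2 + mu_b / t_b^2
    det <- P11 * P22 - P12^2
    m_a <- (P22 * r1 - P12 * r2) / det
    m_b <- (P11 * r2 - P12 * r1) / det
    # Cholesky of the 2x2 covariance (inverse precision)
    c11 <- sqrt(P22 / det)
    c21 <- -P12 / det / c11
    c22 <- sqrt(pmax(P11 / det - c21^2, 0))
    z1 <- stats::rnorm(B); z2 <- stats::rnorm(B)
    a <- m_a + c11 * z1
    b <- m_b + c21 * z1 + c22 * z2

    # log sigma_b random-walk Metropolis, vectorized across batches; a few
    # sub-steps per scan since this is the slowest-mixing block
    sse <- batch_sse(ss, a, b)
    lp_cur <- -ss$n * ls - sse / (2 * exp(2 * ls)) - (ls - mu_ls)^2 / (2 * t_ls^2)
    for (k in 1:3) {
      prop <- ls + step_ls * stats::rnorm(B)
      lp_prop <- -ss$n * prop - sse / (2 * exp(2 * prop)) -
        (prop - mu_ls)^2 / (2 * t_ls^2)
      acc <- log(stats::runif(B)) < (lp_prop - lp_cur)
      ls[acc] <- prop[acc]
      lp_cur[acc] <- lp_prop[acc]
      acc_ls <- acc_ls + acc
    }
    if (it <= warmup && it %% control$adapt_interval == 0) {
      rate <- acc_ls / (3 * control$adapt_interval)
      step_ls <- pmin(pmax(step_ls * exp(rate - 0.44), 1e-3), 5)
      acc_ls <- rep(0, B)
    }

    if (!freeze_hypers) {
      # conjugate mu updates
      mu_a <- draw_mu(a, t_a, priors$mu_alpha)
      mu_b <- draw_mu(b, t_b, priors$mu_beta)
      mu_ls <- draw_mu(ls, t_ls, priors$mu_logsigma)
      # tau updates by slice sampling on log tau
      t_a <- draw_tau(a - mu_a, t_a, priors$tau_alpha)
      t_b <- draw_tau(b - mu_b, t_b, priors$tau_beta)
      t_ls <- draw_tau(ls - mu_ls, t_ls, priors$tau_logsigma)

      # ancillarity-sufficiency interweaving: re-draw (mu, tau) under the
      # non-centered parameterization to break the hierarchical funnel
      s2 <- exp(2 * ls)
      iw <- interweave_linear(
        eta = (a - mu_a) / max(t_a, 1e-10),
        wgt = ss$n / s2, rhs = (ss$Sy - b * ss$Sx) / s2,
        mu_pr = priors$mu_alpha, tau_pr = priors$tau_alpha,
        mu = mu_a, tau = t_a)
      mu_a <- iw$mu; t_a <- iw$tau; a <- mu_a + t_a * iw$eta

      iw <- interweave_linear(
        eta = (b - mu_b) / max(t_b, 1e-10),
        wgt = ss$Sxx / s2, rhs = (ss$Sxy - a * ss$Sx) / s2,
        mu_pr = priors$mu_beta, tau_pr = priors$tau_beta,
        mu = mu_b, tau = t_b)
      mu_b <- iw$mu; t_b <- iw$tau; b <- mu_b + t_b * iw$eta

      sse <- batch_sse(ss, a, b)
      iw <- interweave_logsigma(
        eta = (ls - mu_ls) / max(t_ls, 1e-10),
        n = ss$n, sse = sse,
        mu_pr = priors$mu_logsigma, tau_pr = priors$tau_logsigma,
        mu = mu_ls, tau = t_ls)
      mu_ls <- iw$mu; t_ls <- iw$tau; ls <- mu_ls + t_ls * iw$eta
    }

    if (it > warmup) {
      draws[it - warmup, ] <- c(a, b, ls, mu_a, t_a, mu_b, t_b, mu_ls, t_ls)
    }
  }
  draws
}

tau_init <- function(pr) {
  if (pr$dist == "truncnormal") max(pr$location, pr$scale / 2, 1e-6)
  else max(pr$scale / 2, 1e-6)
}

draw_mu <- function(v, tau, pr) {
  B <- length(v)
  prec <- B / tau^2 + 1 / pr$scale^2
  mean_post <- (sum(v) / tau^2 + pr$location / pr$scale^2) / prec
  stats::rnorm(1, mean_post, sqrt(1 / prec))
}

# Non-centered (mu, tau) redraw for a Gaussian-likelihood level. Writing the
# batch parameter as theta_b = mu + tau * eta_b with eta fixed, the data
# contribute a Gaussian likelihood linear in (mu, tau):
#   sum_b [ -wgt_b/2 * (mu + tau*eta_b)^2 + rhs_b * (mu + tau*eta_b) ]
# (wgt_b, rhs_b are the batch's precision-weighted moments), so (mu, tau)
# are jointly Gaussian. A half-normal tau prior is the t>0 fold of a
# Normal(0, s), so a sign flip of (tau, eta) maps the unconstrained draw
# back legally; for a zero-truncated Normal prior we draw until tau > 0.
interweave_linear <- function(eta, wgt, rhs, mu_pr, tau_pr, mu, tau) {
  A11 <- sum(wgt) + 1 / mu_pr$scale^2
  A12 <- sum(wgt * eta)
  A22 <- sum(wgt * eta^2) + 1 / tau_pr$scale^2
  b1 <- sum(rhs) + mu_pr$location / mu_pr$scale^2
  b2 <- sum(rhs * eta) + tau_pr$location / tau_pr$scale^2
  det <- A11 * A22 - A12^2
  if (det <= 0) return(list(mu = mu, tau = tau, eta = eta))
  m1 <- (A22 * b1 - A12 * b2) / det
  m2 <- (A11 * b2 - A12 * b1) / det
  c11 <- sqrt(A22 / det)
  c21 <- -A12 / det / c11
  c22 <- sqrt(max(A11 / det - c21^2, 0))
  for (try in 1:50) {
    z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
    mu_new <- m1 + c11 * z1
    tau_new <- m2 + c21 * z1 + c22 * z2
    if (tau_pr$dist == "halfnormal" && tau_new < 0) {
      tau_new <- -tau_new
      eta <- -eta
    }
    if (tau_new > 0) return(list(mu = mu_new, tau = tau_new, eta = eta))
  }
  list(mu = mu, tau = tau, eta = eta)  # keep state if truncation never met
}

# Same interweaving for the log-sigma level, whose likelihood in
# ls_b = mu + tau * eta_b is non-Gaussian; mu and log(tau) are slice-sampled.
interweave_logsigma <- function(eta, n, sse, mu_pr, tau_pr, mu, tau) {
  loglik <- function(m, t) {
    lsb <- m + t * eta
    sum(-n * lsb - sse / (2 * exp(2 * lsb)))
  }
  mu <- slice_sample1(mu, function(m) {
    loglik(m, tau) - (m - mu_pr$location)^2 / (2 * mu_pr$scale^2)
  }, w = 0.3)
  u <- slice_sample1(log(max(tau, 1e-10)), function(u) {
    t <- exp(u)
    loglik(mu, t) + tau_logprior(t, tau_pr) + u
  }, w = 0.5)
  list(mu = mu, tau = exp(u), eta = eta)
}

draw_tau <- function(dev, t_cur, pr) {
  B <- length(dev)
  S <- sum(dev^2)
  logf <- function(u) {
    t <- exp(u)
    -B * u - S / (2 * t^2) + tau_logprior(t, pr) + u
  }
  exp(slice_sample1(log(max(t_cur, 1e-8)), logf, w = 0.8))
}

# split-chain potential scale reduction factor
split_rhat <- function(chain_list) {
  halves <- list()
  for (d in chain_list) {
    l <- floor(nrow(d) / 2)
    halves <- c(halves, list(d[seq_len(l), , drop = FALSE],
                             d[l + seq_len(l), , drop = FALSE]))
  }
  l <- nrow(halves[[1]])
  P <- ncol(halves[[1]])
  means <- vapply(halves, colMeans, numeric(P))
  vars <- vapply(halves, function(h) apply(h, 2, stats::var), numeric(P))
  if (P == 1) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  W <- rowMeans(vars)
  Bv <- l * apply(means, 1, stats::var)
  out <- sqrt(((l - 1) / l * W + Bv / l) / W)
  out[!is.finite(out) | W < 1e-12] <- 1
  out
}

# Fit one region: returns draws (combined), per-chain list, diagnostics.
fit_hbr_roi <- function(x, y, batch_idx, batch_keys, priors, control,
                        freeze_hypers = FALSE) {
  B <- length(batch_keys)
  ss <- batch_suffstats(x, y, batch_idx, B)
  chains <- lapply(seq_len(control$chains), function(ch) {
    run_hbr_chain(ss, B, priors, control,
                  chain_seed = derive_seed(control$seed, 100L + ch),
                  freeze_hypers = freeze_hypers)
  })
  draws <- do.call(rbind, chains)
  colnames(draws) <- c(paste0("alpha[", batch_keys, "]"),
                       paste0("beta[", batch_keys, "]"),
                       paste0("ls[", batch_keys, "]"),
                       hyper_names)
  rhat <- if (control$chains >= 1 && control$iter >= 4) {
    stats::setNames(split_rhat(chains), colnames(draws))
  } else {
    stats::setNames(rep(NA_real_, ncol(draws)), colnames(draws))
  }
  # batch summaries feeding predict(): means, 2x2 covariance of (alpha, beta),
  # posterior mean noise variance
  ia <- seq_len(B); ib <- B + ia; il <- 2 * B + ia
  m_alpha <- colMeans(draws[, ia, drop = FALSE])
  m_beta <- colMeans(draws[, ib, drop = FALSE])
  v_alpha <- apply(draws[, ia, drop = FALSE], 2, stats::var)
  v_beta <- apply(draws[, ib, drop = FALSE], 2, stats::var)
  cov_ab <- vapply(seq_len(B), function(bb)
    stats::cov(draws[, ia[bb]], draws[, ib[bb]]), 0)
  mean_sig2 <- colMeans(exp(2 * draws[, il, drop = FALSE]))
  mean_sigma <- colMeans(exp(draws[, il, drop = FALSE]))
  batch_summ <- data.frame(
    batch = batch_keys, n = ss$n,
    alpha_mean = as.numeric(m_alpha), beta_mean = as.numeric(m_beta),
    alpha_var = as.numeric(v_alpha), beta_var = as.numeric(v_beta),
    alphabeta_cov = as.numeric(cov_ab),
    sigma2_mean = as.numeric(mean_sig2), sigma_mean = as.numeric(mean_sigma),
    stringsAsFactors = FALSE
  )
  hy <- draws[, 3 * B + seq_len(6), drop = FALSE]
  hyper_summ <- data.frame(
    hyper = hyper_names,
    mean = as.numeric(colMeans(hy)),
    sd = as.numeric(apply(hy, 2, stats::sd)),
    stringsAsFactors = FALSE
  )
  list(draws = draws, batch = batch_summ, hyper = hyper_summ,
       rhat = rhat, converged = all(is.na(rhat) | rhat < 1.05))
}
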