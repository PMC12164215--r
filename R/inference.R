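#' Specify a Bayesian mixed model
#'
#' A model specification holds the outcome column, likelihood, fixed-effect
#' formula over the sum-to-zero +/-1 contrast columns (see
#' [contrast_codes()]), and the random-effect structure as a named list
#' mapping grouping columns to covariate terms (`"1"` for a random
#' intercept; other entries name contrast columns or `:`-products of them,
#' giving independent random slopes).
#'
#' @param outcome outcome column name.
#' @param fixed one-sided formula of population-level terms, e.g.
#'   `~ group_c * dyad_type_c * ips_c`.
#' @param random named list, e.g.
#'   `list(participant_id = "1", dyad_id = "1")` or
#'   `list(participant_id = c("1", "ips_c"), dyad_id = "1")`.
#' @param likelihood `"gaussian"` (identity link, residual sigma) or
#'   `"poisson"` (log link).
#' @param priors optional named list overriding `beta_scale` (multiplier on
#'   SD(outcome) for coefficient priors), `sd_scale` (half-t scale for
#'   random-effect SDs) or `sigma_rate` (exponential rate for sigma).
#' @param chains,draws,warmup sampler settings (post-warmup kept draws per
#'   chain; `draws * thin` iterations are run).
#' @param thin thinning interval (default 1).
#' @param seed integer seed.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome, fixed, random = list(), likelihood = c("gaussian", "poisson"),
                       priors = list(), chains = 3, draws = 1000, warmup = 1000,
                       thin = 1, seed = 1) {
  likelihood <- match.arg(likelihood)
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 likelihood = likelihood, priors = priors, chains = chains,
                 draws = draws, warmup = warmup, thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "model_spec")
}

re_covariate <- function(table, term) {
  if (term == "1") return(rep(1, nrow(table)))
  cols <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (!all(cols %in% names(table))) {
    stop(sprintf("random term '%s': column not found", term), call. = FALSE)
  }
  Reduce(`*`, table[cols])
}

build_jags_code <- function(likelihood, has_proj) {
  n_terms <- length(has_proj)
  re_eta <- if (n_terms > 0) {
    paste0(vapply(seq_len(n_terms), function(k) {
      sprintf(" + u%d[g%d[i]] * z%d[i]", k, k, k)
    }, character(1)), collapse = "")
  } else ""
  lik <- if (likelihood == "gaussian") {
    "y[i] ~ dnorm(eta[i], tau)"
  } else {
    "y[i] ~ dpois(exp(eta[i]))"
  }
  # Identifiability: a random-effect term's level effects are confounded with
  # any fixed-effect column expressible through the term (the intercept, a
  # level-constant factor code). The effective effects entering the linear
  # predictor are projected onto the orthogonal complement of those columns;
  # the free directions are prior-only and mix instantly, the betas stay
  # fully identified.
  re_priors <- if (n_terms > 0) {
    paste0(vapply(seq_len(n_terms), function(k) {
      if (has_proj[k]) {
        sprintf(paste0(
          "  for (l in 1:L%d) { uraw%d[l] ~ dnorm(0, tau_u%d) }\n",
          "  for (j in 1:Q%d) { gam%d[j] <- inprod(PROJ%d[j,], uraw%d) }\n",
          "  for (l in 1:L%d) { u%d[l] <- uraw%d[l] - inprod(M%d[l,], gam%d) }\n",
          "  tau_u%d ~ dgamma(0.5, sd_prior_rate)\n",
          "  sd_u%d <- 1 / sqrt(tau_u%d)\n"),
          k, k, k, k, k, k, k, k, k, k, k, k, k, k, k)
      } else {
        sprintf(paste0(
          "  for (l in 1:L%d) { u%d[l] ~ dnorm(0, tau_u%d) }\n",
          "  tau_u%d ~ dgamma(0.5, sd_prior_rate)\n",
          "  sd_u%d <- 1 / sqrt(tau_u%d)\n"), k, k, k, k, k, k)
      }
    }, character(1)), collapse = "")
  } else ""
  resid <- if (likelihood == "gaussian") {
    "  sigma ~ dexp(sigma_rate)\n  tau <- pow(sigma, -2)\n"
  } else ""
  sprintf(paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    eta[i] <- inprod(X[i,], beta)%s\n",
    "    %s\n",
    "  }\n",
    "  for (j in 1:P) { beta[j] ~ dnorm(beta_mean[j], beta_prec[j]) }\n",
    "%s%s}\n"), re_eta, lik, re_priors, resid)
}

# Rank-normalized split-R-hat (Vehtari et al. 2021): robust to the skewed
# posteriors of variance parameters. x: iterations x chains matrix.
split_rank_rhat <- function(x) {
  n2 <- floor(nrow(x) / 2)
  if (n2 < 2) return(NA_real_)
  halves <- cbind(x[1:n2, , drop = FALSE], x[(n2 + 1):(2 * n2), , drop = FALSE])
  r <- matrix(rank(halves, ties.method = "average"), nrow = n2)
  z <- stats::qnorm((r - 0.375) / (length(halves) + 0.25))
  mj <- colMeans(z); vj <- apply(z, 2, stats::var)
  B <- n2 * stats::var(mj); W <- mean(vj)
  if (W <= 0) return(1)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

# Fixed-effect columns expressible through a random term: X[, j] equals
# z * m(level) for some per-level constant m. Returns NULL or the per-level
# design M (levels x q) with its projection matrix.
term_projection <- function(X, tk) {
  M <- NULL
  cols <- integer(0)
  for (j in seq_len(ncol(X))) {
    m <- rep(NA_real_, length(tk$levels))
    ok <- TRUE
    for (l in seq_along(tk$levels)) {
      sel <- tk$index == l
      nz <- sel & tk$z != 0
      if (!any(nz)) { ok <- FALSE; break }
      vals <- X[nz, j] / tk$z[nz]
      if (max(vals) - min(vals) > 1e-8) { ok <- FALSE; break }
      if (any(abs(X[sel & tk$z == 0, j]) > 1e-8)) { ok <- FALSE; break }
      m[l] <- vals[1]
    }
    if (ok) { M <- cbind(M, m); cols <- c(cols, j) }
  }
  if (is.null(M)) return(NULL)
  qrM <- qr(M)
  keep <- sort(qrM$pivot[seq_len(qrM$rank)])
  M <- M[, keep, drop = FALSE]
  cols <- cols[keep]
  list(M = M, proj = solve(crossprod(M), t(M)), cols = cols,
       W = solve(crossprod(M)))
}

# Reconstruct the plain-model split of each identified coefficient draw.
#
# With a term's level effects constrained orthogonal to its expressible
# fixed-effect columns, the sampled coefficient s for such a column is the
# identified total: fixed coefficient plus the cluster-mean component that
# the unconstrained model would have assigned to the random effects. The
# likelihood depends only on s, so conditional on s and the current
# variance draws the split is purely the Gaussian-prior decomposition —
# exact for any likelihood. Per draw: beta ~ its conditional given s, the
# remainder is distributed among the terms' gamma components, and the level
# effects are shifted by M gamma so the linear predictor is unchanged.
resplit_confounded <- function(draws, terms, projections, X, beta_mean, beta_sd, seed) {
  K <- length(terms)
  with_proj <- which(!vapply(projections, is.null, logical(1)))
  if (length(with_proj) == 0) return(draws)
  cols_union <- sort(unique(unlist(lapply(projections[with_proj], `[[`, "cols"))))
  p <- length(cols_union)
  # incidence of each term's gamma components in the union columns
  A <- lapply(with_proj, function(k) {
    a <- matrix(0, p, length(projections[[k]]$cols))
    for (jj in seq_along(projections[[k]]$cols)) {
      a[match(projections[[k]]$cols[jj], cols_union), jj] <- 1
    }
    a
  })
  bnames <- paste0("b_", colnames(X)[cols_union])
  sdnames <- vapply(with_proj, function(k) {
    tk <- terms[[k]]
    paste0("sd_", tk$group, "_", gsub(":", ".", tk$term))
  }, character(1))
  unames <- lapply(with_proj, function(k) {
    tk <- terms[[k]]
    sprintf("u_%s_%s[%s]", tk$group, gsub(":", ".", tk$term), tk$levels)
  })
  Vb <- diag(beta_sd^2, p)
  bm <- beta_mean[cols_union]
  set.seed(seed)
  for (i in seq_len(nrow(draws))) {
    s <- draws[i, bnames]
    sig2 <- draws[i, sdnames]^2
    Wk <- lapply(seq_along(with_proj), function(kk) {
      sig2[kk] * projections[[with_proj[kk]]]$W
    })
    Vg <- Reduce(`+`, lapply(seq_along(with_proj), function(kk) {
      A[[kk]] %*% Wk[[kk]] %*% t(A[[kk]])
    }))
    V <- Vb + Vg
    Vinv_dev <- solve(V, s - bm)
    mu_b <- bm + as.numeric(Vb %*% Vinv_dev)
    cov_b <- Vb - Vb %*% solve(V, Vb)
    cov_b <- (cov_b + t(cov_b)) / 2
    b_new <- as.numeric(mu_b + t(chol(cov_b + diag(1e-12, p))) %*% stats::rnorm(p))
    g_tot <- s - b_new
    # split g_tot among the terms: conditional of independent Gaussians on
    # their column sums (conditioning by kriging)
    g0 <- lapply(seq_along(with_proj), function(kk) {
      L <- chol(Wk[[kk]] + diag(1e-12, ncol(Wk[[kk]])))
      as.numeric(t(L) %*% stats::rnorm(ncol(Wk[[kk]])))
    })
    r <- g_tot - Reduce(`+`, lapply(seq_along(with_proj), function(kk) {
      as.numeric(A[[kk]] %*% g0[[kk]])
    }))
    adj <- solve(Vg + diag(1e-12, p), r)
    for (kk in seq_along(with_proj)) {
      gam <- g0[[kk]] + as.numeric(Wk[[kk]] %*% t(A[[kk]]) %*% adj)
      draws[i, unames[[kk]]] <- draws[i, unames[[kk]]] +
        as.numeric(projections[[with_proj[kk]]]$M %*% gam)
    }
    draws[i, bnames] <- b_new
  }
  draws
}

#' Fit a Bayesian hierarchical mixed model
#'
#' Samples the posterior of a Gaussian or Poisson mixed model with
#' sum-to-zero +/-1 population codes and independent Gaussian random-effect
#' terms, via JAGS. Priors are weakly informative: normal(0, beta_scale *
#' SD(y)) on coefficients (centred on mean(y) for the intercept), a
#' Gamma(0.5, (0.04 * sd_scale * SD(y))^2) prior on each random-effect
#' precision — conjugate, nearly flat on log(SD) between a soft floor at a
#' few percent of SD(y) and the outcome scale, so null variance terms can
#' sit low while real ones are unconstrained, and the SD updates stay
#' direct Gibbs draws — and exponential(1 / SD(y))
#' on the residual SD; for the Poisson likelihood the scales are fixed on
#' the log-link scale (2.5). Convergence is checked with the
#' rank-normalized split-R-hat on every monitored parameter (robust to the
#' skewed posteriors of variance parameters) and the fit fails loudly if
#' any exceeds `rhat_max`.
#'
#' @param table data.frame of observations; contrast columns are added with
#'   [contrast_codes()] if absent.
#' @param spec a [model_spec()].
#' @param rhat_max largest tolerated R-hat (default 1.01).
#' @param quiet suppress JAGS progress output.
#' @return object of class `fit_result`: list with `draws` (matrix, chains
#'   pooled, named columns; coefficients confounded with random-effect
#'   terms carry their full plain-model posterior, see Details), `mcmc`
#'   (coda::mcmc.list of the raw identified chains, used for diagnostics),
#'   `rhat`, `ess`, `X`, `terms` (random-term metadata), `data`, `spec`,
#'   `config`.
#'
#' @details Random-effect terms are sampled constrained orthogonal to the
#' fixed-effect columns they can express (e.g. dyad intercepts to the
#' intercept and the dyad-type code), which removes the posterior ridge
#' that plagues Gibbs sampling of such models. The sampled coefficient for
#' a confounded column is then the identified total of the fixed effect and
#' the cluster-mean component; because the likelihood depends only on that
#' total, the split between the two is exactly the Gaussian-prior
#' conditional, which is drawn per iteration in post-processing so that
#' reported coefficient posteriors carry the full between-cluster
#' uncertainty of the unconstrained model.
#' @export
fit_mixed_model <- function(table, spec, rhat_max = 1.01, quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  table <- contrast_codes(as.data.frame(table))
  y <- table[[spec$outcome]]
  if (is.null(y)) stop("fit_mixed_model: outcome column not found", call. = FALSE)
  keep <- is.finite(y)
  table <- table[keep, , drop = FALSE]
  y <- y[keep]
  X <- stats::model.matrix(spec$fixed, table)
  if (qr(X)$rank < ncol(X)) stop("fit_mixed_model: rank-deficient fixed-effect design", call. = FALSE)
  fac_cols <- all.vars(spec$fixed)
  if (!all(vapply(fac_cols, function(cc) length(unique(table[[cc]])) >= 2, logical(1)))) {
    stop("fit_mixed_model: every factor needs >= 2 observed levels", call. = FALSE)
  }

  # random-effect terms: one (grouping, covariate) pair per term
  terms <- list()
  for (g in names(spec$random)) {
    lev <- sort(unique(as.character(table[[g]])))
    for (tm in spec$random[[g]]) {
      terms[[length(terms) + 1]] <- list(
        group = g, term = tm, levels = lev,
        index = match(as.character(table[[g]]), lev),
        z = re_covariate(table, tm)
      )
    }
  }

  sdy <- if (spec$likelihood == "gaussian") stats::sd(y) else 1
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  pr <- utils::modifyList(list(beta_scale = 2.5, sd_scale = 2.5, sigma_rate = 1 / sdy),
                          spec$priors)
  beta_sd <- if (spec$likelihood == "gaussian") pr$beta_scale * sdy else 2.5
  sd_prior_sd <- if (spec$likelihood == "gaussian") pr$sd_scale * sdy else 2.5
  beta_mean <- rep(0, ncol(X))
  beta_mean[1] <- if (spec$likelihood == "gaussian") mean(y) else log(max(mean(y), 1e-6))

  data <- list(N = nrow(X), P = ncol(X), X = X, y = y,
               beta_mean = beta_mean, beta_prec = rep(1 / beta_sd^2, ncol(X)),
               sd_prior_rate = (0.04 * sd_prior_sd)^2)
  if (spec$likelihood == "gaussian") data$sigma_rate <- pr$sigma_rate
  projections <- lapply(terms, function(tk) term_projection(X, tk))
  has_proj <- vapply(projections, Negate(is.null), logical(1))
  for (k in seq_along(terms)) {
    data[[paste0("g", k)]] <- terms[[k]]$index
    data[[paste0("z", k)]] <- terms[[k]]$z
    data[[paste0("L", k)]] <- length(terms[[k]]$levels)
    if (has_proj[k]) {
      data[[paste0("M", k)]] <- projections[[k]]$M
      data[[paste0("PROJ", k)]] <- projections[[k]]$proj
      data[[paste0("Q", k)]] <- ncol(projections[[k]]$M)
    }
  }

  # The glm module's block sampler is a large win for small linear
  # structures but its per-iteration factorization cost grows quadratically
  # in the number of coefficient nodes; above the threshold the base
  # samplers (with the identifiability projection) are faster per unit of
  # effective sample size.
  n_nodes <- ncol(X) + sum(vapply(terms, function(tk) length(tk$levels), integer(1)))
  if (n_nodes <= 120) {
    try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  } else {
    try(rjags::unload.module("glm", quiet = TRUE), silent = TRUE)
  }

  code <- build_jags_code(spec$likelihood, has_proj)
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed * 1000L + ch)
  })
  monitors <- c("beta",
                if (length(terms) > 0) paste0("sd_u", seq_along(terms)),
                if (length(terms) > 0) paste0("u", seq_along(terms)),
                if (spec$likelihood == "gaussian") "sigma")
  run <- function() {
    m <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                           n.chains = spec$chains, quiet = TRUE)
    stats::update(m, spec$warmup, progress.bar = "none")
    thin <- if (is.null(spec$thin)) 1L else spec$thin
    rjags::coda.samples(m, monitors, n.iter = spec$draws * thin, thin = thin,
                        progress.bar = "none")
  }
  mcmc <- if (quiet) suppressWarnings(run()) else run()

  # rename parameters to readable names
  rename <- function(nms) {
    out <- nms
    for (j in seq_len(ncol(X))) out[out == sprintf("beta[%d]", j)] <- paste0("b_", colnames(X)[j])
    for (k in seq_along(terms)) {
      tk <- terms[[k]]
      lab <- paste0("sd_", tk$group, "_", gsub(":", ".", tk$term))
      out[out == sprintf("sd_u%d", k)] <- lab
      for (l in seq_along(tk$levels)) {
        out[out == sprintf("u%d[%d]", k, l)] <-
          sprintf("u_%s_%s[%s]", tk$group, gsub(":", ".", tk$term), tk$levels[l])
      }
    }
    out
  }
  for (ch in seq_along(mcmc)) colnames(mcmc[[ch]]) <- rename(colnames(mcmc[[ch]]))

  pnames <- colnames(mcmc[[1]])
  rhat <- vapply(pnames, function(pn) {
    split_rank_rhat(vapply(mcmc, function(ch) as.matrix(ch)[, pn], numeric(nrow(mcmc[[1]]))))
  }, numeric(1))
  # effective sizes for the population-level and variance parameters only
  # (the per-level effects are numerous and their spectral fits are costly)
  top <- !grepl("^u_", colnames(mcmc[[1]]))
  ess <- coda::effectiveSize(mcmc[, top, drop = FALSE])
  draws <- do.call(rbind, lapply(mcmc, as.matrix))
  draws <- resplit_confounded(draws, terms, projections, X,
                              beta_mean, beta_sd, spec$seed + 7L)

  bad <- rhat[is.finite(rhat) & rhat > rhat_max]
  fit <- structure(
    list(draws = draws, mcmc = mcmc, rhat = rhat, ess = ess, X = X,
         terms = terms, data = table, y = y, spec = spec,
         config = list(priors = pr, beta_sd = beta_sd, sd_prior_sd = sd_prior_sd,
                       beta_mean = beta_mean, chains = spec$chains,
                       draws = spec$draws, warmup = spec$warmup, seed = spec$seed)),
    class = "fit_result")
  if (length(bad) > 0) {
    stop(structure(class = c("dyadsync_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "fit_mixed_model: R-hat > %g for %d parameter(s): %s",
                     rhat_max, length(bad),
                     paste(sprintf("%s=%.3f", names(bad), bad), collapse = ", ")),
                     call = NULL, fit = fit)))
  }
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model of '%s': %d obs, %d fixed effects, %d RE terms\n",
              x$spec$likelihood, x$spec$outcome, nrow(x$X), ncol(x$X), length(x$terms)))
  cat(sprintf("  %d draws (%d chains), max R-hat %.4f\n",
              nrow(x$draws), length(x$mcmc), max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summary table of the population-level parameters
#' @param fit a `fit_result`.
#' @param level credible level for the equal-tailed interval.
#' @return data.frame: parameter, mean, lower, upper, rhat, ess.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  keep <- !grepl("^u_", colnames(fit$draws))
  q <- c((1 - level) / 2, 1 - (1 - level) / 2)
  d <- fit$draws[, keep, drop = FALSE]
  data.frame(parameter = colnames(d),
             mean = colMeans(d),
             lower = apply(d, 2, stats::quantile, q[1]),
             upper = apply(d, 2, stats::quantile, q[2]),
             rhat = fit$rhat[colnames(d)],
             ess = fit$ess[colnames(d)],
             row.names = NULL)
}

contrast_draws <- function(fit, contrast) {
  if (is.function(contrast)) return(contrast(fit$draws))
  if (is.character(contrast) && length(contrast) == 1) {
    if (!contrast %in% colnames(fit$draws)) {
      stop(sprintf("test_hypothesis: unknown parameter '%s'", contrast), call. = FALSE)
    }
    return(fit$draws[, contrast])
  }
  if (is.numeric(contrast) && !is.null(names(contrast))) {
    miss <- setdiff(names(contrast), colnames(fit$draws))
    if (length(miss) > 0) {
      stop(sprintf("test_hypothesis: unknown parameter '%s'", miss[1]), call. = FALSE)
    }
    return(as.numeric(fit$draws[, names(contrast), drop = FALSE] %*% contrast))
  }
  stop("test_hypothesis: contrast must be a parameter name, named weights or a function", call. = FALSE)
}

#' Evaluate a directed or undirected hypothesis on a fitted model
#'
#' Directed hypotheses report the posterior probability that the contrast
#' has the hypothesised sign and are supported when that probability reaches
#' `1 - alpha` (alpha = 0.05 by convention here). Undirected hypotheses use
#' the equal-tailed `1 - 2 * alpha` credible interval (alpha = 0.025, i.e. a
#' 95% interval) and are supported when it excludes zero. The posterior
#' mean and interval of the contrast are returned alongside; with +/-1
#' coding, `2 *` a two-level coefficient is the marginal condition
#' difference on the outcome scale.
#'
#' @param fit a `fit_result`.
#' @param contrast a parameter name, a named weight vector over parameters,
#'   or a function mapping the draw matrix to a vector of contrast draws.
#' @param directed logical.
#' @param alpha decision threshold (default 0.05 directed, 0.025 undirected).
#' @param direction `">"` (contrast > 0) or `"<"` for directed hypotheses.
#' @return data.frame row: `estimate`, `lower`, `upper`,
#'   `posterior_probability`, `directed`, `supported`.
#' @export
test_hypothesis <- function(fit, contrast, directed = TRUE,
                            alpha = if (directed) 0.05 else 0.025,
                            direction = c(">", "<")) {
  direction <- match.arg(direction)
  q <- contrast_draws(fit, contrast)
  ci <- stats::quantile(q, c(alpha, 1 - alpha), names = FALSE)
  if (directed) {
    pp <- if (direction == ">") mean(q > 0) else mean(q < 0)
    supported <- pp >= 1 - alpha
  } else {
    pp <- max(mean(q > 0), mean(q < 0))
    supported <- ci[1] > 0 || ci[2] < 0
  }
  data.frame(estimate = mean(q), lower = ci[1], upper = ci[2],
             posterior_probability = pp, directed = directed,
             supported = supported, row.names = NULL)
}

#' Marginal difference between the two levels of a coded factor
#'
#' Returns posterior draws of the difference in the average model prediction
#' (over the observed design grid, population level) between the `+1` and
#' `-1` level of a contrast column. For the Gaussian likelihood this equals
#' twice the coefficient when the design is balanced; for the Poisson
#' likelihood predictions are averaged on the response (rate) scale, and
#' the per-level average rates are attached as attributes `rate_plus` /
#' `rate_minus`.
#'
#' @param fit a `fit_result`.
#' @param col contrast column name (e.g. `"dyad_type_c"`).
#' @return numeric vector of draws of (level +1 minus level -1), with rate
#'   attributes for Poisson fits.
#' @export
marginal_difference <- function(fit, col) {
  tab <- fit$data
  if (!col %in% names(tab)) stop("marginal_difference: unknown column", call. = FALSE)
  beta <- fit$draws[, paste0("b_", colnames(fit$X)), drop = FALSE]
  pred <- function(value) {
    t2 <- tab
    t2[[col]] <- value
    Xp <- stats::model.matrix(fit$spec$fixed, t2)
    eta <- beta %*% t(Xp)
    if (fit$spec$likelihood == "poisson") rowMeans(exp(eta)) else rowMeans(eta)
  }
  hi <- pred(1)
  lo <- pred(-1)
  out <- hi - lo
  if (fit$spec$likelihood == "poisson") {
    attr(out, "rate_plus") <- hi
    attr(out, "rate_minus") <- lo
  }
  out
}

#' Prior or posterior predictive check
#'
#' Simulates replicated outcome vectors from the model (prior draws or
#' posterior draws, random effects included) and locates the observed test
#' statistic within the replicated distribution, per cell of the design
#' (cells are the combinations of the factor columns present among `group`,
#' `dyad_type`, `condition`/`ips`, `aoi`).
#'
#' @param fit a `fit_result`.
#' @param statistic `"mean"`, `"sd"` or `"max"`.
#' @param type `"posterior"` or `"prior"`.
#' @param nrep number of replicated data sets.
#' @return data.frame with one row per design cell: cell labels, observed
#'   statistic, and `quantile` (fraction of replicates below the observed
#'   value, ties split).
#' @export
predictive_check <- function(fit, statistic = c("mean", "sd", "max"),
                             type = c("posterior", "prior"), nrep = 200) {
  statistic <- match.arg(statistic)
  type <- match.arg(type)
  stat_fun <- switch(statistic, mean = mean, sd = stats::sd, max = max)
  tab <- fit$data
  cells <- intersect(c("group", "dyad_type", "condition", "ips", "aoi"), names(tab))
  cell_id <- if (length(cells) > 0) interaction(tab[cells], drop = TRUE) else factor(rep("all", nrow(tab)))
  n <- nrow(tab)
  P <- ncol(fit$X)
  gaussian <- fit$spec$likelihood == "gaussian"
  ndraw <- nrow(fit$draws)
  idx <- sample.int(ndraw, nrep, replace = nrep > ndraw)

  simulate_one <- function(i) {
    if (type == "posterior") {
      beta <- fit$draws[i, paste0("b_", colnames(fit$X))]
      eta <- as.numeric(fit$X %*% beta)
      for (k in seq_along(fit$terms)) {
        tk <- fit$terms[[k]]
        u <- fit$draws[i, sprintf("u_%s_%s[%s]", tk$group, gsub(":", ".", tk$term), tk$levels)]
        eta <- eta + u[tk$index] * tk$z
      }
      sigma <- if (gaussian) fit$draws[i, "sigma"] else NA
    } else {
      beta <- stats::rnorm(P, fit$config$beta_mean, fit$config$beta_sd)
      eta <- as.numeric(fit$X %*% beta)
      for (k in seq_along(fit$terms)) {
        tk <- fit$terms[[k]]
        sd_u <- 1 / sqrt(stats::rgamma(1, 0.5, rate = (0.04 * fit$config$sd_prior_sd)^2))
        u <- stats::rnorm(length(tk$levels), 0, sd_u)
        eta <- eta + u[tk$index] * tk$z
      }
      sigma <- if (gaussian) stats::rexp(1, fit$config$priors$sigma_rate) else NA
    }
    if (gaussian) stats::rnorm(n, eta, sigma) else stats::rpois(n, exp(pmin(eta, 20)))
  }

  obs <- tapply(fit$y, cell_id, stat_fun)
  reps <- vapply(idx, function(i) {
    yr <- simulate_one(i)
    as.numeric(tapply(yr, cell_id, stat_fun))
  }, numeric(nlevels(cell_id)))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  qtl <- vapply(seq_len(nlevels(cell_id)), function(j) {
    mean(reps[j, ] < obs[j]) + 0.5 * mean(reps[j, ] == obs[j])
  }, numeric(1))
  out <- unique(data.frame(tab[cells], cell = cell_id))
  out <- out[match(levels(cell_id), out$cell), , drop = FALSE]
  out$observed <- as.numeric(obs)
  out$quantile <- qtl
  rownames(out) <- NULL
  out
}

#' Default-prior (JZS) two-sample Bayes-factor t-test
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor for a two-sample mean
#' difference by numerical integration of the t likelihood over the Cauchy
#' effect-size prior (scale `rscale`, default sqrt(2)/2), following the
#' standard inverse-gamma mixture representation. If `auto_rank` is set and
#' either sample fails a Shapiro-Wilk normality check at p < 0.05, both
#' samples are jointly rank-transformed first.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param rscale Cauchy prior scale on the standardised effect.
#' @param auto_rank rank-transform on evidence of non-normality.
#' @return natural-log BF10 (positive favours a group difference), with
#'   attributes `t`, `rank_transformed`.
#' @export
bayes_t_test <- function(x, y, rscale = sqrt(2) / 2, auto_rank = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("bayes_t_test: each sample needs n >= 2", call. = FALSE)
  ranked <- FALSE
  if (auto_rank) {
    swp <- function(v) {
      if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) return(1)
      tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 1)
    }
    if (swp(x) < 0.05 || swp(y) < 0.05) {
      r <- rank(c(x, y))
      x <- r[seq_along(x)]
      y <- r[-seq_along(x)]
      ranked <- TRUE
    }
  }
  n1 <- length(x); n2 <- length(y)
  nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / nu
  if (sp2 <= 0) stop("bayes_t_test: zero pooled variance", call. = FALSE)
  neff <- n1 * n2 / (n1 + n2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 / neff)

  log_lik0 <- -((nu + 1) / 2) * log1p(t^2 / nu)
  # marginal likelihood under H1: g ~ InverseGamma(1/2, rscale^2/2)
  log_integrand <- function(g) {
    -0.5 * log1p(neff * g) -
      ((nu + 1) / 2) * log1p(t^2 / ((1 + neff * g) * nu)) +
      0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - rscale^2 / (2 * g)
  }
  shift <- log_integrand(rscale^2) # stabilise the quadrature
  int <- stats::integrate(function(g) exp(log_integrand(g) - shift), 0, Inf,
                          rel.tol = 1e-9, subdivisions = 500L)
  logbf <- (log(int$value) + shift) - log_lik0
  attr(logbf, "t") <- t
  attr(logbf, "rank_transformed") <- ranked
  logbf
}
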