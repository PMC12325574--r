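test_that("beta-binomial log-likelihood matches direct pmf evaluations", {
  ## symmetry forces P(0 of 1) = 1/2 at mu = 0.5 for any phi
  for (phi in c(0.5, 2, 50)) {
    expect_equal(betabinom_loglik(0, 1, 0.5, phi), log(0.5))
  }
  ## oracle: the pmf via numerical integration of binomial x beta
  pmf_int <- function(k, n, mu, phi) {
    stats::integrate(function(p) stats::dbinom(k, n, p) *
                       stats::dbeta(p, mu * phi, (1 - mu) * phi),
                     0, 1, rel.tol = 1e-10)$value
  }
  expect_equal(betabinom_loglik(3, 5, 0.6, 10), log(pmf_int(3, 5, 0.6, 10)),
               tolerance = 1e-8)
  expect_equal(betabinom_loglik(7, 12, 0.3, 4), log(pmf_int(7, 12, 0.3, 4)),
               tolerance = 1e-8)

  ## binomial limit as phi grows
  expect_equal(betabinom_loglik(3, 5, 0.6, 1e7),
               stats::dbinom(3, 5, 0.6, log = TRUE), tolerance = 1e-5)

  expect_error(betabinom_loglik(6, 5, 0.5, 1), "chosen")
  expect_error(betabinom_loglik(1, 5, 0.5, -1), "phi")
})

test_that("the beta-binomial pmf normalizes over its support on a (mu, phi) grid", {
  for (mu in c(0.1, 0.5, 0.9)) {
    for (phi in c(0.5, 5, 50)) {
      total <- sum(exp(betabinom_loglik(0:10, 10, mu, phi)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("simulated beta-binomial counts show the modeled overdispersion", {
  withr::with_seed(77, x <- rbetabinom(20000, 10, 0.3, 5))
  expect_equal(mean(x) / 10, 0.3, tolerance = 0.02)
  ## var = n mu (1-mu) (1 + (n-1)/(phi+1))
  expect_equal(stats::var(x), 10 * 0.3 * 0.7 * (1 + 9 / 6), tolerance = 0.1)
})

test_that("null data give a posterior centered at chance with interaction covering zero", {
  tab <- sim_from_relmodel(404, n_participants = 12, n_dyads = 10,
                           b = c(0, 0, 0, 0), sd_d = 0.2, sd_p = 0.2, phi = 30)
  fit <- suppressWarnings(fit_model(tab, fast_spec(), seed = 9))
  s <- summary(fit)
  int <- s[s$parameter == "condition_rival:x", ]
  expect_gt(int$u95, 0)
  expect_lt(int$l95, 0)
  ## mean percent chosen near 0.5 on the response scale
  expect_equal(stats::plogis(s$median[s$parameter == "(Intercept)"]), 0.5,
               tolerance = 0.1)
  me <- marginal_effects(fit)
  expect_true(all(me$l95 < 0 & me$u95 > 0))
})

test_that("the fit is deterministic under its seed and input checks fire", {
  tab <- sim_from_relmodel(11, n_participants = 6, n_dyads = 6)
  f1 <- suppressWarnings(fit_model(tab, fast_spec(), seed = 31))
  f2 <- suppressWarnings(fit_model(tab, fast_spec(), seed = 31))
  expect_identical(f1$main, f2$main)

  bad <- tab; bad$x <- 1
  expect_error(fit_model(bad, fast_spec(), seed = 1), "zero variance")
  bad <- tab; bad$x[1] <- NA
  expect_error(fit_model(bad, fast_spec(), seed = 1), "complete cases")
  expect_error(fit_model(tab[tab$dyad == "d1", ], fast_spec(), seed = 1),
               "at least 2 dyads")
  expect_error(fit_model(tab, fast_spec(), seed = 1, spec = "x"))
})

test_that("without an interaction the two conditions share one marginal slope", {
  tab <- sim_from_relmodel(77, n_participants = 8, n_dyads = 8,
                           b = c(0.3, -0.2, 0.8, 0), sd_d = 0.3, sd_p = 0.2)
  fit <- suppressWarnings(
    fit_model(tab, fast_spec(include_interaction = FALSE), seed = 13))
  me <- marginal_effects(fit)
  expect_equal(me$estimate[me$condition == "friend"],
               me$estimate[me$condition == "rival"])
  expect_error(marginal_effects(fit, "win"), "not present")
})

test_that("posterior quantiles agree with an independent JAGS fit of the same model", {
  tab <- sim_from_relmodel(55, n_participants = 10, n_dyads = 10,
                           b = c(0.5, -0.3, 1, -1.5), phi = 15)
  fit <- suppressWarnings(fit_model(tab, model_spec(chains = 2, iter = 2500,
                                                    warmup = 800,
                                                    on_nonconvergence = "warn"),
                                    seed = 3))
  s <- summary(fit)

  des <- convrel:::build_design(tab, TRUE)
  mstr <- "model{
    for(i in 1:N){
      logit(mu[i]) <- inprod(X[i,], b) + ud[dc[i]] + up[pc[i]]
      a[i] <- mu[i]*phi
      bb[i] <- (1-mu[i])*phi
      ll[i] <- logfact(n[i]) - logfact(y[i]) - logfact(n[i]-y[i]) +
               loggam(y[i]+a[i]) + loggam(n[i]-y[i]+bb[i]) - loggam(n[i]+phi) +
               loggam(phi) - loggam(a[i]) - loggam(bb[i])
      ones[i] ~ dbern(exp(ll[i]))
    }
    for(j in 1:Nd){ ud[j] ~ dnorm(0, pow(sd_d,-2)) }
    for(j in 1:Np){ up[j] ~ dnorm(0, pow(sd_p,-2)) }
    b[1] ~ dnorm(0.5, 1)
    for(k in 2:P){ b[k] ~ dnorm(0, 0.04) }
    sd_d ~ dt(0, 0.04, 1) T(0,)
    sd_p ~ dt(0, 0.04, 1) T(0,)
    phi ~ dt(0, 0.04, 1) T(0,)
  }"
  dat <- list(N = nrow(tab), y = tab$chosen, n = tab$presented, X = des$X,
              P = ncol(des$X), dc = des$dc, pc = des$pc,
              Nd = max(des$dc), Np = max(des$pc), ones = rep(1, nrow(tab)))
  inits <- lapply(1:2, function(i) {
    list(b = rep(0, ncol(des$X)), sd_d = 1, sd_p = 1, phi = 1,
         .RNG.name = "base::Mersenne-Twister", .RNG.seed = i)
  })
  m <- rjags::jags.model(textConnection(mstr), data = dat, n.chains = 2,
                         n.adapt = 400, inits = inits, quiet = TRUE)
  stats::update(m, 600)
  draws <- rjags::coda.samples(m, c("b", "sd_d", "sd_p", "phi"), n.iter = 1500)
  jq <- summary(draws)$quantiles
  ## posterior medians of the fixed effects agree between the two samplers
  for (k in 1:4) {
    ours <- s$median[k]
    theirs <- jq[paste0("b[", k, "]"), "50%"]
    expect_equal(ours, theirs, tolerance = 0.25, info = s$parameter[k])
  }
  expect_equal(s$median[s$parameter == "sd_dyad"], jq["sd_d", "50%"],
               tolerance = 0.25)
})

test_that("Bayes factors distinguish generated-with from generated-without interactions", {
  tab_int <- sim_from_relmodel(61, n_participants = 12, n_dyads = 12,
                               b = c(0.5, -0.3, 1, -2), phi = 20)
  full <- suppressWarnings(fit_model(tab_int, fast_spec(), seed = 8))
  red <- suppressWarnings(
    fit_model(tab_int, fast_spec(include_interaction = FALSE), seed = 9))
  bf_with <- bayes_factor(full, red)
  expect_gt(bf_with$bf, 10)

  tab_null <- sim_from_relmodel(62, n_participants = 12, n_dyads = 12,
                                b = c(0.5, -0.3, 1, 0), phi = 20)
  full0 <- suppressWarnings(fit_model(tab_null, fast_spec(), seed = 10))
  red0 <- suppressWarnings(
    fit_model(tab_null, fast_spec(include_interaction = FALSE), seed = 11))
  bf_without <- bayes_factor(full0, red0)
  expect_lt(bf_without$bf, 10)
  expect_gt(bf_with$bf, bf_without$bf)

  ## identical models: BF exactly 1; bridge agrees closely
  expect_equal(bayes_factor(red, red)$bf, 1)
  bf_bridge_same <- bayes_factor(full, full, method = "bridge")
  expect_equal(bf_bridge_same$bf, 1)

  ## bridge sampling agrees with Savage-Dickey on the log scale
  bf_bridge <- bayes_factor(full0, red0, method = "bridge")
  expect_equal(bf_bridge$log_bf, bf_without$log_bf, tolerance = 1.5)

  ## mismatched data are rejected
  expect_error(bayes_factor(full, red0), "same table")
})

test_that("evidence bands follow the stated Bayes-factor thresholds", {
  expect_equal(convrel:::classify_bf(500), "very strong")
  expect_equal(convrel:::classify_bf(50), "moderate")
  expect_equal(convrel:::classify_bf(2), "little to none")
})
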