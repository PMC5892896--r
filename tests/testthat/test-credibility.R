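test_that("default conditional table matches the printed probabilities", {
  tb <- credibility_table()
  expect_s3_class(tb, "credibility_table")
  expect_equal(nrow(tb), 8L)
  expect_true(all(tb$p_rep >= 0 & tb$p_rep <= 1))
  h <- tb$p_rep[tb$hypothesis == "H"][order(!tb$trust[tb$hypothesis == "H"],
                                            !tb$expertise[tb$hypothesis == "H"])]
  nh <- tb$p_rep[tb$hypothesis == "notH"][order(!tb$trust[tb$hypothesis == "notH"],
                                                !tb$expertise[tb$hypothesis == "notH"])]
  expect_equal(h, c(0.80, 0.58, 0.34, 0.18))
  expect_equal(nh, c(0.22, 0.42, 0.59, 0.71))
})

test_that("marginal likelihoods match enumeration oracle at corners and interior", {
  cases <- list(
    c(1, 1), c(0, 0), c(0.5, 0.5), c(0.6, 0.6), c(0.3, 0.9), c(0.85, 0.15)
  )
  for (cs in cases) {
    got <- marginal_likelihoods(cs[1], cs[2])
    want <- oracle_likelihoods(cs[1], cs[2])
    expect_equal(got$p_rep_given_h, want[1], tolerance = 1e-12)
    expect_equal(got$p_rep_given_not_h, want[2], tolerance = 1e-12)
  }
  # frozen values: corners read straight off the table, interior from the
  # four-term weighted sum
  expect_equal(unlist(marginal_likelihoods(1, 1), use.names = FALSE),
               c(0.80, 0.22))
  expect_equal(unlist(marginal_likelihoods(0, 0), use.names = FALSE),
               c(0.18, 0.71))
  expect_equal(unlist(marginal_likelihoods(0.5, 0.5), use.names = FALSE),
               c(0.475, 0.485))
  expect_equal(unlist(marginal_likelihoods(0.6, 0.6), use.names = FALSE),
               c(0.5376, 0.4352), tolerance = 1e-12)
})

test_that("marginal likelihoods are vectorized and validate inputs", {
  got <- marginal_likelihoods(c(0, 1), c(0, 1))
  expect_equal(got$p_rep_given_h, c(0.18, 0.80))
  expect_error(marginal_likelihoods(1.2, 0.5), "trust")
  expect_error(marginal_likelihoods(0.5, -0.1), "expertise")
})

test_that("posterior belief reproduces direct Bayes arithmetic", {
  # fully credible source endorsing at even prior: 0.40 / (0.40 + 0.11)
  expect_equal(posterior_belief(0.5, 0.80, 0.22, "endorse"), 0.40 / 0.51,
               tolerance = 1e-12)
  # fully credible source opposing: 0.10 / (0.10 + 0.39)
  expect_equal(posterior_belief(0.5, 0.80, 0.22, "oppose"), 0.10 / 0.49,
               tolerance = 1e-12)
  # backfire: endorsement from a zero-credibility source lowers belief
  # 0.6*0.18 / (0.6*0.18 + 0.4*0.71)
  expect_equal(posterior_belief(0.6, 0.18, 0.71, "endorse"), 0.108 / 0.392,
               tolerance = 1e-12)
  # uninformative source leaves belief unchanged
  expect_equal(posterior_belief(0.5, 0.4, 0.4, "endorse"), 0.5)
  # certainty is absorbing
  expect_equal(posterior_belief(1, 0.3, 0.9, "endorse"), 1)
  expect_equal(posterior_belief(0, 0.3, 0.9, "endorse"), 0)
  expect_error(posterior_belief(1.5, 0.5, 0.5), "prior")
})

test_that("degenerate zero denominator returns the prior with a warning", {
  expect_warning(out <- posterior_belief(0, 0.5, 0, "endorse"), "denominator")
  expect_equal(out, 0)
  expect_warning(out2 <- posterior_belief(1, 1, 0.5, "oppose"), "denominator")
  expect_equal(out2, 1)
})

test_that("posterior matches oracle on a 1000-point random grid and stays in [0,1]", {
  set.seed(42)
  n <- 1000
  prior <- runif(n)
  trust <- runif(n)
  expertise <- runif(n)
  lik <- marginal_likelihoods(trust, expertise)
  post_e <- posterior_belief(prior, lik$p_rep_given_h, lik$p_rep_given_not_h, "endorse")
  post_o <- posterior_belief(prior, lik$p_rep_given_h, lik$p_rep_given_not_h, "oppose")
  for (i in seq_len(n)) {
    want <- oracle_likelihoods(trust[i], expertise[i])
    expect_equal(post_e[i], oracle_posterior(prior[i], want[1], want[2]),
                 tolerance = 1e-10)
    expect_equal(post_o[i], oracle_posterior(prior[i], want[1], want[2], oppose = TRUE),
                 tolerance = 1e-10)
  }
  expect_true(all(post_e >= 0 & post_e <= 1))
  expect_true(all(post_o >= 0 & post_o <= 1))
})

test_that("endorsement direction is characterized by the likelihood ordering", {
  set.seed(7)
  for (i in 1:200) {
    prior <- runif(1, 0.05, 0.95)
    lh <- runif(1)
    lnh <- runif(1)
    post <- posterior_belief(prior, lh, lnh, "endorse")
    if (lh > lnh) expect_gt(post, prior)
    if (lh < lnh) expect_lt(post, prior)
  }
  expect_equal(posterior_belief(0.3, 0.6, 0.6, "endorse"), 0.3)
})

test_that("posterior is strictly increasing in the prior", {
  priors <- seq(0.05, 0.95, by = 0.05)
  for (lik in list(c(0.8, 0.22), c(0.18, 0.71), c(0.5376, 0.4352))) {
    post <- posterior_belief(priors, lik[1], lik[2], "endorse")
    expect_true(all(diff(post) > 0))
  }
})

test_that("oppose equals the complement update with hypothesis roles swapped", {
  grid <- expand.grid(prior = seq(0.1, 0.9, 0.2),
                      trust = seq(0.1, 0.9, 0.2),
                      expertise = seq(0.1, 0.9, 0.2))
  lik <- marginal_likelihoods(grid$trust, grid$expertise)
  lhs <- posterior_belief(grid$prior, lik$p_rep_given_h, lik$p_rep_given_not_h,
                          "oppose")
  # swapped roles: hypothesis complement believes 1-prior; it sees an
  # endorsement whose likelihoods are the negated-report probabilities
  rhs <- 1 - posterior_belief(1 - grid$prior,
                              1 - lik$p_rep_given_not_h,
                              1 - lik$p_rep_given_h,
                              "endorse")
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("mean perception sits in the backfire region at 0.4 and 0.5 but not 0.6", {
  for (mu in c(0.4, 0.5)) {
    lik <- marginal_likelihoods(mu, mu)
    expect_lt(lik$p_rep_given_h, lik$p_rep_given_not_h)
  }
  lik <- marginal_likelihoods(0.6, 0.6)
  expect_gt(lik$p_rep_given_h, lik$p_rep_given_not_h)
})

test_that("credibility score is the mean of trust and expertise", {
  expect_equal(credibility_score(0.4, 0.8), 0.6)
  expect_equal(credibility_score(0, 0), 0)
  expect_equal(credibility_score(1, 0), 0.5)
  expect_equal(credibility_score(c(0.2, 0.6), c(0.4, 1)), c(0.3, 0.8))
  expect_error(credibility_score(2, 0.5), "trust")
})
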