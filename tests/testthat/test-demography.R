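test_that("model specs free the documented parameter sets", {
  expect_equal(model_spec("SI")$k, 4)
  expect_equal(model_spec("IM")$k, 6)
  expect_equal(model_spec("AM")$k, 7)
  expect_equal(model_spec("SC")$k, 7)
  expect_equal(model_spec("SCS")$k, 8)
  expect_error(demographic_params(100, 100, 100, 10, T_1 = 20),
               "epoch times")
  expect_error(demographic_params(100, 100, 100, 10, mmj = 1.2), "mmj")
  # a model requesting an epoch parameter the params do not define errors
  p <- demographic_params(100, 100, 100, 1000)
  expect_error(divergescan:::migration_epoch(p, model_spec("SCS")), "T_1|T_2")
})

test_that("composite log-likelihood follows the stated arithmetic", {
  proj <- c(2, 2)
  mk <- function(m) joint_sfs(m, proj)
  # all observed mass in one cell with expectation 0.1, S = 10 -> -10
  obs <- matrix(0, 3, 3); obs[2, 1] <- 10
  ex <- matrix(0, 3, 3); ex[2, 1] <- 0.1
  ex[ex == 0] <- (1 - 0.1) / 7 # spread the rest anywhere positive
  ex[1, 1] <- 0; ex[3, 3] <- 0
  expect_equal(composite_log_likelihood(mk(obs), mk(ex)), -10)
  # mismatched projections error
  expect_error(composite_log_likelihood(mk(obs), joint_sfs(matrix(1, 2, 3),
                                                           c(1, 2))),
               "mismatch")
})

test_that("likelihood is maximized at expected = observed proportions (Gibbs)", {
  set.seed(12)
  proj <- c(4, 3)
  for (i in 1:20) {
    cnt <- matrix(rpois(20, 5), 5, 4)
    cnt[1, 1] <- 0; cnt[5, 4] <- 0
    obs <- joint_sfs(cnt, proj)
    S <- sfs_total(obs)
    um <- divergescan:::unmasked_entries(c(5, 4))
    p_star <- cnt / S; p_star[!um] <- 0
    p_star[um & p_star == 0] <- 1e-12
    p_star[um] <- p_star[um] / sum(p_star[um])
    best <- composite_log_likelihood(obs, joint_sfs(p_star, proj))
    # any perturbed proportion vector scores lower
    q <- p_star
    q[um] <- q[um] + runif(sum(um), 0, 0.1)
    q[um] <- q[um] / sum(q[um])
    expect_gte(best, composite_log_likelihood(obs, joint_sfs(q, proj)))
  }
})

test_that("expected SFS is a proper folded spectrum with floored cells", {
  set.seed(77)
  p <- demographic_params(500, 500, 500, 2000, mmj = 0.01, mjm = 0.01)
  e <- expected_sfs(p, model_spec("IM"), c(6, 4), n_loci = 2000)
  um <- divergescan:::unmasked_entries(dim(e$counts))
  expect_equal(sum(e$counts[um]), 1, tolerance = 1e-12)
  expect_true(all(e$counts[um] > 0))
  expect_equal(e$counts[1, 1], 0)
  # deep-split SI concentrates mass on entries monomorphic in one deme
  set.seed(78)
  p2 <- demographic_params(500, 500, 500, 5e4)
  e2 <- expected_sfs(p2, model_spec("SI"), c(6, 4), n_loci = 2000)
  edge <- sum(e2$counts[, 1]) + sum(e2$counts[1, ]) - e2$counts[1, 1]
  expect_gt(edge, 0.9)
})

test_that("single-deme expected folded SFS matches the neutral closed form", {
  set.seed(41)
  p <- demographic_params(500, 500, 500, 1e-3)
  n <- 10
  e <- expected_sfs(p, model_spec("SI"), c(n, 0), n_loci = 1e4)
  got <- e$counts[2:n, 1]
  i <- 1:(n - 1)
  want <- ifelse(i < n / 2, 1 / i + 1 / (n - i), ifelse(i == n / 2, 1 / i, 0))
  want <- want / sum(want)
  expect_lt(max(abs(got - want)), 0.02)
})

test_that("AIC follows 2k - 2 ln(10) logCL10 and ranks by parsimony", {
  mk_fit <- function(model, logCL, ck = 1) {
    structure(list(model = model_spec(model), k = model_spec(model)$k,
                   logCL10 = logCL,
                   AIC = 2 * model_spec(model)$k - 2 * log(10) * logCL,
                   restarts = tibble::tibble(restart = 1L, logCL_search = logCL,
                                             logCL_final = logCL,
                                             convergence = 0L),
                   obs_total = 100, obs_checksum = ck,
                   free = model_spec(model)$free),
              class = "demog_fit")
  }
  f <- mk_fit("IM", -100)
  expect_equal(f$AIC, 12 + 200 * log(10), tolerance = 1e-9)
  expect_equal(f$AIC, 472.5170, tolerance = 1e-4)
  # equal likelihoods: the 4-parameter SI model ranks first
  cmp <- compare_models(list(mk_fit("SI", -50), mk_fit("IM", -50)))
  expect_equal(attr(cmp, "best"), "SI")
  expect_error(compare_models(list(mk_fit("SI", -50), mk_fit("IM", -50, 2))),
               "different observed")
})

test_that("fits are deterministic given the RNG state", {
  set.seed(61)
  obs <- sim_obs_sfs(scaled_truth(), model_spec("SCS"), n_loci = 200,
                     n_hap = c(8, 6))
  search <- search_config(n_restarts = 1, n_loci = 100, polish_n_loci = 200,
                          final_n_loci = 500, maxit = 15, polish_maxit = 8)
  set.seed(99); f1 <- fit_model(obs, model_spec("SI"), search)
  set.seed(99); f2 <- fit_model(obs, model_spec("SI"), search)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$logCL10, f2$logCL10)
})

test_that("SI is effectively nested in IM", {
  set.seed(62)
  obs <- sim_obs_sfs(scaled_truth(), model_spec("SCS"), n_loci = 400,
                     n_hap = c(10, 6))
  search <- search_config(n_restarts = 2, n_loci = 200, polish_n_loci = 1000,
                          final_n_loci = 20000, maxit = 60, polish_maxit = 30)
  fits <- fit_all_models(obs, models = c("SI", "IM"), search = search,
                         eval_seed = 7)
  # IM extends SI (and is seeded with it), so it cannot do materially worse
  expect_gte(fits$IM$logCL10, fits$SI$logCL10 - 3)
})

test_that("bootstrap percentile CIs degenerate to min/max at n_boot = 2", {
  set.seed(63)
  obs <- sim_obs_sfs(scaled_truth(), model_spec("SCS"), n_loci = 300,
                     n_hap = c(8, 4))
  search <- search_config(n_restarts = 1, n_loci = 100, polish_n_loci = 300,
                          final_n_loci = 1000, maxit = 20, polish_maxit = 10)
  fit <- fit_model(obs, model_spec("SI"), search)
  ci <- bootstrap_ci(fit, n_boot = 2, search = search)
  expect_equal(nrow(ci), 4)
  expect_true(all(ci$lower <= ci$upper))
  expect_equal(ci$n_boot_ok, rep(2L, 4))
})
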