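test_that("mixture survival functions match their closed forms", {
  expect_equal(mixture_sf(0, "mix_half_chisq1_chisq2"), 1)
  expect_equal(mixture_sf(0, "mix_half_chisq0_chisq1"), 1)
  # 0.05 critical values: 5.14 for the joint two-constraint mixture,
  # half the chi1 tail at the 0.90 quantile (2.706) for the tau boundary
  expect_equal(mixture_sf(5.14, "mix_half_chisq1_chisq2"), 0.05,
               tolerance = 1e-3)
  expect_equal(mixture_sf(qchisq(0.9, 1), "mix_half_chisq0_chisq1"), 0.05,
               tolerance = 1e-12)
  expect_equal(mixture_sf(3, "chisq1"),
               pchisq(3, 1, lower.tail = FALSE))
  expect_error(mixture_sf(-1, "chisq1"), "nonnegative")
  # strictly decreasing and continuous on (0, Inf)
  x <- seq(1e-6, 20, length.out = 200)
  for (mx in c("chisq1", "mix_half_chisq0_chisq1",
               "mix_half_chisq1_chisq2")) {
    v <- mixture_sf(x, mx)
    expect_true(all(diff(v) < 0))
  }
})

test_that("lrt picks the null distribution from the released constraints", {
  mk <- function(model, ll) {
    f <- igc_fit_from_params(toy2_params(), two_tip_tree(), toy2(),
                             model = model, logLik = ll)
    f$n_col <- 100L
    f
  }
  r <- lrt_igc(mk("omega-IGC", -10), mk("omega+IGC", -8))
  expect_equal(r$null_distribution, "mix_half_chisq0_chisq1")
  expect_equal(r$statistic, 4)
  r <- lrt_igc(mk("omega+IGC", -10), mk("omegaHN+IGC", -9))
  expect_equal(r$null_distribution, "chisq1")
  r <- lrt_igc(mk("omega-IGC", -10), mk("omegaHN+IGC", -9))
  expect_equal(r$null_distribution, "mix_half_chisq1_chisq2")
  # equal likelihoods: Lambda = 0, p = 1
  r <- lrt_igc(mk("omega-IGC", -10), mk("omega+IGC", -10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$rejected)
  # non-nested pairs are rejected
  expect_error(lrt_igc(mk("omega+IGC", -10), mk("omegaHN-IGC", -9)),
               "not nested")
  expect_error(lrt_igc(mk("omegaHN+IGC", -10), mk("omega-IGC", -9)),
               "not nested")
})

test_that("fitted log-likelihoods respect the model lattice", {
  fx <- make_fixture("two-tip-minimal", n_codons = 400, seed = 21)
  lat <- model_lattice(fx$alignment, fx$tree, n_starts = 1,
                       control = list(factr = 1e9))
  ll <- vapply(lat$fits, `[[`, numeric(1), "logLik")
  tol <- 1e-4
  expect_gte(ll[["omega+IGC"]], ll[["omega-IGC"]] - tol)
  expect_gte(ll[["omegaHN-IGC"]], ll[["omega-IGC"]] - tol)
  expect_gte(ll[["omegaHN+IGC"]], ll[["omega+IGC"]] - tol)
  expect_gte(ll[["omegaHN+IGC"]], ll[["omegaHN-IGC"]] - tol)
  # the two decomposition paths telescope to the same total
  tests <- lat$tests
  stat <- function(nl, al) {
    tests$statistic[tests$null_model == nl & tests$alt_model == al]
  }
  path1 <- stat("omega-IGC", "omega+IGC") + stat("omega+IGC", "omegaHN+IGC")
  path2 <- stat("omega-IGC", "omegaHN-IGC") +
    stat("omegaHN-IGC", "omegaHN+IGC")
  expect_equal(path1, path2, tolerance = 1e-6)
  expect_equal(path1, stat("omega-IGC", "omegaHN+IGC"), tolerance = 1e-6)
})

test_that("parameters are recovered from simulated toy data", {
  code <- toy3()
  tree <- two_tip_tree()
  truth <- igc_params(pi = c(A = 0.45, C = 0.25, G = 0.3), kappa = 3,
                      omega = 0.3, tau = 0.5)
  sim <- simulate_igc(truth, tree, 3000, code, seed = 42)
  fit <- fit_igc(sim$alignment, tree, "omega+IGC", n_starts = 1,
                 control = list(factr = 1e9))
  est <- tidy(fit)
  expect_lt(abs(est$estimate[est$term == "omega"] - 0.3) / 0.3, 0.3)
  expect_lt(abs(est$estimate[est$term == "tau"] - 0.5) / 0.5, 0.4)
  expect_lt(abs(est$estimate[est$term == "kappa"] - 3) / 3, 0.4)
  # truth should beat a clearly perturbed parameter set on long data
  ll_truth <- log_likelihood(sim$alignment, tree, truth, code)
  worse <- igc_params(pi = truth$pi, kappa = 3, omega = 0.9, tau = 2.5)
  expect_gt(ll_truth, log_likelihood(sim$alignment, tree, worse, code))
})

test_that("paralog swap screen flags mislabeled orthology", {
  code <- toy3()
  tree <- two_tip_tree()
  truth <- igc_params(pi = c(A = 0.45, C = 0.25, G = 0.3), kappa = 2,
                      omega = 0.3, tau = 0.3)
  sim <- simulate_igc(truth, tree, 1500, code, seed = 9)
  opts <- list(n_starts = 1, control = list(factr = 1e9))
  ok <- do.call(paralog_swap_check,
                c(list(sim$alignment, tree, swap_taxon = "A"), opts))
  expect_equal(ok$status, "consistent")
  bad_aln <- swap_paralogs(sim$alignment, "A")
  bad <- do.call(paralog_swap_check,
                 c(list(bad_aln, tree, swap_taxon = "A"), opts))
  expect_equal(bad$status, "suspect")
  # identical paralogs: swap is a no-op, ties favor the given labels
  seqs <- c(Out = "AAAC", "A|0" = "AACA", "A|1" = "AACA",
            "B|0" = "ACAA", "B|1" = "ACAA")
  tie <- do.call(paralog_swap_check,
                 c(list(pair_alignment(seqs, code), tree, swap_taxon = "A"),
                   opts))
  expect_equal(tie$status, "consistent")
  expect_equal(tie$logLik_given, tie$logLik_swapped, tolerance = 1e-8)
})

test_that("branch length screen applies the cap", {
  fit <- igc_fit_from_params(toy2_params(), two_tip_tree(), toy2())
  sc <- branch_length_screen(fit)
  expect_true(all(sc$pass))
  expect_true(attr(sc, "pass"))
  long <- set_branch_lengths(two_tip_tree(), c(0.1, 0.1, 1.6, 0.1, 0.1))
  fit2 <- igc_fit_from_params(toy2_params(), long, toy2())
  sc2 <- branch_length_screen(fit2)
  expect_false(attr(sc2, "pass"))
  expect_equal(sum(!sc2$pass), 1)
  expect_true(attr(branch_length_screen(fit2, cap = 2), "pass"))
})

test_that("boundary flags mark tau at zero and omegaH at its cap", {
  code <- toy3()
  tree <- two_tip_tree()
  truth <- igc_params(pi = c(A = 0.45, C = 0.25, G = 0.3), kappa = 2,
                      omega = 0.3, tau = 0)
  sim <- simulate_igc(truth, tree, 600, code, seed = 4)
  fit <- fit_igc(sim$alignment, tree, "omega+IGC", n_starts = 1,
                 control = list(factr = 1e9))
  expect_true(fit$tau_at_boundary || fit$params$tau < 0.15)
  expect_s3_class(glance(fit), "tbl_df")
})
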