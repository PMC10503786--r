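test_that("duplication tree annotates regimes and countable branches", {
  tree <- two_tip_tree()
  ed <- tidy(tree)
  expect_equal(ed$regime[ed$child_label == "Out"], "single_copy")
  expect_equal(ed$regime[ed$child_label == "dup"], "single_copy")
  expect_equal(ed$regime[ed$child_label == "spec"], "pair")
  # the branch between duplication and first speciation is not countable
  expect_false(ed$countable[ed$child_label == "spec"])
  expect_setequal(ed$child_label[ed$countable], c("A", "B"))
  # explicit countable override
  tr2 <- read_duplication_tree(
    "(((A:0.15,B:0.15)spec:0.1)dup:0.1,Out:0.3)root;", "dup",
    countable = "A")
  expect_equal(sum(tidy(tr2)$countable), 1)
  expect_error(read_duplication_tree(
    "(((A:0.15,B:0.15)spec:0.1)dup:0.1,Out:0.3)root;", "dup",
    countable = "Out"), "pair regime")
  expect_error(read_duplication_tree(
    "((A:1,B:1)x:1,Out:1)root;", "nope"), "duplication_node")
})

test_that("alignment constructor validates codon content", {
  code <- standard_code()
  expect_error(pair_alignment(c(Out = "ATGTGAAAA"), code), "stop codon")
  expect_error(pair_alignment(c(Out = "ATGA"), code), "multiple")
  expect_error(pair_alignment(c("A|2" = "ATG"), code), "taxon")
  a <- pair_alignment(c(Out = "ATGAAA", "X|0" = "ATGAAA", "X|1" = "ATGAAG"),
                      code)
  expect_equal(a$n_col, 2)
  expect_true(a$taxa$paired[a$taxa$taxon == "X"])
  expect_false(a$taxa$paired[a$taxa$taxon == "Out"])
  ep <- empirical_pi(a)
  expect_equal(sum(ep), 1)
  expect_equal(unname(ep[["T"]]), 3 / 18)
})

test_that("pruning equals exhaustive ancestral-state summation", {
  code <- toy2()
  tree <- two_tip_tree()
  for (params in list(toy2_params(tau = 0.4),
                      igc_params(pi = c(A = 0.6, C = 0.4), kappa = 1,
                                 omega_h = 0.9, omega_n = 0.3, tau = 0.5))) {
    cols <- list(
      list(Out = "AA", A = c("AC", "CA"), B = c("AA", "AA")),
      list(Out = "CC", A = c("CC", "CC"), B = c("CA", "AC")),
      list(Out = "AC", A = c("AA", "CC"), B = c("CC", "AA"))
    )
    for (col in cols) {
      got <- site_log_likelihood(col, tree, params, code)
      want <- brute_force_ll(col$Out, col$A, col$B, params, code)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("site likelihoods sum to one over all possible columns", {
  code <- toy2()
  tree <- two_tip_tree()
  params <- toy2_params(tau = 0.6)
  n <- code$n
  grid <- expand.grid(o = 1:n, a0 = 1:n, a1 = 1:n, b0 = 1:n, b1 = 1:n)
  seqs <- c(
    Out = paste0(code$codons[grid$o], collapse = ""),
    "A|0" = paste0(code$codons[grid$a0], collapse = ""),
    "A|1" = paste0(code$codons[grid$a1], collapse = ""),
    "B|0" = paste0(code$codons[grid$b0], collapse = ""),
    "B|1" = paste0(code$codons[grid$b1], collapse = "")
  )
  aln <- pair_alignment(seqs, code)
  ll <- log_likelihood(aln, tree, params, code, per_site = TRUE)
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
})

test_that("tau = 0 joint likelihood factorizes over loci", {
  code <- toy2()
  tree <- two_tip_tree()
  p0 <- toy2_params(tau = 0)
  # independent-locus oracle: shared single-copy history to the
  # duplication, then each locus evolves independently below it
  srm <- single_rate_matrix(p0, code)
  Ps <- function(t) as.matrix(Matrix::expm(Matrix::Matrix(srm$q) * t))
  f <- srm$stationary
  n <- code$n
  col <- list(Out = "AA", A = c("AC", "CA"), B = c("AA", "CC"))
  P_out <- Ps(0.3); P_rd <- Ps(0.1); P_sp <- Ps(0.1); P_tip <- Ps(0.15)
  a <- match(col$A, code$codons); b <- match(col$B, code$codons)
  tot <- 0
  for (r in 1:n) for (d in 1:n) {
    pre <- f[r] * P_out[r, match(col$Out, code$codons)] * P_rd[r, d]
    loc <- 1
    for (lc in 1:2) {
      s_sum <- 0
      for (s in 1:n) s_sum <- s_sum + P_sp[d, s] * P_tip[s, a[lc]] *
          P_tip[s, b[lc]]
      loc <- loc * s_sum
    }
    tot <- tot + pre * loc
  }
  expect_equal(site_log_likelihood(col, tree, p0, code), log(tot),
               tolerance = 1e-10)
})

test_that("degenerate zero-length tree returns stationary log-frequency", {
  code <- toy2()
  params <- toy2_params(tau = 0.4)
  tree <- two_tip_tree()
  tree0 <- set_branch_lengths(tree, rep(0, nrow(tree$edges)))
  f <- single_rate_matrix(params, code)$stationary
  for (k in seq_len(code$n)) {
    cd <- code$codons[k]
    ll <- site_log_likelihood(list(Out = cd, A = c(cd, cd), B = c(cd, cd)),
                              tree0, params, code)
    expect_equal(ll, log(f[k]), tolerance = 1e-12)
  }
})

test_that("duplicated and permuted columns behave additively", {
  code <- toy2()
  tree <- two_tip_tree()
  params <- toy2_params()
  a1 <- pair_alignment(c(Out = "AAAA", "A|0" = "ACAC", "A|1" = "CACA",
                         "B|0" = "AAAA", "B|1" = "CCCC"), code)
  one <- pair_alignment(c(Out = "AA", "A|0" = "AC", "A|1" = "CA",
                          "B|0" = "AA", "B|1" = "CC"), code)
  expect_equal(log_likelihood(a1, tree, params),
               2 * log_likelihood(one, tree, params), tolerance = 1e-12)
  two <- pair_alignment(c(Out = "AACC", "A|0" = "ACCA", "A|1" = "CAAC",
                          "B|0" = "AAAA", "B|1" = "CCCC"), code)
  perm <- pair_alignment(c(Out = "CCAA", "A|0" = "CAAC", "A|1" = "ACCA",
                           "B|0" = "AAAA", "B|1" = "CCCC"), code)
  expect_equal(log_likelihood(perm, tree, params),
               log_likelihood(two, tree, params), tolerance = 1e-12)
})

test_that("map_duplication reads the pair diagonal", {
  n <- 4
  v <- rep(0, n * n)
  v[pair_index(3, 3, n)] <- 1
  expect_equal(map_duplication(v, n), c(0, 0, 1, 0))
  expect_equal(map_duplication(rep(0, n * n), n), rep(0, n))
  expect_equal(map_duplication(rep(1, n * n), n), rep(1, n))
  expect_error(map_duplication(rep(1, 5), 4), "length")
})

test_that("likelihood is invariant to a global paralog swap but not a local one", {
  code <- toy2()
  tree <- two_tip_tree()
  params <- toy2_params(tau = 0.5)
  aln <- pair_alignment(c(Out = "AA", "A|0" = "AC", "A|1" = "CA",
                          "B|0" = "AA", "B|1" = "CC"), code)
  both <- swap_paralogs(swap_paralogs(aln, "A"), "B")
  expect_equal(log_likelihood(both, tree, params),
               log_likelihood(aln, tree, params), tolerance = 1e-12)
  one <- swap_paralogs(aln, "A")
  expect_gt(abs(log_likelihood(one, tree, params) -
                  log_likelihood(aln, tree, params)), 1e-8)
})

test_that("missing codons are marginalized over compatible states", {
  code <- toy2()
  tree <- two_tip_tree()
  params <- toy2_params()
  miss <- pair_alignment(c(Out = "NN", "A|0" = "AC", "A|1" = "CA",
                           "B|0" = "AA", "B|1" = "CC"), code)
  tot <- 0
  for (o in code$codons) {
    tot <- tot + exp(site_log_likelihood(
      list(Out = o, A = c("AC", "CA"), B = c("AA", "CC")),
      tree, params, code))
  }
  expect_equal(log_likelihood(miss, tree, params), log(tot),
               tolerance = 1e-10)
})
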