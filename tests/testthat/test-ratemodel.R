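test_that("single-locus rates follow the F1x4 + kappa + omega scheme", {
  code <- standard_code()
  # all factors 1: every admissible single-nucleotide change has rate pi_h
  p1 <- igc_params(kappa = 1, omega = 1)
  q <- single_rate_matrix(p1, code, normalize = FALSE)$q
  off <- q[q > 0 & row(q) != col(q)]
  expect_true(all(abs(off - 0.25) < 1e-12))
  # transition/transversion and frequency ratio
  p <- igc_params(pi = c(A = 0.35, C = 0.15, G = 0.2, T = 0.3),
                  kappa = 2.5, omega = 0.3)
  q <- single_rate_matrix(p, code, normalize = FALSE)$q
  i <- match("ATG", code$codons)
  jC <- match("CTG", code$codons)  # A->C transversion
  jG <- match("GTG", code$codons)  # A->G transition
  expect_equal(q[i, jC] / q[i, jG], (0.15 / 0.2) / 2.5, tolerance = 1e-12)
})

test_that("partner amino acid selects omegaH vs omegaN for point rates", {
  code <- standard_code()
  p <- igc_params(kappa = 2, omega_h = 0.8, omega_n = 0.2)
  m <- single_rate_matrix(p, code, partner_aa = "L", u = 1)
  i <- match("TTT", code$codons)
  j_hom <- match("TTA", code$codons)   # Phe -> Leu, matches partner: omegaH
  j_non <- match("TGT", code$codons)   # Phe -> Cys: omegaN
  pi <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_equal(m$q[i, j_hom], pi[["A"]] * 0.8, tolerance = 1e-12)
  expect_equal(m$q[i, j_non], pi[["G"]] * 0.2, tolerance = 1e-12)
})

test_that("normalization makes stationary point flux one per codon", {
  code <- standard_code()
  pw <- igc_params(pi = c(A = 0.35, C = 0.15, G = 0.2, T = 0.3),
                   kappa = 2, omega = 0.3)
  srm <- single_rate_matrix(pw, code)
  expect_equal(sum(srm$stationary * -diag(srm$q)), 1, tolerance = 1e-10)
  ph <- igc_params(pi = c(A = 0.35, C = 0.15, G = 0.2, T = 0.3),
                   kappa = 2, omega_h = 0.8, omega_n = 0.2)
  prm <- pair_rate_matrix(ph, code)
  flux <- 0.5 * sum(prm$stationary_tau0 * Matrix::rowSums(prm$q_point))
  expect_equal(flux, 1, tolerance = 1e-10)
})

test_that("u matches a brute-force enumeration oracle", {
  # independent re-derivation over the full 61-codon space
  tab <- Biostrings::GENETIC_CODE
  codons <- sort(names(tab)[tab != "*"])
  pi <- c(A = 0.3, C = 0.2, G = 0.24, T = 0.26)
  kappa <- 1.7; omega <- 0.4
  f <- vapply(strsplit(codons, ""), function(x) prod(pi[x]), numeric(1))
  f <- f / sum(f)
  is_ts <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  flux <- 0
  for (i in seq_along(codons)) {
    ci <- strsplit(codons[i], "")[[1]]
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ci[p])) {
      cj <- ci; cj[p] <- b
      j <- paste0(cj, collapse = "")
      if (!j %in% codons) next
      r <- pi[[b]] * (if (is_ts(ci[p], b)) kappa else 1) *
        (if (tab[[codons[i]]] == tab[[j]]) 1 else omega)
      flux <- flux + f[i] * r
    }
  }
  u_oracle <- 1 / flux
  code <- standard_code()
  expect_equal(normalize_u(igc_params(pi = pi, kappa = kappa, omega = omega),
                           code),
               u_oracle, tolerance = 1e-12)
})

test_that("omegaH = omegaN collapses to the one-omega model", {
  for (code in list(toy2(), standard_code())) {
    pw <- igc_params(pi = NULL, kappa = 2, omega = 0.35, tau = 0.3)
    ph <- igc_params(pi = NULL, kappa = 2, omega_h = 0.35, omega_n = 0.35,
                     tau = 0.3)
    expect_equal(normalize_u(ph, code), normalize_u(pw, code),
                 tolerance = 1e-12)
    a <- pair_rate_matrix(ph, code)
    b <- pair_rate_matrix(pw, code)
    expect_equal(max(abs(a$q - b$q)), 0, tolerance = 1e-12)
  }
})

test_that("pair matrix composes point and IGC rates per the five cases", {
  code <- standard_code()
  p <- igc_params(kappa = 2, omega_h = 0.8, omega_n = 0.2, tau = 0.5)
  prm <- pair_rate_matrix(p, code)
  n <- code$n
  ix <- function(a, b) pair_index(match(a, code$codons),
                                  match(b, code$codons), n)
  # point transversion to the partner's codon + IGC copy: u*piA*omegaH + omegaH*tau
  r <- prm$q[ix("TTT", "TTA"), ix("TTA", "TTA")]
  expect_equal(r, prm$u * 0.25 * 0.8 + 0.8 * 0.5, tolerance = 1e-12)
  # three-nucleotide difference: pure IGC
  r <- prm$q[ix("CCT", "GGG"), ix("GGG", "GGG")]
  expect_equal(r, 0.8 * 0.5, tolerance = 1e-12)
  # both-loci changes are impossible
  expect_equal(prm$q[ix("TTT", "TTT"), ix("TTA", "TTA")], 0)
  # IGC never leaves the identical-pair diagonal
  expect_equal(sum(prm$q_igc[ix("AAA", "AAA"), ]), 0)
})

test_that("tau = 0 pair generator is the Kronecker sum of single-locus ones", {
  for (code in list(toy2(), toy3())) {
    p <- igc_params(pi = NULL, kappa = 1.5, omega = 0.4, tau = 0)
    srm <- single_rate_matrix(p, code)
    prm <- pair_rate_matrix(p, code)
    n <- code$n
    K <- kronecker(srm$q, diag(n)) + kronecker(diag(n), srm$q)
    expect_lt(max(abs(as.matrix(prm$q) - K)), 1e-12)
  }
})

test_that("rate matrices satisfy structural invariants", {
  code <- toy3()
  p <- igc_params(pi = c(A = 0.5, C = 0.2, G = 0.3), kappa = 2.2,
                  omega_h = 0.7, omega_n = 0.15, tau = 0.6)
  prm <- pair_rate_matrix(p, code)
  expect_lt(max(abs(Matrix::rowSums(prm$q))), 1e-10)
  expect_true(all(prm$q[row(as.matrix(prm$q)) != col(as.matrix(prm$q))] >= 0))
  # label decomposition conserves the off-diagonal generator
  lab <- Reduce(`+`, prm$labels)
  off <- prm$q - Matrix::Diagonal(nrow(prm$q), Matrix::diag(prm$q))
  expect_lt(max(abs(lab - off)), 1e-12)
  # the triplet export reproduces the additive split
  tr <- rate_triplets(prm)
  expect_equal(tr$rate, tr$point_rate + tr$igc_rate, tolerance = 1e-12)
})

test_that("tau0 stationary distribution matches the null-space solve", {
  for (code in list(toy2(), toy3())) {
    p <- igc_params(pi = NULL, kappa = 1.8, omega_h = 0.9, omega_n = 0.25,
                    tau = 0)
    s_closed <- stationary_tau0(p, code)
    s_solve <- stationary_tau0(p, code, method = "solve")
    expect_equal(s_closed, s_solve, tolerance = 1e-9)
    expect_equal(sum(s_closed), 1, tolerance = 1e-12)
    pw <- igc_params(pi = NULL, kappa = 1.8, omega = 0.25)
    f <- codon_freqs(pw, code)
    expect_equal(stationary_tau0(pw, code),
                 as.numeric(t(outer(f, f))), tolerance = 1e-12)
  }
})

test_that("tau0 closed form holds on the full 61^2-state chain", {
  code <- standard_code()
  p <- igc_params(pi = c(A = 0.3, C = 0.2, G = 0.24, T = 0.26),
                  kappa = 2, omega_h = 0.8, omega_n = 0.2, tau = 0)
  s_closed <- stationary_tau0(p, code)
  s_solve <- stationary_tau0(p, code, method = "solve")
  expect_equal(s_closed, s_solve, tolerance = 1e-9)
})

test_that("invalid parameters are rejected", {
  expect_error(igc_params(kappa = 2), "supply omega")
  expect_error(igc_params(omega = 0.2, omega_h = 1, omega_n = 0.1), "not both")
  expect_error(igc_params(omega = -1), "nonnegative")
  expect_error(igc_params(pi = c(A = 0.7, C = 0.7), omega = 1), "sum to 1")
})
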