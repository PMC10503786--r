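#' Model parameters for the paralog-pair codon process
#'
#' Bundles the parameters of the point-mutation codon model (F1x4
#' nucleotide frequencies, transition/transversion ratio kappa, and either
#' a single nonsynonymous factor omega or the homogenizing/nonhomogenizing
#' pair omegaH/omegaN) together with the IGC intensity tau. Setting
#' `tau = 0` recovers independent evolution of the two paralogs given
#' their shared pre-duplication history.
#'
#' @param pi Named numeric vector of nucleotide frequencies over the
#'   code's alphabet (must sum to 1). Defaults to equal frequencies.
#' @param kappa Transition/transversion rate ratio, >= 0.
#' @param omega Nonsynonymous/synonymous factor for the one-omega model.
#'   Supply either `omega`, or both `omega_h` and `omega_n`.
#' @param omega_h,omega_n Homogenizing and nonhomogenizing nonsynonymous
#'   factors: a nonsynonymous change gets factor `omega_h` when it makes
#'   the changed codon encode the same amino acid as the partner codon,
#'   and `omega_n` otherwise.
#' @param tau IGC intensity >= 0: the added rate at which a codon is
#'   replaced wholesale by the partner's codon (scaled by the applicable
#'   omega factor when the copy is nonsynonymous).
#' @return An `igc_params` object with a `mode` field of `"omega"` or
#'   `"omega_h_n"`.
#' @export
#' @examples
#' igc_params(kappa = 3, omega = 0.1, tau = 0.2)
#' igc_params(kappa = 3, omega_h = 0.5, omega_n = 0.1, tau = 0.2)
igc_params <- function(pi = NULL, kappa = 1, omega = NULL,
                       omega_h = NULL, omega_n = NULL, tau = 0) {
  has_w <- !is.null(omega)
  has_hn <- !is.null(omega_h) || !is.null(omega_n)
  if (has_w && has_hn) {
    stop("supply either omega, or omega_h and omega_n, not both", call. = FALSE)
  }
  if (has_hn && (is.null(omega_h) || is.null(omega_n))) {
    stop("omega_h and omega_n must be supplied together", call. = FALSE)
  }
  if (!has_w && !has_hn) {
    stop("supply omega, or omega_h and omega_n", call. = FALSE)
  }
  mode <- if (has_w) "omega" else "omega_h_n"
  p <- structure(
    list(pi = pi, kappa = kappa, omega = omega,
         omega_h = omega_h, omega_n = omega_n, tau = tau, mode = mode),
    class = "igc_params"
  )
  validate_igc_params(p)
}

validate_igc_params <- function(p, code = NULL) {
  num_ok <- function(x) is.null(x) || (is.numeric(x) && length(x) == 1L &&
                                         is.finite(x) && x >= 0)
  if (!num_ok(p$kappa) || !num_ok(p$omega) || !num_ok(p$omega_h) ||
      !num_ok(p$omega_n) || !num_ok(p$tau)) {
    stop("kappa, omega factors and tau must be finite nonnegative scalars",
         call. = FALSE)
  }
  if (!is.null(p$pi)) {
    if (any(p$pi < 0) || any(p$pi > 1) || abs(sum(p$pi) - 1) > 1e-8) {
      stop("nucleotide frequencies must lie in [0,1] and sum to 1",
           call. = FALSE)
    }
    if (!is.null(code) && !setequal(names(p$pi), code$alphabet)) {
      stop("pi must be named by the code's nucleotide alphabet", call. = FALSE)
    }
  }
  p
}

#' @export
print.igc_params <- function(x, ...) {
  ws <- if (x$mode == "omega") {
    sprintf("omega=%.4g", x$omega)
  } else {
    sprintf("omegaH=%.4g omegaN=%.4g", x$omega_h, x$omega_n)
  }
  cat(sprintf("<igc_params mode=%s kappa=%.4g %s tau=%.4g>\n",
              x$mode, x$kappa, ws, x$tau))
  invisible(x)
}

params_pi <- function(params, code) {
  if (is.null(params$pi)) {
    stats::setNames(rep(1 / length(code$alphabet), length(code$alphabet)),
                    code$alphabet)
  } else {
    params$pi[code$alphabet]
  }
}

# Nonsynonymous factor of a point change given the partner's amino acid.
omega_factor <- function(params, aa_to, partner_aa = NULL) {
  if (params$mode == "omega") {
    rep(params$omega, length(aa_to))
  } else {
    if (is.null(partner_aa)) {
      stop("partner_aa is required for omega_h_n point rates", call. = FALSE)
    }
    ifelse(aa_to == partner_aa, params$omega_h, params$omega_n)
  }
}

#' F1x4 sense-codon stationary frequencies
#'
#' Product of position-wise nucleotide frequencies over the codon
#' positions, restricted to sense codons and renormalized: the stationary
#' distribution of the single-locus point process.
#'
#' @param params An `igc_params` object.
#' @param code A `genetic_code`.
#' @return Numeric vector over sense codons, summing to 1.
#' @export
codon_freqs <- function(params, code) {
  pi <- params_pi(params, code)
  mat <- do.call(rbind, strsplit(code$codons, ""))
  f <- apply(mat, 1, function(r) prod(pi[r]))
  f / sum(f)
}

# Unnormalized single-locus point rate matrix (no diagonal).
# partner_aa selects omega_h vs omega_n for nonsynonymous targets under
# the omega_h_n mode; a single omega factor may be forced via `omega_as`.
single_q_unnorm <- function(params, code, partner_aa = NULL, omega_as = NULL) {
  n <- code$n
  pi <- params_pi(params, code)
  mv <- code$moves
  base <- unname(pi[mv$to_nt]) * ifelse(mv$transition, params$kappa, 1)
  wfac <- if (!is.null(omega_as)) {
    ifelse(mv$synonymous, 1, omega_as)
  } else {
    ifelse(mv$synonymous, 1, omega_factor(params, mv$aa_to, partner_aa))
  }
  q <- matrix(0, n, n)
  q[cbind(mv$from, mv$to)] <- base * wfac
  q
}

# Parameters of the single-copy (pre-duplication / outgroup) intervals:
# under omega_h_n there is no partner, and omegaN is used as the
# nonsynonymous rate factor for these intervals.
single_interval_params <- function(params) {
  if (params$mode == "omega") {
    params
  } else {
    p <- params
    p$mode <- "omega"
    p$omega <- params$omega_n
    p$omega_h <- NULL
    p$omega_n <- NULL
    p
  }
}

#' Single-locus codon rate matrix
#'
#' Builds the point-mutation rate matrix over sense codons. Under the
#' one-omega mode this is the F1x4+kappa+omega Muse-Gaut-style matrix.
#' Under the omegaH/omegaN mode the nonsynonymous factor of a change to
#' amino acid `a` is `omega_h` when `a` equals `partner_aa` and `omega_n`
#' otherwise, so `partner_aa` is required; the normalization constant for
#' that case lives at the pair-chain level and must be passed via `u`.
#' With `partner_aa = NULL` and mode `omega_h_n`, the single-copy interval
#' convention applies: omegaN is used and the interval is normalized on
#' its own.
#'
#' @param params An `igc_params` object.
#' @param code A `genetic_code`.
#' @param partner_aa Optional amino-acid symbol of the partner codon.
#' @param normalize Apply the normalization constant `u` (expected
#'   point-mutation substitutions per codon = 1 at stationarity).
#' @param u Optional externally supplied normalization constant.
#' @return A `single_rate_matrix`: list with `q` (dense, rows sum to 0),
#'   `u`, and `stationary` (F1x4 sense-codon frequencies).
#' @export
single_rate_matrix <- function(params, code, partner_aa = NULL,
                               normalize = TRUE, u = NULL) {
  validate_igc_params(params, code)
  if (params$mode == "omega_h_n" && is.null(partner_aa)) {
    params <- single_interval_params(params)
  }
  q <- single_q_unnorm(params, code, partner_aa)
  if (is.null(u)) {
    u <- if (normalize) {
      if (!is.null(partner_aa)) {
        stop("supply u explicitly when building a partner-conditional matrix",
             call. = FALSE)
      }
      normalize_u(params, code)
    } else 1
  }
  q <- q * u
  diag(q) <- -rowSums(q)
  structure(
    list(q = q, u = u, stationary = codon_freqs(params, code),
         params = params, code = code),
    class = "single_rate_matrix"
  )
}

# Synonymous and per-amino-acid nonsynonymous exit weights of each codon:
# S[i] = sum of pi_h * kappa^ts over synonymous moves from i;
# N[i, a] = the same sum over nonsynonymous moves whose target encodes a.
exit_weights <- function(params, code) {
  pi <- params_pi(params, code)
  mv <- code$moves
  base <- unname(pi[mv$to_nt]) * ifelse(mv$transition, params$kappa, 1)
  aas <- sort(unique(unname(code$aa)))
  S <- vapply(seq_len(code$n), function(i) {
    sum(base[mv$from == i & mv$synonymous])
  }, numeric(1))
  N <- matrix(0, code$n, length(aas), dimnames = list(NULL, aas))
  ns <- !mv$synonymous
  if (any(ns)) {
    agg <- stats::aggregate(base[ns],
                            by = list(from = mv$from[ns], aa = mv$aa_to[ns]),
                            FUN = sum)
    N[cbind(agg$from, match(agg$aa, aas))] <- agg$x
  }
  list(S = S, N = N, aas = aas)
}

#' Stationary distribution of the pair chain at tau = 0
#'
#' With IGC absent the two loci evolve independently given shared
#' parameters. Under the one-omega mode the stationary distribution is the
#' outer product of the single-locus F1x4 codon frequencies. Under the
#' omegaH/omegaN mode the chain remains reversible and has the closed form
#' pi(i, i') proportional to f(i) f(i') (omegaH/omegaN)^(aa(i) == aa(i')).
#' `method = "solve"` instead solves the global-balance equations
#' numerically (the oracle used to validate the closed form).
#'
#' @param params An `igc_params` object (tau is treated as 0).
#' @param code A `genetic_code`.
#' @param method `"closed_form"` (default) or `"solve"`.
#' @return Numeric vector of length `code$n^2`, summing to 1, indexed by
#'   [pair_index()].
#' @export
stationary_tau0 <- function(params, code,
                            method = c("closed_form", "solve")) {
  method <- match.arg(method)
  if (method == "closed_form") {
    f <- codon_freqs(params, code)
    P2 <- outer(f, f)
    if (params$mode == "omega_h_n") {
      if (params$omega_n <= 0) {
        stop("closed form requires omega_n > 0; use method = 'solve'",
             call. = FALSE)
      }
      same <- outer(code$aa, code$aa, `==`)
      P2 <- P2 * ifelse(same, params$omega_h / params$omega_n, 1)
    }
    # pair_index varies the second locus fastest, so flatten row-major
    v <- as.numeric(t(P2))
    return(v / sum(v))
  }
  p0 <- params
  p0$tau <- 0
  prm <- pair_rate_matrix(p0, code, normalize = FALSE)
  Q <- as.matrix(prm$q)
  A <- t(Q)
  A[nrow(A), ] <- 1
  b <- c(rep(0, nrow(A) - 1L), 1)
  sol <- solve(A, b)
  if (any(sol < -1e-8)) {
    stop("global-balance solution is not a distribution (disconnected chain?)",
         call. = FALSE)
  }
  sol[sol < 0] <- 0
  sol / sum(sol)
}

#' Normalization constant u
#'
#' Computes `u` such that, with `tau = 0`, the stationary expected rate of
#' substitutions per codon that originate from point mutation equals 1.
#' Under the one-omega mode this uses the single-locus chain at its F1x4
#' stationary distribution. Under the omegaH/omegaN mode the rate at one
#' locus depends on the partner's amino acid, so the pair chain (n^2
#' states) at its tau = 0 stationary distribution is used and the total
#' expected pair flux is halved (a pair state covers two codons). `u` is
#' not recomputed as tau varies.
#'
#' @param params An `igc_params` object.
#' @param code A `genetic_code`.
#' @return The scalar normalization constant.
#' @export
normalize_u <- function(params, code) {
  validate_igc_params(params, code)
  if (params$mode == "omega") {
    f <- codon_freqs(params, code)
    q <- single_q_unnorm(params, code)
    1 / sum(f * rowSums(q))
  } else {
    ew <- exit_weights(params, code)
    aa_idx <- match(unname(code$aa), ew$aas)
    # exit1[i, ip]: unnormalized point exit rate of locus 1 codon i when
    # the partner encodes aa(ip)
    Nsame <- ew$N[, aa_idx, drop = FALSE]          # N[i, aa(ip)]
    Ntot <- rowSums(ew$N)
    exit1 <- ew$S + params$omega_h * Nsame +
      params$omega_n * (Ntot - Nsame)              # n x n matrix
    pv <- stationary_tau0(params, code)
    P2 <- matrix(pv, code$n, code$n, byrow = TRUE)  # P2[i, ip]
    # locus 2 exit: exit of codon ip given partner aa(i), i.e. exit1[ip, i]
    flux <- sum(P2 * (exit1 + t(exit1)))
    1 / (0.5 * flux)
  }
}

#' Joint rate matrix over ordered codon pairs, with origin labels
#'
#' Builds the n^2-state instantaneous rate matrix of the joint two-paralog
#' process. Only one locus may change at a time. A change of locus 1 from
#' i to j with partner i' has rate `Q[i,j] + nu * (j == i')`: the
#' point-mutation rate (zero when i and j differ at more than one
#' nucleotide) plus, when the change copies the partner's codon, the IGC
#' rate `nu` -- `tau` for a synonymous copy, `omega * tau` or
#' `omega_h * tau` for a nonsynonymous (always homogenizing) copy.
#' Point and IGC components are stored separately, along with five label
#' matrices (igc_syn, igc_nonsyn, point_syn, point_nonsyn_hom,
#' point_nonsyn_nonhom) whose sum reproduces the off-diagonal rates.
#'
#' @param params An `igc_params` object.
#' @param code A `genetic_code`.
#' @param normalize Apply the tau = 0 normalization constant `u` to the
#'   point components.
#' @param with_labels Build the five label matrices (skipped inside the
#'   optimizer, where only `q` is needed).
#' @param dense Assemble base dense matrices instead of sparse ones
#'   (faster for small toy codes; ignored for large state spaces).
#' @return A `pair_rate_matrix`: sparse `q`, `q_point`, `q_igc`, the
#'   `labels` list, `u`, and `stationary_tau0`.
#' @export
pair_rate_matrix <- function(params, code, normalize = TRUE,
                             with_labels = TRUE, dense = FALSE) {
  validate_igc_params(params, code)
  n <- code$n
  N2 <- n * n
  u <- if (normalize) normalize_u(params, code) else 1
  mv <- code$moves
  pi <- params_pi(params, code)
  base <- unname(pi[mv$to_nt]) * ifelse(mv$transition, params$kappa, 1)
  M <- nrow(mv)
  partner <- rep(seq_len(n), each = M)
  mfrom <- rep(mv$from, n); mto <- rep(mv$to, n)
  mbase <- rep(base, n); msyn <- rep(mv$synonymous, n)
  maa_to <- rep(mv$aa_to, n)
  partner_aa <- unname(code$aa[partner])
  wfac <- ifelse(msyn, 1,
                 if (params$mode == "omega") params$omega
                 else ifelse(maa_to == partner_aa, params$omega_h,
                             params$omega_n))
  rate1 <- u * mbase * wfac
  hom <- !msyn & maa_to == partner_aa
  # locus 1 changes: (i, p) -> (j, p)
  from1 <- pair_index(mfrom, partner, n)
  to1 <- pair_index(mto, partner, n)
  # locus 2 changes: (p, i) -> (p, j); same rates by locus exchangeability
  from2 <- pair_index(partner, mfrom, n)
  to2 <- pair_index(partner, mto, n)
  p_from <- c(from1, from2); p_to <- c(to1, to2)
  p_rate <- c(rate1, rate1)
  p_syn <- c(msyn, msyn); p_hom <- c(hom, hom)

  # IGC: from any (i, p) with i != p, locus 1 copies the partner -> (p, p)
  # and locus 2 copies locus 1 -> (i, i)
  ii <- rep(seq_len(n), each = n)
  pp <- rep(seq_len(n), times = n)
  off <- ii != pp
  gi <- ii[off]; gp <- pp[off]
  g_syn <- unname(code$aa[gi]) == unname(code$aa[gp])
  nu_nonsyn <- if (params$mode == "omega") params$omega * params$tau
               else params$omega_h * params$tau
  g_rate <- ifelse(g_syn, params$tau, nu_nonsyn)
  g_from <- c(pair_index(gi, gp, n), pair_index(gi, gp, n))
  g_to <- c(pair_index(gp, gp, n), pair_index(gi, gi, n))
  g_rate2 <- c(g_rate, g_rate)
  g_syn2 <- c(g_syn, g_syn)

  dense <- dense && N2 <= 4096
  spm <- if (dense) {
    function(i, j, x) {
      m <- matrix(0, N2, N2)
      m[cbind(i, j)] <- x
      m
    }
  } else {
    function(i, j, x) {
      keep <- x != 0
      Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                           dims = c(N2, N2))
    }
  }
  q_point <- spm(p_from, p_to, p_rate)
  q_igc <- spm(g_from, g_to, g_rate2)
  labels <- if (!with_labels) NULL else list(
    igc_syn = spm(g_from[g_syn2], g_to[g_syn2], g_rate2[g_syn2]),
    igc_nonsyn = spm(g_from[!g_syn2], g_to[!g_syn2], g_rate2[!g_syn2]),
    point_syn = spm(p_from[p_syn], p_to[p_syn], p_rate[p_syn]),
    point_nonsyn_hom = spm(p_from[!p_syn & p_hom], p_to[!p_syn & p_hom],
                           p_rate[!p_syn & p_hom]),
    point_nonsyn_nonhom = spm(p_from[!p_syn & !p_hom],
                              p_to[!p_syn & !p_hom],
                              p_rate[!p_syn & !p_hom])
  )
  q <- q_point + q_igc
  q <- if (dense) q - diag(rowSums(q))
       else q - Matrix::Diagonal(N2, x = Matrix::rowSums(q))
  structure(
    list(q = q, q_point = q_point, q_igc = q_igc, labels = labels, u = u,
         stationary_tau0 = stationary_tau0(params, code),
         params = params, code = code, n_states = N2),
    class = "pair_rate_matrix"
  )
}

#' @export
print.pair_rate_matrix <- function(x, ...) {
  cat(sprintf("<pair_rate_matrix: %d states (%d codons), mode=%s, tau=%.4g, u=%.6g>\n",
              x$n_states, x$code$n, x$params$mode, x$params$tau, x$u))
  invisible(x)
}

#' Export a pair rate matrix as a labeled triplet table
#'
#' @param prm A `pair_rate_matrix`.
#' @return A tibble with columns `from`, `to` (1-based pair indices),
#'   `rate`, `point_rate`, `igc_rate` for every nonzero off-diagonal entry.
#' @export
rate_triplets <- function(prm) {
  tq <- Matrix::summary(methods::as(prm$q_point + prm$q_igc, "TsparseMatrix"))
  pt <- prm$q_point[cbind(tq$i, tq$j)]
  ig <- prm$q_igc[cbind(tq$i, tq$j)]
  tibble::tibble(from = tq$i, to = tq$j, rate = tq$x,
                 point_rate = as.numeric(pt), igc_rate = as.numeric(ig)) |>
    dplyr::arrange(.data$from, .data$to)
}
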