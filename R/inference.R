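#' Model tags
#'
#' The four model variants form a lattice: `"omega-IGC"` (one
#' nonsynonymous factor, no IGC) is nested in `"omega+IGC"` and
#' `"omegaHN-IGC"`, both of which are nested in `"omegaHN+IGC"`.
#'
#' @name model_tags
#' @keywords internal
NULL

MODEL_TAGS <- c("omega-IGC", "omega+IGC", "omegaHN-IGC", "omegaHN+IGC")

parse_model_tag <- function(model) {
  model <- gsub("ωH/ωN", "omegaHN", model)
  model <- gsub("ω", "omega", model)
  model <- gsub("−", "-", model)
  if (!model %in% MODEL_TAGS) {
    stop(sprintf("unknown model tag; use one of %s",
                 paste(MODEL_TAGS, collapse = ", ")), call. = FALSE)
  }
  list(tag = model,
       mode = if (startsWith(model, "omegaHN")) "omega_h_n" else "omega",
       igc = endsWith(model, "+IGC"))
}

#' Maximum-likelihood fit of one model variant
#'
#' Maximizes the log-(composite-)likelihood over kappa, the omega
#' factor(s), tau (when the model includes IGC) and all branch lengths.
#' Positive parameters are optimized on the log scale; tau is optimized on
#' its natural scale with a lower bound at 0 so the boundary is reachable;
#' omegaH is capped (default 1000) and a boundary flag is raised when the
#' estimate hits the cap, the finite representation of an effectively
#' infinite homogenizing rate. Multistart initial points are jittered
#' deterministically from `seed`.
#'
#' @param alignment A `pair_alignment`.
#' @param tree A `duplication_tree` (its branch lengths seed the optimizer).
#' @param model One of `"omega-IGC"`, `"omega+IGC"`, `"omegaHN-IGC"`,
#'   `"omegaHN+IGC"`.
#' @param code A `genetic_code`.
#' @param pi `"empirical"` (F1x4 frequencies counted from the alignment,
#'   the default), `"ml"` (estimated by maximum likelihood via a softmax
#'   transform), or a named numeric vector of fixed frequencies.
#' @param n_starts Number of multistart optimizations.
#' @param seed Integer seed controlling the multistart jitter.
#' @param omega_h_cap Upper bound for omegaH.
#' @param init Optional named list overriding initial values
#'   (`kappa`, `omega`, `omega_h`, `omega_n`, `tau`).
#' @param control Passed to [stats::optim()] (method `"L-BFGS-B"`).
#' @return An `igc_fit` with the model tag, the `igc_params` at the
#'   optimum, the tree with fitted branch lengths, the maximized
#'   log-likelihood, convergence diagnostics and boundary flags.
#' @export
fit_igc <- function(alignment, tree, model, code = alignment$code,
                    pi = "empirical", n_starts = 3, seed = 1,
                    omega_h_cap = 1e3, init = NULL,
                    control = list()) {
  mt <- parse_model_tag(model)
  ml_pi <- identical(pi, "ml")
  pi_fixed <- if (is.numeric(pi)) {
    validate_igc_params(igc_params(pi = pi[code$alphabet], omega = 1),
                        code)$pi
  } else if (identical(pi, "empirical")) {
    empirical_pi(alignment)
  } else if (ml_pi) {
    empirical_pi(alignment)  # starting point for the softmax parameters
  } else {
    stop("pi must be 'empirical', 'ml' or a named numeric vector",
         call. = FALSE)
  }
  na <- length(code$alphabet)

  defaults <- list(kappa = 2, omega = 0.2, omega_h = 0.4, omega_n = 0.15,
                   tau = 0.3)
  defaults[names(init)] <- init
  br0 <- pmax(tree$edges$length, 0.02)

  n_edge <- nrow(tree$edges)
  theta_names <- c("log_kappa",
                   if (mt$mode == "omega") "log_omega"
                   else c("log_omega_n", "log_omega_h"),
                   if (mt$igc) "tau",
                   paste0("len", seq_len(n_edge)),
                   if (ml_pi) paste0("pi_raw", seq_len(na - 1)))
  base_theta <- c(log(defaults$kappa),
                  if (mt$mode == "omega") log(defaults$omega)
                  else c(log(defaults$omega_n), log(defaults$omega_h)),
                  if (mt$igc) defaults$tau,
                  log(br0),
                  if (ml_pi) log(pi_fixed[-na] / pi_fixed[na]))
  lower <- c(-7,
             if (mt$mode == "omega") -9 else c(-9, -9),
             if (mt$igc) 0,
             rep(log(1e-6), n_edge),
             if (ml_pi) rep(-12, na - 1))
  upper <- c(7,
             if (mt$mode == "omega") log(omega_h_cap)
             else c(log(omega_h_cap), log(omega_h_cap)),
             if (mt$igc) 100,
             rep(log(10), n_edge),
             if (ml_pi) rep(12, na - 1))

  unpack <- function(theta) {
    i <- 1L
    kappa <- exp(theta[i]); i <- i + 1L
    if (mt$mode == "omega") {
      omega <- exp(theta[i]); i <- i + 1L
      w <- list(omega = omega)
    } else {
      w <- list(omega_n = exp(theta[i]), omega_h = exp(theta[i + 1L]))
      i <- i + 2L
    }
    tau <- if (mt$igc) { v <- theta[i]; i <- i + 1L; v } else 0
    lens <- exp(theta[i:(i + n_edge - 1L)]); i <- i + n_edge
    pv <- if (ml_pi) {
      raw <- c(theta[i:(i + na - 2L)], 0)
      e <- exp(raw - max(raw))
      stats::setNames(e / sum(e), code$alphabet)
    } else pi_fixed
    params <- do.call(igc_params, c(list(pi = pv, kappa = kappa, tau = tau), w))
    list(params = params, lens = lens)
  }

  cp <- compress_patterns(alignment, tree)
  n_eval <- 0L
  nll <- function(theta) {
    n_eval <<- n_eval + 1L
    up <- unpack(theta)
    tr <- set_branch_lengths(tree, up$lens)
    val <- tryCatch({
      prm <- pair_rate_matrix(up$params, code, with_labels = FALSE,
                              dense = code$n^2 <= 1024)
      srm <- single_rate_matrix(single_interval_params(up$params), code)
      pr <- prune_patterns(alignment, tr, up$params, code, prm = prm,
                           srm = srm, cp = cp)
      sum(pr$site_ll * cp$weights)
    }, error = function(e) -Inf)
    if (!is.finite(val)) 1e10 else -val
  }

  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e7), control)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- base_theta
    if (s > 1) {
      th0 <- th0 + stats::rnorm(length(th0), 0, 0.4)
      th0 <- pmin(pmax(th0, lower), upper)
      if (mt$igc) {
        k <- which(theta_names == "tau")
        th0[k] <- abs(base_theta[k] + stats::rnorm(1, 0, 0.3))
      }
    }
    res <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  up <- unpack(best$par)
  tau_hat <- up$params$tau
  structure(
    list(
      model = mt$tag,
      params = up$params,
      tree = set_branch_lengths(tree, up$lens),
      logLik = -best$value,
      n_col = alignment$n_col,
      convergence = best$convergence,
      message = best$message,
      n_eval = n_eval,
      n_starts = n_starts,
      seed = seed,
      tau_at_boundary = mt$igc && tau_hat < 1e-6,
      omega_h_at_cap = mt$mode == "omega_h_n" &&
        up$params$omega_h > 0.999 * omega_h_cap,
      omega_h_cap = omega_h_cap,
      pi_policy = if (ml_pi) "ml" else if (is.numeric(pi)) "fixed"
                  else "empirical",
      code = code
    ),
    class = "igc_fit"
  )
}

#' Wrap known parameters as a fit object
#'
#' Builds an `igc_fit` from externally supplied (e.g., true, simulated)
#' parameter values without optimizing, so expected-count and screening
#' machinery can be run under known parameters.
#'
#' @param params An `igc_params` object.
#' @param tree A `duplication_tree` carrying the branch lengths to use.
#' @param code A `genetic_code`.
#' @param model Optional model tag; derived from `params` if omitted.
#' @param logLik Optional log-likelihood to record.
#' @return An `igc_fit`.
#' @export
igc_fit_from_params <- function(params, tree, code, model = NULL,
                                logLik = NA_real_) {
  if (is.null(model)) {
    model <- paste0(if (params$mode == "omega") "omega" else "omegaHN",
                    if (params$tau > 0) "+IGC" else "-IGC")
  }
  structure(
    list(model = parse_model_tag(model)$tag, params = params, tree = tree,
         logLik = logLik, n_col = NA_integer_, convergence = 0L,
         message = "parameters supplied, not optimized", n_eval = 0L,
         n_starts = 0L, seed = NA_integer_,
         tau_at_boundary = params$tau == 0,
         omega_h_at_cap = FALSE, omega_h_cap = Inf,
         pi_policy = "fixed", code = code),
    class = "igc_fit"
  )
}

#' @export
print.igc_fit <- function(x, ...) {
  cat(sprintf("<igc_fit %s: logLik = %.4f, %d columns%s%s>\n",
              x$model, x$logLik, x$n_col,
              if (isTRUE(x$tau_at_boundary)) ", tau at 0" else "",
              if (isTRUE(x$omega_h_at_cap)) ", omegaH at cap" else ""))
  print(x$params)
  invisible(x)
}

#' @export
logLik.igc_fit <- function(object, ...) {
  p <- object$params
  np <- 1 + (if (p$mode == "omega") 1 else 2) +
    (if (endsWith(object$model, "+IGC")) 1 else 0) +
    nrow(object$tree$edges)
  structure(object$logLik, df = np, nobs = object$n_col, class = "logLik")
}

#' Tidy an IGC model fit
#'
#' @param x An `igc_fit`.
#' @param branch_lengths Include one row per branch length.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.igc_fit <- function(x, branch_lengths = FALSE, ...) {
  p <- x$params
  out <- tibble::tibble(
    term = c("kappa",
             if (p$mode == "omega") "omega" else c("omega_n", "omega_h"),
             "tau"),
    estimate = c(p$kappa,
                 if (p$mode == "omega") p$omega else c(p$omega_n, p$omega_h),
                 p$tau)
  )
  if (branch_lengths) {
    ed <- x$tree$edges
    lab <- ifelse(is.na(ed$child_label) | ed$child_label == "",
                  paste0("node", ed$child), ed$child_label)
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("length_", lab), estimate = ed$length))
  }
  out
}

#' One-row summary of an IGC model fit
#'
#' @param x An `igc_fit`.
#' @param ... Unused.
#' @return A tibble with the model tag, log-likelihood, parameter count,
#'   number of columns and boundary flags.
#' @exportS3Method generics::glance
glance.igc_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    logLik = x$logLik,
    np = attr(logLik(x), "df"),
    n_col = x$n_col,
    convergence = x$convergence,
    tau_at_boundary = x$tau_at_boundary,
    omega_h_at_cap = x$omega_h_at_cap
  )
}

# ---- likelihood-ratio tests -------------------------------------------------

MIXTURES <- c("chisq1", "mix_half_chisq0_chisq1", "mix_half_chisq1_chisq2")

#' Tail probability of the boundary-mixture null distributions
#'
#' Null distributions for the nested model comparisons: a plain chi-square
#' with 1 df when only the omegaH = omegaN constraint is released; an
#' equiprobable mixture of a point mass at 0 and a chi-square(1) when the
#' released parameter (tau) sits on the boundary of its space; and an
#' equiprobable mixture of chi-square(1) and chi-square(2) when both are
#' released at once. The 0.05 critical value of the last mixture is 5.14.
#'
#' @param x Nonnegative test statistic (vectorized).
#' @param mixture One of `"chisq1"`, `"mix_half_chisq0_chisq1"`,
#'   `"mix_half_chisq1_chisq2"`.
#' @return P(statistic > x) under the null.
#' @export
#' @examples
#' mixture_sf(5.14, "mix_half_chisq1_chisq2")  # ~0.05
mixture_sf <- function(x, mixture = MIXTURES) {
  mixture <- match.arg(mixture)
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  switch(
    mixture,
    chisq1 = stats::pchisq(x, df = 1, lower.tail = FALSE),
    mix_half_chisq0_chisq1 =
      ifelse(x == 0, 1, 0.5 * stats::pchisq(x, df = 1, lower.tail = FALSE)),
    mix_half_chisq1_chisq2 =
      0.5 * stats::pchisq(x, df = 1, lower.tail = FALSE) +
      0.5 * stats::pchisq(x, df = 2, lower.tail = FALSE)
  )
}

# which constraints separate two nested model tags
nesting_constraints <- function(null_tag, alt_tag) {
  nt <- parse_model_tag(null_tag); at <- parse_model_tag(alt_tag)
  adds_igc <- !nt$igc && at$igc
  adds_hn <- nt$mode == "omega" && at$mode == "omega_h_n"
  drops <- (nt$igc && !at$igc) || (nt$mode == "omega_h_n" && at$mode == "omega")
  if (drops || (!adds_igc && !adds_hn)) {
    stop(sprintf("'%s' is not nested in '%s'", null_tag, alt_tag),
         call. = FALSE)
  }
  list(adds_igc = adds_igc, adds_hn = adds_hn)
}

#' Likelihood-ratio test between two nested fits
#'
#' Computes twice the log-likelihood difference and selects the null
#' distribution automatically from the constraints separating the two
#' models: releasing omegaH = omegaN alone gives chi-square(1); releasing
#' tau = 0 alone gives the half-and-half mixture of a point mass at 0 and
#' chi-square(1), because tau = 0 lies on the boundary of the parameter
#' space; releasing both gives the half-and-half mixture of chi-square(1)
#' and chi-square(2). Small negative statistics from optimizer noise are
#' clamped to 0 and flagged.
#'
#' @param null_fit,alt_fit `igc_fit` objects for properly nested models
#'   fitted to the same data.
#' @param level Significance level for the rejection flag.
#' @return An `igc_lrt` object (tidy-able) with the statistic, null
#'   distribution, p-value and rejection flag.
#' @export
lrt_igc <- function(null_fit, alt_fit, level = 0.05) {
  if (null_fit$n_col != alt_fit$n_col) {
    stop("fits must be on identical data", call. = FALSE)
  }
  cons <- nesting_constraints(null_fit$model, alt_fit$model)
  stat <- 2 * (alt_fit$logLik - null_fit$logLik)
  clamped <- stat < 0
  if (stat < -1e-6) {
    warning(sprintf(
      "negative LRT statistic %.3g exceeds optimizer tolerance; clamped to 0",
      stat))
  }
  stat <- max(stat, 0)
  dist <- if (cons$adds_igc && cons$adds_hn) "mix_half_chisq1_chisq2"
          else if (cons$adds_igc) "mix_half_chisq0_chisq1"
          else "chisq1"
  p <- mixture_sf(stat, dist)
  structure(
    list(null_model = null_fit$model, alt_model = alt_fit$model,
         statistic = stat, null_distribution = dist, p_value = p,
         rejected = p < level, level = level, clamped = clamped),
    class = "igc_lrt"
  )
}

#' @export
print.igc_lrt <- function(x, ...) {
  cat(sprintf("<igc_lrt %s vs %s: Lambda = %.4f, null = %s, p = %.4g%s>\n",
              x$null_model, x$alt_model, x$statistic, x$null_distribution,
              x$p_value, if (x$rejected) " *" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.igc_lrt <- function(x, ...) {
  tibble::tibble(
    null_model = x$null_model, alt_model = x$alt_model,
    statistic = x$statistic, null_distribution = x$null_distribution,
    p_value = x$p_value, rejected = x$rejected, clamped = x$clamped
  )
}

#' Run the full model-comparison lattice
#'
#' Fits all four model variants and performs the five nested comparisons:
#' the two two-step decomposition paths from the simplest model to the
#' most flexible one, plus the direct two-constraint comparison.
#'
#' @inheritParams fit_igc
#' @param ... Passed to [fit_igc()].
#' @return A list with `fits` (named list of `igc_fit`) and `tests`
#'   (tibble of the five tidy LRT rows).
#' @export
model_lattice <- function(alignment, tree, code = alignment$code, ...) {
  fits <- lapply(stats::setNames(MODEL_TAGS, MODEL_TAGS), function(m) {
    fit_igc(alignment, tree, m, code = code, ...)
  })
  pairs <- list(
    c("omega-IGC", "omega+IGC"),
    c("omega-IGC", "omegaHN-IGC"),
    c("omega+IGC", "omegaHN+IGC"),
    c("omegaHN-IGC", "omegaHN+IGC"),
    c("omega-IGC", "omegaHN+IGC")
  )
  tests <- dplyr::bind_rows(lapply(pairs, function(p) {
    tidy(lrt_igc(fits[[p[1]]], fits[[p[2]]]))
  }))
  list(fits = fits, tests = tests)
}

# ---- data screens -----------------------------------------------------------

#' Paralog-swap orthology screen
#'
#' Fits the no-IGC one-omega model under the given orthology labels and
#' again with the two paralogs of one taxon swapped. A higher swapped
#' likelihood suggests mislabeled orthology/paralogy relationships, so the
#' data set is flagged suspect; ties favor the given labels. The intended
#' input is the five-sequence subset containing the outgroup and the
#' paralog pairs of the two earliest-diverging post-duplication taxa.
#'
#' @param alignment A `pair_alignment` containing the subset.
#' @param tree The matching `duplication_tree`.
#' @param swap_taxon Taxon whose paralog pair is swapped for the
#'   alternative fit.
#' @param code A `genetic_code`.
#' @param ... Passed to [fit_igc()].
#' @return A list with `status` ("consistent" or "suspect"),
#'   `logLik_given`, `logLik_swapped` and the swapped taxon.
#' @export
paralog_swap_check <- function(alignment, tree, swap_taxon,
                               code = alignment$code, ...) {
  if (!swap_taxon %in% alignment$taxa$taxon ||
      !alignment$taxa$paired[alignment$taxa$taxon == swap_taxon]) {
    stop(sprintf("'%s' is not a paired taxon of the alignment", swap_taxon),
         call. = FALSE)
  }
  fit0 <- fit_igc(alignment, tree, "omega-IGC", code = code, ...)
  swapped <- swap_paralogs(alignment, swap_taxon)
  fit1 <- fit_igc(swapped, tree, "omega-IGC", code = code, ...)
  delta <- fit1$logLik - fit0$logLik
  list(
    status = if (delta > 1e-6) "suspect" else "consistent",
    logLik_given = fit0$logLik,
    logLik_swapped = fit1$logLik,
    swap_taxon = swap_taxon
  )
}

#' Swap the paralog labels of one taxon
#'
#' @param alignment A `pair_alignment`.
#' @param taxon A paired taxon.
#' @return The alignment with the taxon's locus-0 and locus-1 rows
#'   exchanged.
#' @export
swap_paralogs <- function(alignment, taxon) {
  s0 <- paste0(taxon, "|0"); s1 <- paste0(taxon, "|1")
  if (!all(c(s0, s1) %in% rownames(alignment$states))) {
    stop(sprintf("taxon '%s' has no paralog pair", taxon), call. = FALSE)
  }
  st <- alignment$states
  tmp <- st[s0, ]
  st[s0, ] <- st[s1, ]
  st[s1, ] <- tmp
  alignment$states <- st
  alignment
}

#' Branch-length screen
#'
#' Flags fits in which any estimated branch length exceeds the cap
#' (default 1.5 codon substitutions per codon), a symptom of sequencing,
#' alignment or orthology problems.
#'
#' @param fit An `igc_fit`.
#' @param cap Maximum acceptable branch length.
#' @return A tibble with one row per branch (`child_label`, `length`,
#'   `pass`) and an attribute `pass` for the whole fit.
#' @export
branch_length_screen <- function(fit, cap = 1.5) {
  ed <- fit$tree$edges
  out <- tibble::tibble(
    child_label = ifelse(is.na(ed$child_label) | ed$child_label == "",
                         paste0("node", ed$child), ed$child_label),
    length = ed$length,
    pass = ed$length <= cap
  )
  attr(out, "pass") <- all(out$pass)
  out
}
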