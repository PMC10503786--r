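#' Integrated labeled-flux matrix J(t)
#'
#' Computes `J(t) = integral_0^t exp(Q s) L exp(Q (t - s)) ds`, the
#' kernel of expected labeled substitution counts over a branch of length
#' `t`, as the upper-right block of the exponential of the 2x2 block
#' matrix `[[Q, L], [0, Q]] * t` (the matrix-of-exponentials technique).
#' `L` must be an entrywise nonnegative subset of the off-diagonal rates
#' of `Q`, marking the transitions to be counted.
#'
#' @param Q Rate matrix (dense or sparse).
#' @param L Label matrix, same dimension.
#' @param t Branch length, >= 0.
#' @return Dense matrix J(t).
#' @export
joint_integral <- function(Q, L, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  m <- nrow(Q)
  if (!all(dim(Q) == dim(L))) stop("Q and L shapes differ", call. = FALSE)
  if (t == 0) return(matrix(0, m, m))
  Z <- Matrix::Matrix(0, m, m, sparse = TRUE)
  A <- rbind(cbind(Q, L), cbind(Z, Q))
  E <- as.matrix(Matrix::expm(A * t))
  E[seq_len(m), m + seq_len(m), drop = FALSE]
}

# J(t) %*% V without forming J: exp([[Q,L],[0,Q]] t) [0; V] = [J V; P V].
joint_integral_apply <- function(Q, L, t, V) {
  V <- as.matrix(V)
  m <- nrow(Q)
  if (t == 0) return(matrix(0, m, ncol(V)))
  Z <- Matrix::Matrix(0, m, m, sparse = TRUE)
  A <- rbind(cbind(Q, L), cbind(Z, Q))
  W <- expm_apply(A, t, rbind(matrix(0, m, ncol(V)), V))
  W[seq_len(m), , drop = FALSE]
}

DEFAULT_LABELS <- c("igc_syn", "igc_nonsyn", "point_syn",
                    "point_nonsyn_hom", "point_nonsyn_nonhom")

# Outside (rootward) vectors. For every node v, O[[v]] is the partial of
# the data outside v's subtree as a function of the state at v (with a
# per-pattern log-scale); for every edge e = (a, c), Opre[[e]] is the
# outside-of-edge vector at a: O[[a]] times the rootward messages of c's
# sibling subtrees, diagonal-embedded into pair space when a is the
# duplication node. Spaces: single above the duplication, pair below.
outside_pass <- function(tree, inside, contribs, srm, n, npat) {
  edges <- tree$edges
  nn <- length(tree$labels)
  O <- vector("list", nn); Osc <- vector("list", nn)
  Opre <- vector("list", nrow(edges)); Opre_sc <- vector("list", nrow(edges))
  O[[tree$root]] <- matrix(srm$stationary, n, npat)
  Osc[[tree$root]] <- rep(0, npat)
  # preorder: parents before children (reverse postorder)
  for (v in rev(tree$postorder)) {
    ch_e <- which(edges$parent == v)
    if (!length(ch_e)) next
    base <- O[[v]]
    base_sc <- Osc[[v]]
    if (v == tree$dup) {
      # embed the single-copy outside vector on the pair diagonal
      emb <- matrix(0, n * n, npat)
      emb[pair_index(seq_len(n), seq_len(n), n), ] <- base
      base <- emb
    }
    for (e in ch_e) {
      c_node <- edges$child[e]
      pre <- base
      sc <- base_sc
      for (s in ch_e[ch_e != e]) {
        pre <- pre * contribs[[s]]$mat
        sc <- sc + contribs[[s]]$scale
      }
      Opre[[e]] <- pre
      Opre_sc[[e]] <- sc
      oc <- expm_apply(Matrix::t(contribs[[e]]$Q), edges$length[e], pre)
      mx <- col_max(oc)
      mx[mx <= 0] <- 1
      O[[c_node]] <- sweep(oc, 2, mx, "/")
      Osc[[c_node]] <- sc + log(mx)
    }
  }
  list(O = O, scale = Osc, Opre = Opre, Opre_sc = Opre_sc)
}

#' Expected labeled substitution counts per branch
#'
#' For each countable branch (and optionally every pair-regime branch),
#' computes the expected number of substitutions of each labeled class --
#' IGC synonymous, IGC nonsynonymous, point synonymous, point
#' nonsynonymous homogenizing, point nonsynonymous nonhomogenizing --
#' either conditional on the observed alignment (the default: posterior
#' expectations combining branch-endpoint partial likelihoods with the
#' integrated flux J(t)) or unconditional under the fitted model. Rates
#' entering the pair diagonal are a sum of a point and an IGC component;
#' attribution follows that additive decomposition.
#'
#' @param fit An `igc_fit` (its parameters and branch lengths are used).
#' @param alignment The `pair_alignment` the fit was computed on
#'   (required for conditional expectations).
#' @param conditional Condition on the observed data (default) or report
#'   prior expectations under the model.
#' @param countable_only Restrict to countable branches (the branches
#'   subsequent to the first post-duplication speciation), the only ones
#'   over which IGC is identifiable; `FALSE` is a diagnostic override
#'   covering all pair-regime branches.
#' @param labels Character subset of the five label classes.
#' @param label_matrices Optional named list of custom label matrices (an
#'   entrywise nonnegative subset of the off-diagonal pair rates each),
#'   overriding the built-in five-class decomposition.
#' @return An `igc_counts` tibble: one row per branch x label with column
#'   `expected`, plus attributes `proportion_igc`, `totals`, `conditional`
#'   and `model`.
#' @export
expected_counts <- function(fit, alignment = NULL, conditional = TRUE,
                            countable_only = TRUE,
                            labels = DEFAULT_LABELS,
                            label_matrices = NULL) {
  stopifnot(inherits(fit, "igc_fit"))
  labels <- if (is.null(label_matrices)) {
    match.arg(labels, DEFAULT_LABELS, several.ok = TRUE)
  } else {
    names(label_matrices)
  }
  tree <- fit$tree
  code <- fit$code
  params <- fit$params
  n <- code$n
  prm <- pair_rate_matrix(params, code)
  srm <- single_rate_matrix(single_interval_params(params), code)
  edges <- tree$edges
  sel <- if (countable_only) which(edges$countable)
         else which(edges$regime == "pair")
  if (!length(sel)) stop("tree has no countable branch", call. = FALSE)

  if (conditional) {
    if (is.null(alignment)) {
      stop("alignment is required for conditional expectations",
           call. = FALSE)
    }
    pr <- prune_patterns(alignment, tree, params, code, prm = prm, srm = srm,
                         keep_partials = TRUE)
    npat <- pr$patterns$n_pat
    w <- pr$patterns$weights
    inside <- pr$stored
    # per-edge rootward messages P(t_e) B_child with their scales
    contribs <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      Q <- if (edges$regime[e] == "pair") prm$q else srm$q
      contribs[[e]] <- list(
        mat = expm_apply(Q, edges$length[e], inside$partials[[edges$child[e]]]),
        scale = inside$scales[[edges$child[e]]],
        Q = Q
      )
    }
    out <- outside_pass(tree, inside, contribs, srm, n, npat)
    rows <- list()
    for (e in sel) {
      c_node <- edges$child[e]
      B <- inside$partials[[c_node]]
      Oa <- out$Opre[[e]]
      logw <- out$Opre_sc[[e]] + inside$scales[[c_node]] - pr$site_ll
      for (lb in labels) {
        Lm <- if (is.null(label_matrices)) prm$labels[[lb]]
              else label_matrices[[lb]]
        JV <- joint_integral_apply(prm$q, Lm, edges$length[e], B)
        e_pat <- colSums(Oa * JV) * exp(logw)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          branch = edge_label(edges, e), label = lb,
          expected = sum(w * e_pat)
        )
      }
    }
    counts <- dplyr::bind_rows(rows)
  } else {
    # unconditional: propagate the state distribution from the root and
    # integrate the labeled flux; per-site expectation times n columns
    n_col <- if (is.null(alignment)) 1L else alignment$n_col
    mu <- vector("list", length(tree$labels))
    mu[[tree$root]] <- srm$stationary
    for (v in rev(tree$postorder)) {
      ch_e <- which(edges$parent == v)
      if (!length(ch_e)) next
      m_here <- mu[[v]]
      if (v == tree$dup) {
        emb <- rep(0, n * n)
        emb[pair_index(seq_len(n), seq_len(n), n)] <- m_here
        m_here <- emb
      }
      for (e in ch_e) {
        Q <- if (edges$regime[e] == "pair") prm$q else srm$q
        mu[[edges$child[e]]] <- as.numeric(
          expm_apply(Matrix::t(Q), edges$length[e], m_here))
      }
    }
    rows <- list()
    for (e in sel) {
      m_par <- mu[[edges$parent[e]]]
      if (edges$parent[e] == tree$dup) {
        emb <- rep(0, n * n)
        emb[pair_index(seq_len(n), seq_len(n), n)] <- m_par
        m_par <- emb
      }
      ones <- matrix(1, n * n, 1)
      for (lb in labels) {
        Lm <- if (is.null(label_matrices)) prm$labels[[lb]]
              else label_matrices[[lb]]
        JV <- joint_integral_apply(prm$q, Lm, edges$length[e], ones)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          branch = edge_label(edges, e), label = lb,
          expected = n_col * sum(m_par * JV)
        )
      }
    }
    counts <- dplyr::bind_rows(rows)
  }
  totals <- tapply(counts$expected, counts$label, sum)
  igc_total <- sum(totals[grepl("^igc", names(totals))], na.rm = TRUE)
  all_total <- sum(totals, na.rm = TRUE)
  structure(
    counts,
    class = c("igc_counts", class(counts)),
    proportion_igc = if (all_total > 0) igc_total / all_total else NA_real_,
    totals = totals,
    conditional = conditional,
    model = fit$model
  )
}

edge_label <- function(edges, e) {
  lb <- edges$child_label[e]
  if (is.na(lb) || lb == "") paste0("node", edges$child[e]) else lb
}

#' Proportion of substitutions attributed to IGC
#'
#' Ratio of the summed IGC-labeled expected counts to the all-label total
#' over the branches in `counts` (countable branches by default).
#'
#' @param counts An `igc_counts` object.
#' @return A number in [0, 1], or NA (with a warning) when the total
#'   expected number of substitutions is zero.
#' @export
igc_proportion <- function(counts) {
  p <- attr(counts, "proportion_igc")
  if (is.na(p)) {
    warning("total expected substitution count is zero; proportion undefined")
  }
  p
}

#' @export
print.igc_counts <- function(x, ...) {
  cat(sprintf("<igc_counts (%s, %s): proportion IGC = %s>\n",
              attr(x, "model"),
              if (attr(x, "conditional")) "conditional" else "unconditional",
              format(attr(x, "proportion_igc"), digits = 4)))
  NextMethod()
}

#' Per-branch labeled counts in wide layout
#'
#' @param x An `igc_counts` object.
#' @param ... Unused.
#' @return A tibble with one row per branch, one column per label, plus
#'   per-branch totals and IGC proportions.
#' @exportS3Method generics::tidy
tidy.igc_counts <- function(x, ...) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x), names_from = "label",
                             values_from = "expected")
  lab_cols <- intersect(DEFAULT_LABELS, names(wide))
  tot <- rowSums(wide[lab_cols])
  igc <- rowSums(wide[intersect(c("igc_syn", "igc_nonsyn"), names(wide))])
  wide$total <- tot
  wide$proportion_igc <- ifelse(tot > 0, igc / tot, NA_real_)
  wide
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot expected labeled counts per branch
#'
#' Stacked bars of the expected substitution counts by label class for
#' each branch, the visual companion of [expected_counts()].
#'
#' @param object An `igc_counts` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.igc_counts <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch, y = .data$expected,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "branch (child node)",
                  y = "expected substitutions",
                  fill = "class",
                  title = sprintf("Expected substitution counts (%s)",
                                  attr(object, "model")),
                  subtitle = sprintf("proportion from IGC: %s",
                                     format(attr(object, "proportion_igc"),
                                            digits = 3))) +
    ggplot2::theme_minimal()
}
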