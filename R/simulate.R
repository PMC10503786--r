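#' Exact event-logged simulation of paralog-pair evolution
#'
#' Gillespie simulation of the joint codon process on a duplication tree:
#' the root codon is drawn from the single-copy stationary distribution,
#' evolved down single-copy branches, copied deterministically into the
#' identical pair (i, i) at the duplication node, and evolved down pair
#' branches under the labeled joint generator. Sites are independent,
#' matching the inference model's per-codon IGC assumption (tract-level
#' IGC is deliberately not simulated). Every substitution event is
#' logged with its origin: when a state change is admissible both as a
#' point mutation and as an IGC copy, the origin is sampled with
#' probability proportional to the two additive rate components, so
#' realized labeled counts estimate the same quantities as the expected-
#' count machinery. Each site uses its own random stream derived from the
#' master seed, so results are bit-reproducible and independent of
#' iteration order.
#'
#' @param params An `igc_params` object.
#' @param tree A `duplication_tree`.
#' @param n_codons Number of independent codon sites.
#' @param code A `genetic_code`.
#' @param seed Integer master seed.
#' @return An `igc_sim` list: `alignment` (a `pair_alignment` of the tip
#'   sequences), `events` (tibble: site, branch, time, locus, from1,
#'   from2, to1, to2, origin, synonymous, homogenizing), `root_states`,
#'   and the inputs.
#' @export
simulate_igc <- function(params, tree, n_codons, code = standard_code(),
                         seed = 1) {
  validate_igc_params(params, code)
  stopifnot(n_codons >= 1)
  srm <- single_rate_matrix(single_interval_params(params), code)
  prm <- pair_rate_matrix(params, code)
  kern <- pair_sim_kernel(prm)
  skern <- single_sim_kernel(srm)
  n <- code$n
  edges <- tree$edges
  kids_e <- split(seq_len(nrow(edges)), edges$parent)
  # preorder list of edges (parent edge before child edges)
  edge_order <- integer(0)
  stack <- kids_e[[as.character(tree$root)]]
  while (length(stack)) {
    e <- stack[[1]]; stack <- stack[-1]
    edge_order <- c(edge_order, e)
    ch <- kids_e[[as.character(edges$child[e])]]
    stack <- c(ch, stack)
  }
  set.seed(as.integer(seed))
  site_seeds <- sample.int(.Machine$integer.max - 1L, n_codons)
  f <- srm$stationary

  aa <- unname(code$aa)
  # hoist edge fields out of the tibble for the hot loop
  e_parent <- edges$parent; e_child <- edges$child; e_len <- edges$length
  e_pair <- edges$regime == "pair"
  e_lab <- vapply(seq_len(nrow(edges)), function(e) edge_label(edges, e),
                  character(1))
  s_exit <- skern$exit; s_targets <- skern$targets; s_rates <- skern$rates
  k_exit <- kern$exit; k_rows <- kern$rows
  n_tip <- tree$n_tip; dup <- tree$dup
  # flat event accumulators, grown geometrically
  cap <- max(64L, 4L * n_codons)
  ev_site <- integer(cap); ev_edge <- integer(cap); ev_time <- numeric(cap)
  ev_locus <- integer(cap); ev_f1 <- integer(cap); ev_f2 <- integer(cap)
  ev_t1 <- integer(cap); ev_t2 <- integer(cap); ev_igc <- logical(cap)
  ev_syn <- logical(cap); ev_hom <- logical(cap)
  n_ev <- 0L
  grow <- function() {
    cap <<- cap * 2L
    ev_site <<- `length<-`(ev_site, cap)
    ev_edge <<- `length<-`(ev_edge, cap)
    ev_time <<- `length<-`(ev_time, cap)
    ev_locus <<- `length<-`(ev_locus, cap)
    ev_f1 <<- `length<-`(ev_f1, cap)
    ev_f2 <<- `length<-`(ev_f2, cap)
    ev_t1 <<- `length<-`(ev_t1, cap)
    ev_t2 <<- `length<-`(ev_t2, cap)
    ev_igc <<- `length<-`(ev_igc, cap)
    ev_syn <<- `length<-`(ev_syn, cap)
    ev_hom <<- `length<-`(ev_hom, cap)
  }
  root_states <- integer(n_codons)
  tip_states <- matrix(NA_integer_, n_tip, n_codons)  # pair or single idx
  node_state <- integer(length(tree$labels))
  for (site in seq_len(n_codons)) {
    set.seed(site_seeds[site])
    root_states[site] <- sample.int(n, 1, prob = f)
    node_state[tree$root] <- root_states[site]
    for (e in edge_order) {
      a <- e_parent[e]; c_node <- e_child[e]
      st <- node_state[a]
      if (a == dup) st <- (st - 1L) * n + st
      len <- e_len[e]
      if (!e_pair[e]) {
        t_now <- 0
        repeat {
          rate <- s_exit[st]
          if (rate <= 0) break
          t_now <- t_now + stats::rexp(1, rate)
          if (t_now > len) break
          tg <- s_targets[[st]]
          k <- if (length(tg) == 1L) 1L
               else sample.int(length(tg), 1, prob = s_rates[[st]])
          to <- tg[k]
          if (n_ev == cap) grow()
          n_ev <- n_ev + 1L
          ev_site[n_ev] <- site; ev_edge[n_ev] <- e; ev_time[n_ev] <- t_now
          ev_locus[n_ev] <- 1L
          ev_f1[n_ev] <- st; ev_f2[n_ev] <- NA_integer_
          ev_t1[n_ev] <- to; ev_t2[n_ev] <- NA_integer_
          ev_igc[n_ev] <- FALSE
          ev_syn[n_ev] <- aa[st] == aa[to]; ev_hom[n_ev] <- NA
          st <- to
        }
      } else {
        t_now <- 0
        repeat {
          rate <- k_exit[st]
          if (rate <= 0) break
          t_now <- t_now + stats::rexp(1, rate)
          if (t_now > len) break
          idx <- k_rows[[st]]
          k <- if (length(idx$targets) == 1L) 1L
               else sample.int(length(idx$targets), 1, prob = idx$total)
          to <- idx$targets[k]
          p_rate <- idx$point[k]; g_rate <- idx$igc[k]
          is_igc <- if (g_rate <= 0) FALSE
                    else if (p_rate <= 0) TRUE
                    else stats::runif(1) >= p_rate / (p_rate + g_rate)
          f1 <- ((st - 1L) %/% n) + 1L; f2 <- ((st - 1L) %% n) + 1L
          t1 <- ((to - 1L) %/% n) + 1L; t2 <- ((to - 1L) %% n) + 1L
          locus <- if (f1 != t1) 1L else 2L
          old <- if (locus == 1L) f1 else f2
          new <- if (locus == 1L) t1 else t2
          partner <- if (locus == 1L) f2 else f1
          syn <- aa[old] == aa[new]
          if (n_ev == cap) grow()
          n_ev <- n_ev + 1L
          ev_site[n_ev] <- site; ev_edge[n_ev] <- e; ev_time[n_ev] <- t_now
          ev_locus[n_ev] <- locus
          ev_f1[n_ev] <- f1; ev_f2[n_ev] <- f2
          ev_t1[n_ev] <- t1; ev_t2[n_ev] <- t2
          ev_igc[n_ev] <- is_igc
          ev_syn[n_ev] <- syn
          ev_hom[n_ev] <- if (syn) NA else aa[new] == aa[partner]
          st <- to
        }
      }
      node_state[c_node] <- st
      if (c_node <= n_tip) tip_states[c_node, site] <- st
    }
  }
  keep <- seq_len(n_ev)
  events <- tibble::tibble(
    site = ev_site[keep], branch = e_lab[ev_edge[keep]],
    time = ev_time[keep], locus = ev_locus[keep],
    from1 = code$codons[ev_f1[keep]], from2 = code$codons[ev_f2[keep]],
    to1 = code$codons[ev_t1[keep]], to2 = code$codons[ev_t2[keep]],
    origin = ifelse(ev_igc[keep], "igc", "point"),
    synonymous = ev_syn[keep], homogenizing = ev_hom[keep]
  )
  seqs <- character(0)
  for (k in seq_len(tree$n_tip)) {
    lab <- tree$tips$label[k]
    if (tree$tips$regime[k] == "pair") {
      ij <- pair_unindex(tip_states[k, ], n)
      seqs[paste0(lab, "|0")] <- paste0(code$codons[ij[, "first"]],
                                        collapse = "")
      seqs[paste0(lab, "|1")] <- paste0(code$codons[ij[, "second"]],
                                        collapse = "")
    } else {
      seqs[lab] <- paste0(code$codons[tip_states[k, ]], collapse = "")
    }
  }
  structure(
    list(alignment = pair_alignment(seqs, code), events = events,
         root_states = root_states, tree = tree, params = params,
         code = code, seed = seed, n_codons = n_codons),
    class = "igc_sim"
  )
}

#' @export
print.igc_sim <- function(x, ...) {
  cat(sprintf("<igc_sim: %d codons, %d events (%d IGC), seed %d>\n",
              x$n_codons, nrow(x$events), sum(x$events$origin == "igc"),
              x$seed))
  invisible(x)
}

# per-state adjacency of the sparse pair generator, with the additive
# point/IGC split retained for origin sampling
pair_sim_kernel <- function(prm) {
  qo <- prm$q_point + prm$q_igc
  tr <- Matrix::summary(methods::as(qo, "TsparseMatrix"))
  pt <- as.numeric(prm$q_point[cbind(tr$i, tr$j)])
  ig <- as.numeric(prm$q_igc[cbind(tr$i, tr$j)])
  ord <- order(tr$i, tr$j)
  i <- tr$i[ord]; j <- tr$j[ord]; x <- tr$x[ord]
  pt <- pt[ord]; ig <- ig[ord]
  rows <- vector("list", prm$n_states)
  sp <- split(seq_along(i), i)
  for (s in names(sp)) {
    k <- sp[[s]]
    rows[[as.integer(s)]] <- list(targets = j[k], total = x[k],
                                  point = pt[k], igc = ig[k])
  }
  exit <- numeric(prm$n_states)
  agg <- tapply(x, i, sum)
  exit[as.integer(names(agg))] <- agg
  list(rows = rows, exit = exit)
}

single_sim_kernel <- function(srm) {
  q <- srm$q
  n <- nrow(q)
  targets <- vector("list", n); rates <- vector("list", n)
  for (s in seq_len(n)) {
    r <- q[s, ]; r[s] <- 0
    nz <- which(r > 0)
    targets[[s]] <- nz
    rates[[s]] <- r[nz]
  }
  list(targets = targets, rates = rates, exit = -diag(q))
}

#' Replay an event log from the root states
#'
#' Reapplies every logged event in branch order and time order, starting
#' from the logged root state of each site, and returns the resulting tip
#' sequences. Used to verify that the log is complete and consistent:
#' replay must reproduce the simulated alignment exactly.
#'
#' @param sim An `igc_sim`.
#' @return A named character vector of tip sequences in the alignment's
#'   slot naming.
#' @export
replay_events <- function(sim) {
  tree <- sim$tree; code <- sim$code; n <- code$n
  edges <- tree$edges
  kids_e <- split(seq_len(nrow(edges)), edges$parent)
  codon_index <- stats::setNames(seq_len(n), code$codons)
  ev <- sim$events
  tips <- matrix(NA_integer_, tree$n_tip, sim$n_codons)
  walk <- function(v, st, site) {
    if (v <= tree$n_tip) { tips[v, site] <<- st; return(invisible()) }
    for (e in kids_e[[as.character(v)]]) {
      st_e <- if (v == tree$dup && edges$regime[e] == "pair" &&
                  length(st) == 1L && st <= n) pair_index(st, st, n) else st
      lab <- edge_label(edges, e)
      here <- ev[ev$site == site & ev$branch == lab, , drop = FALSE]
      here <- here[order(here$time), , drop = FALSE]
      cur <- st_e
      if (nrow(here)) {
        for (r in seq_len(nrow(here))) {
          if (edges$regime[e] == "pair") {
            expect <- pair_index(codon_index[here$from1[r]],
                                 codon_index[here$from2[r]], n)
            stopifnot(cur == expect)
            cur <- pair_index(codon_index[here$to1[r]],
                              codon_index[here$to2[r]], n)
          } else {
            stopifnot(cur == codon_index[here$from1[r]])
            cur <- unname(codon_index[here$to1[r]])
          }
        }
      }
      walk(edges$child[e], cur, site)
    }
  }
  for (site in seq_len(sim$n_codons)) {
    walk(tree$root, sim$root_states[site], site)
  }
  seqs <- character(0)
  for (k in seq_len(tree$n_tip)) {
    lab <- tree$tips$label[k]
    if (tree$tips$regime[k] == "pair") {
      ij <- pair_unindex(tips[k, ], n)
      seqs[paste0(lab, "|0")] <- paste0(code$codons[ij[, "first"]],
                                        collapse = "")
      seqs[paste0(lab, "|1")] <- paste0(code$codons[ij[, "second"]],
                                        collapse = "")
    } else {
      seqs[lab] <- paste0(code$codons[tips[k, ]], collapse = "")
    }
  }
  seqs
}

#' Realized substitution-event tallies of a simulation
#'
#' Counts logged events by origin over a chosen branch scope and reports
#' the realized percentage of substitutions attributable to IGC. Because
#' an IGC substitution requires a prior point substitution to have
#' desynchronized the paralogs, this percentage cannot exceed 50 over the
#' full post-duplication history started from identical paralogs.
#'
#' @param sim An `igc_sim`.
#' @param scope `"post_duplication"` (every pair-regime branch, the
#'   default) or `"countable"` (branches subsequent to the first
#'   post-duplication speciation).
#' @return A one-row tibble: `n_point`, `n_igc`, `pct_igc`.
#' @export
realized_igc <- function(sim, scope = c("post_duplication", "countable")) {
  scope <- match.arg(scope)
  edges <- sim$tree$edges
  keep_br <- vapply(seq_len(nrow(edges)), function(e) edge_label(edges, e),
                    character(1))
  keep_br <- keep_br[if (scope == "countable") edges$countable
                     else edges$regime == "pair"]
  ev <- sim$events[sim$events$branch %in% keep_br, , drop = FALSE]
  n_igc <- sum(ev$origin == "igc")
  n_point <- sum(ev$origin == "point")
  tibble::tibble(
    n_point = n_point, n_igc = n_igc,
    pct_igc = if (n_igc + n_point > 0) 100 * n_igc / (n_igc + n_point)
              else NA_real_
  )
}

#' Deterministic bundled test scenarios
#'
#' Named simulation scenarios used throughout the tests and examples:
#' \describe{
#'   \item{teleost-like}{Standard code on an outgroup + duplication +
#'     four-taxon post-duplication clade, with teleost-like truth
#'     (kappa = 3, omegaN = 0.1, omegaH = 0.5, tau = 0.2).}
#'   \item{two-tip-minimal}{A two-"codon"-letter toy code and two paired
#'     tips: small enough for exhaustive-likelihood oracles.}
#'   \item{yeast-like-high-tau}{Standard code with the high-IGC,
#'     high-omegaH regime reported for duplicated yeast ribosomal
#'     protein genes (tau = 2.3, omegaH = 5.7).}
#' }
#'
#' @param scenario Scenario tag.
#' @param n_codons Number of codon sites (scenario default if NULL).
#' @param seed Master seed.
#' @return A list: `alignment`, `tree`, `params` (the truth), `code`,
#'   `events`, `sim`.
#' @export
make_fixture <- function(scenario = c("teleost-like", "two-tip-minimal",
                                      "yeast-like-high-tau"),
                         n_codons = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  if (scenario == "teleost-like") {
    code <- standard_code()
    tree <- read_duplication_tree(
      "(((((A:0.2,B:0.2)n3:0.2,C:0.2)n2:0.2,D:0.2)spec:0.2)dup:0.1,Out:0.5)root;",
      duplication_node = "dup")
    params <- igc_params(pi = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                         kappa = 3, omega_h = 0.5, omega_n = 0.1, tau = 0.2)
    if (is.null(n_codons)) n_codons <- 500
  } else if (scenario == "two-tip-minimal") {
    code <- toy_code(c("A", "C"), 2,
                     c(AA = "K", AC = "K", CA = "T", CC = "T"))
    tree <- read_duplication_tree(
      "(((A:0.15,B:0.15)spec:0.1)dup:0.1,Out:0.3)root;",
      duplication_node = "dup")
    params <- igc_params(pi = c(A = 0.6, C = 0.4), kappa = 1,
                         omega = 0.5, tau = 0.4)
    if (is.null(n_codons)) n_codons <- 200
  } else {
    code <- standard_code()
    tree <- read_duplication_tree(
      "((((Y1:0.12,Y2:0.12)n2:0.08,Y3:0.15)spec:0.1)dup:0.08,Outg:0.4)root;",
      duplication_node = "dup")
    params <- igc_params(pi = c(A = 0.3, C = 0.22, G = 0.22, T = 0.26),
                         kappa = 4, omega_h = 5.7, omega_n = 0.08, tau = 2.3)
    if (is.null(n_codons)) n_codons <- 300
  }
  sim <- simulate_igc(params, tree, n_codons, code, seed = seed)
  list(alignment = sim$alignment, tree = tree, params = params,
       code = code, events = sim$events, sim = sim)
}
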